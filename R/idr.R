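#' Pair peaks across two replicates
#'
#' Greedy one-to-one matching: replicate-1 peaks are visited in descending
#' score order and each takes the highest-scoring not-yet-taken replicate-2
#' peak it overlaps (>= 1 bp). Leftover peaks on either side are recorded as
#' unpaired; they can never be called reproducible.
#'
#' @param rep1,rep2 non-empty [peak_set()]s.
#' @return Object of class `paired_peaks`: list with `pairs` (data frame of
#'   matched intervals and scores) and `unpaired` (a [peak_set()] per
#'   replicate).
#' @export
pair_replicates <- function(rep1, rep2) {
  if (!nrow(rep1) || !nrow(rep2))
    stop("both replicates must be non-empty; no IDR analysis is possible ",
         "on an empty peak set")
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(.ps_granges(rep1), .ps_granges(rep2),
                                minoverlap = 1L))
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  taken2 <- rep(FALSE, nrow(rep2))
  match2 <- rep(NA_integer_, nrow(rep1))
  cand <- split(s, q)
  for (i in order(-rep1$score)) {
    ci <- cand[[as.character(i)]]
    ci <- ci[!taken2[ci]]
    if (!length(ci)) next
    j <- ci[which.max(rep2$score[ci])]
    match2[i] <- j
    taken2[j] <- TRUE
  }
  hit <- which(!is.na(match2))
  pairs <- data.frame(
    chrom = rep1$chrom[hit],
    start1 = rep1$start[hit], end1 = rep1$end[hit],
    start2 = rep2$start[match2[hit]], end2 = rep2$end[match2[hit]],
    score1 = rep1$score[hit], score2 = rep2$score[match2[hit]],
    name1 = rep1$name[hit], name2 = rep2$name[match2[hit]],
    stringsAsFactors = FALSE)
  un1 <- rep1[is.na(match2), , drop = FALSE]
  un2 <- rep2[!taken2, , drop = FALSE]
  structure(list(pairs = pairs,
                 unpaired = list(
                   rep1 = structure(un1, class = class(rep1),
                                    factor = attr(rep1, "factor"),
                                    replicate = attr(rep1, "replicate")),
                   rep2 = structure(un2, class = class(rep2),
                                    factor = attr(rep2, "factor"),
                                    replicate = attr(rep2, "replicate")))),
            class = "paired_peaks")
}

#' @export
print.paired_peaks <- function(x, ...) {
  cat(sprintf("paired_peaks: %d pair(s); %d + %d unpaired\n",
              nrow(x$pairs), nrow(x$unpaired$rep1), nrow(x$unpaired$rep2)))
  invisible(x)
}

# log density of the two components on normal scores
.idr_logdens <- function(z1, z2, pi1, mu, sigma2, rho) {
  ld0 <- -log(2 * pi) - (z1^2 + z2^2) / 2
  d1 <- z1 - mu; d2 <- z2 - mu
  q <- (d1^2 - 2 * rho * d1 * d2 + d2^2) / (sigma2 * (1 - rho^2))
  ld1 <- -log(2 * pi) - log(sigma2) - 0.5 * log(1 - rho^2) - q / 2
  list(ld0 = ld0, ld1 = ld1)
}

# posterior of the reproducible component + total log-likelihood
.idr_estep <- function(z1, z2, pi1, mu, sigma2, rho) {
  ld <- .idr_logdens(z1, z2, pi1, mu, sigma2, rho)
  a <- log(pi1) + ld$ld1
  b <- log1p(-pi1) + ld$ld0
  m <- pmax(a, b)
  ll <- sum(m + log(exp(a - m) + exp(b - m)))
  list(w = 1 / (1 + exp(b - a)), loglik = ll)
}

# invert the fitted mixture marginal CDF at the rank quantiles
# (pseudo-data step: maps the irreproducible mass back onto the standard
# normal the model's component 0 assumes)
.idr_pseudo_data <- function(u, pi1, mu, sigma2) {
  s <- sqrt(sigma2)
  g <- seq(min(-4.5, mu - 4.5 * s), max(4.5, mu + 4.5 * s),
           length.out = 4000)
  H <- pi1 * stats::pnorm(g, mu, s) + (1 - pi1) * stats::pnorm(g)
  stats::approx(H, g, xout = u, rule = 2, ties = "ordered")$y
}

#' Fit the IDR copula mixture model
#'
#' Replicate scores enter only through their ranks (`u = (rank - 0.5) / n`).
#' A two-component bivariate normal mixture is fitted by EM: component 0
#' (irreproducible) is standard bivariate normal with independent
#' coordinates; component 1 (reproducible) has mean `(mu, mu)`, common
#' variance `sigma2` and correlation `rho`. Because the marginal of the
#' mixture is itself a mixture, the normal scores are recomputed between EM
#' passes by inverting the current fitted marginal CDF at the rank
#' quantiles (the pseudo-data iteration of semiparametric copula
#' estimation); without this step the irreproducible mass cannot line up
#' with the fixed standard-normal component and the fit collapses to one
#' component.
#'
#' @param paired a [pair_replicates()] result with >= 50 pairs.
#' @param max_iter,tol inner-EM iteration cap and log-likelihood
#'   convergence tolerance.
#' @param max_outer,outer_tol pseudo-data iteration cap and parameter-change
#'   tolerance.
#' @return Object of class `idr_fit` with elements `pi1`, `mu`, `sigma2`,
#'   `rho`, `loglik_trace` (of the final EM pass), `converged`, `n_pairs`,
#'   and the final pseudo-data scores `z1`, `z2`.
#' @seealso [assign_idr()], [call_reproducible()]
#' @export
fit_idr <- function(paired, max_iter = 500L, tol = 1e-6,
                    max_outer = 30L, outer_tol = 1e-4) {
  p <- paired$pairs
  if (nrow(p) < 50)
    stop("need >= 50 paired peaks for a stable IDR fit (got ", nrow(p), ")")
  if (length(unique(p$score1)) == 1 || length(unique(p$score2)) == 1)
    stop("degenerate input: all scores tied in one replicate; ",
         "ranks carry no information and the IDR model cannot be fitted")
  n <- nrow(p)
  u1 <- (rank(p$score1, ties.method = "average") - 0.5) / n
  u2 <- (rank(p$score2, ties.method = "average") - 0.5) / n
  pi1 <- 0.5; mu <- 1; sigma2 <- 1; rho <- 0.5
  trace <- numeric(0)
  converged <- FALSE
  z1 <- z2 <- NULL
  for (o in seq_len(max_outer)) {
    z1 <- .idr_pseudo_data(u1, pi1, mu, sigma2)
    z2 <- .idr_pseudo_data(u2, pi1, mu, sigma2)
    old <- c(pi1, mu, sigma2, rho)
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      e <- .idr_estep(z1, z2, pi1, mu, sigma2, rho)
      trace <- c(trace, e$loglik)
      w <- e$w
      sw <- sum(w)
      pi1 <- min(max(sw / n, 1e-4), 1 - 1e-4)
      mu <- sum(w * (z1 + z2)) / (2 * sw)
      sigma2 <- max(sum(w * ((z1 - mu)^2 + (z2 - mu)^2)) / (2 * sw), 1e-6)
      rho <- sum(w * (z1 - mu) * (z2 - mu)) / (sw * sigma2)
      rho <- min(max(rho, 0), 0.999)
      if (it > 1 && abs(trace[it] - trace[it - 1]) < tol) {
        converged <- TRUE
        break
      }
    }
    if (max(abs(c(pi1, mu, sigma2, rho) - old)) < outer_tol) break
  }
  if (!converged)
    warning("IDR EM did not converge in ", max_iter, " iterations")
  structure(list(pi1 = pi1, mu = mu, sigma2 = sigma2, rho = rho,
                 loglik_trace = trace, converged = converged,
                 n_pairs = n, z1 = z1, z2 = z2),
            class = "idr_fit")
}

#' @export
print.idr_fit <- function(x, ...) {
  cat("IDR copula mixture fit\n")
  cat(sprintf("  pairs: %d | EM iterations: %d (%s)\n", x$n_pairs,
              length(x$loglik_trace),
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  pi1 = %.3f  mu = %.3f  sigma2 = %.3f  rho = %.3f\n",
              x$pi1, x$mu, x$sigma2, x$rho))
  invisible(x)
}

#' @export
coef.idr_fit <- function(object, ...) {
  c(pi1 = object$pi1, mu = object$mu, sigma2 = object$sigma2,
    rho = object$rho)
}

#' @export
logLik.idr_fit <- function(object, ...) {
  structure(utils::tail(object$loglik_trace, 1), df = 4,
            nobs = object$n_pairs, class = "logLik")
}

#' @export
summary.idr_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  final log-likelihood: %.2f\n",
              utils::tail(object$loglik_trace, 1)))
  invisible(object)
}

#' @export
plot.idr_fit <- function(x, ...) {
  e <- .idr_estep(x$z1, x$z2, x$pi1, x$mu, x$sigma2, x$rho)
  graphics::plot(x$z1, x$z2, col = grDevices::grey(1 - e$w), pch = 16,
                 cex = 0.5, xlab = "replicate 1 (normal score)",
                 ylab = "replicate 2 (normal score)",
                 main = sprintf("IDR fit: pi1 = %.2f, rho = %.2f",
                                x$pi1, x$rho), ...)
  invisible(x)
}

#' Per-pair local and global IDR
#'
#' The local IDR of a pair is its posterior probability of belonging to the
#' irreproducible component; the global IDR of the i-th best pair is the
#' mean of the i smallest local IDR values (a non-decreasing, FDR-like
#' quantity along the ranking).
#'
#' @param model a fitted [fit_idr()] model.
#' @param paired the [pair_replicates()] result the model was fitted on.
#' @return Object of class `idr_assignment`: list with `local_idr` and
#'   `global_idr`, both aligned with `paired$pairs` rows.
#' @export
assign_idr <- function(model, paired) {
  p <- paired$pairs
  n <- nrow(p)
  z1 <- .idr_pseudo_data((rank(p$score1, ties.method = "average") - 0.5) / n,
                         model$pi1, model$mu, model$sigma2)
  z2 <- .idr_pseudo_data((rank(p$score2, ties.method = "average") - 0.5) / n,
                         model$pi1, model$mu, model$sigma2)
  e <- .idr_estep(z1, z2, model$pi1, model$mu, model$sigma2, model$rho)
  local <- 1 - e$w
  ord <- order(local)
  g <- cumsum(local[ord]) / seq_along(local)
  global <- numeric(length(local))
  global[ord] <- g
  structure(list(local_idr = local, global_idr = global),
            class = "idr_assignment")
}

#' @export
print.idr_assignment <- function(x, ...) {
  cat(sprintf("idr_assignment: %d pair(s); %d at global IDR <= 0.05\n",
              length(x$local_idr), sum(x$global_idr <= 0.05)))
  invisible(x)
}

#' Call reproducible peaks at a global IDR threshold
#'
#' Pairs with global IDR at or below `alpha` are exported as single merged
#' intervals (the union span of the two replicate peaks) with combined
#' score equal to the sum of the replicate scores.
#'
#' @param assignment an [assign_idr()] result.
#' @param paired the matching [pair_replicates()] result.
#' @param alpha global IDR threshold in (0, 1); default 0.05.
#' @return A [peak_set()] of reproducible peaks.
#' @export
call_reproducible <- function(assignment, paired, alpha = 0.05) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  p <- paired$pairs
  keep <- assignment$global_idr <= alpha
  if (!any(keep)) return(.empty_peak_set())
  p <- p[keep, , drop = FALSE]
  peak_set(p$chrom, pmin(p$start1, p$start2), pmax(p$end1, p$end2),
           score = p$score1 + p$score2, name = p$name1)
}

#' Merge replicates without reproducibility filtering
#'
#' The lenient alternative to IDR filtering: the union of both replicates'
#' intervals, collapsed by overlap. Its loci are always a superset of the
#' loci passing any IDR threshold on the same input.
#'
#' @param rep1,rep2 [peak_set()]s.
#' @return A [peak_set()].
#' @export
merge_replicates <- function(rep1, rep2) {
  both <- rbind(as.data.frame(rep1), as.data.frame(rep2))
  if (!nrow(both)) return(.empty_peak_set(factor = attr(rep1, "factor")))
  merge_intervals(peak_set(both$chrom, both$start, both$end,
                           score = both$score, name = both$name,
                           factor = attr(rep1, "factor")))
}
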