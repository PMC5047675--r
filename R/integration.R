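#' Nearest-gene set of a peak set
#'
#' Deduplicated nearest-gene ids of all peaks — the standard peak-to-gene
#' assignment behind "factor-associated genes".
#'
#' @param peaks a [peak_set()].
#' @param ann a [gene_annotation()].
#' @return Character vector of unique gene ids (unassignable peaks are
#'   dropped).
#' @export
peak_gene_set <- function(peaks, ann) {
  if (!nrow(peaks)) return(character(0))
  ng <- nearest_gene(peaks, ann)
  unique(ng$gene_id[!is.na(ng$gene_id)])
}

#' Overlap report between two gene sets
#'
#' Cardinalities, the intersection as an integer percentage of `|A|`
#' (half-away-from-zero rounding — the field's reporting convention), and,
#' when a differential-expression result is supplied, the up/down split of
#' the intersection by fold-change sign among FDR-passing genes.
#'
#' @param a,b character vectors of gene ids (coerced to sets).
#' @param de optional [de_test()] result used for the direction split.
#' @return Object of class `overlap_report`: list with `n_a`, `n_b`,
#'   `n_intersect`, `percentage` (NA when `|A| = 0`), and `up` / `down`
#'   when `de` is given.
#' @export
overlap_report <- function(a, b, de = NULL) {
  a <- unique(a); b <- unique(b)
  inter <- intersect(a, b)
  pct <- if (length(a)) as.integer(round_half_up(100 * length(inter) / length(a)))
         else NA_integer_
  out <- list(n_a = length(a), n_b = length(b), n_intersect = length(inter),
              percentage = pct)
  if (!is.null(de)) {
    sig <- de[de$fdr <= attr(de, "alpha_fdr") & de$gene %in% inter, ,
              drop = FALSE]
    out$up <- sum(sig$log2fc > 0)
    out$down <- sum(sig$log2fc < 0)
  }
  structure(out, class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap_report: |A| = %d, |B| = %d, |A n B| = %d (%s%% of A)\n",
              x$n_a, x$n_b, x$n_intersect,
              if (is.na(x$percentage)) "undefined" else x$percentage))
  if (!is.null(x$up))
    cat(sprintf("  direction split of intersection: %d up, %d down\n",
                x$up, x$down))
  invisible(x)
}

#' Direction-of-change correlation between two DE results
#'
#' Least-squares regression of one contrast's log2 fold changes on the
#' other's over the genes called DE in both; the reported R-squared equals
#' the squared Pearson correlation of the pairs. The "no correlation"
#' regime (R-squared near zero) is the signature of two factors that do not
#' co-regulate their shared targets.
#'
#' @param de_x,de_y [de_test()] results.
#' @param gene_universe optional restriction of the shared gene set.
#' @return Object of class `direction_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `n_genes` and the paired fold changes.
#' @export
direction_correlation <- function(de_x, de_y, gene_universe = NULL) {
  gx <- de_genes(de_x); gy <- de_genes(de_y)
  shared <- intersect(gx, gy)
  if (!is.null(gene_universe)) shared <- intersect(shared, gene_universe)
  if (length(shared) < 3)
    stop("need >= 3 genes DE in both contrasts (got ", length(shared), ")")
  x <- de_x$log2fc[match(shared, de_x$gene)]
  y <- de_y$log2fc[match(shared, de_y$gene)]
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n_genes = length(shared),
                 pairs = data.frame(gene = shared, log2fc_x = x,
                                    log2fc_y = y)),
            class = "direction_fit")
}

#' @export
print.direction_fit <- function(x, ...) {
  cat(sprintf("direction_fit: %d shared DE genes; slope %.3f, R-squared %.3f\n",
              x$n_genes, x$slope, x$r_squared))
  invisible(x)
}

#' @export
plot.direction_fit <- function(x, ...) {
  graphics::plot(x$pairs$log2fc_x, x$pairs$log2fc_y, pch = 16, cex = 0.6,
                 xlab = "log2 fold change (x)", ylab = "log2 fold change (y)",
                 main = sprintf("R-squared = %.2f", x$r_squared), ...)
  graphics::abline(x$intercept, x$slope, col = "red")
  invisible(x)
}

#' Recruitment-dependency analysis of peak loss
#'
#' Identifies the cofactor peaks lost in a knockout ([peaks_lost()]) and
#' reports what percentage of those lost peaks were bound by the candidate
#' recruiter in WT cells — the test of whether the recruiter explains the
#' cofactor's positioning. Also reports the recruiter-dependent lost peaks
#' as a fraction of all WT cofactor peaks.
#'
#' @param mbd3_wt,mbd3_ko cofactor peak sets in WT and recruiter-null
#'   cells.
#' @param sall4_wt the candidate recruiter's WT peak set.
#' @return Object of class `dependency_report`: list with `n_wt`, `n_lost`,
#'   `n_lost_bound`, `pct_lost_bound` (NA when nothing is lost) and
#'   `pct_of_all_wt`.
#' @export
dependency_analysis <- function(mbd3_wt, mbd3_ko, sall4_wt) {
  lost <- peaks_lost(mbd3_wt, mbd3_ko)
  n_lost <- nrow(lost)
  n_bound <- if (n_lost) sum(overlap_any(lost, sall4_wt)) else 0L
  structure(list(
    n_wt = nrow(mbd3_wt), n_lost = n_lost, n_lost_bound = n_bound,
    pct_lost_bound = if (n_lost)
      as.integer(round_half_up(100 * n_bound / n_lost)) else NA_integer_,
    pct_of_all_wt = if (nrow(mbd3_wt))
      round_half_up(100 * n_bound / nrow(mbd3_wt), 1) else NA_real_),
    class = "dependency_report")
}

#' @export
print.dependency_report <- function(x, ...) {
  cat(sprintf("dependency_report: %d WT peaks, %d lost in KO; %d of the lost (%s%%) recruiter-bound (%.1f%% of all WT peaks)\n",
              x$n_wt, x$n_lost, x$n_lost_bound,
              if (is.na(x$pct_lost_bound)) "undefined" else x$pct_lost_bound,
              x$pct_of_all_wt))
  invisible(x)
}

#' Fold gain in peak numbers between conditions
#'
#' @param a,b [peak_set()]s (or bare counts); the ratio `|a| / |b|` is
#'   rounded to one decimal.
#' @return Numeric ratio to one decimal.
#' @export
fold_gain <- function(a, b) {
  na <- if (inherits(a, "data.frame")) nrow(a) else as.numeric(a)
  nb <- if (inherits(b, "data.frame")) nrow(b) else as.numeric(b)
  if (nb == 0) stop("reference peak set is empty; fold gain undefined")
  round_half_up(na / nb, 1)
}

#' Premature activation fraction
#'
#' Of the genes upregulated in the reference differentiation contrast, the
#' percentage already upregulated in the mutant self-renewal contrast — the
#' measure of a differentiation programme firing ahead of schedule.
#'
#' @param de_wt_diff DE result of the WT differentiation contrast.
#' @param de_mutant_selfrenewal DE result of the mutant-vs-WT contrast in
#'   self-renewal conditions.
#' @return Integer percentage, or `NA` when no gene is up in the first
#'   contrast.
#' @export
premature_activation_fraction <- function(de_wt_diff, de_mutant_selfrenewal) {
  up_wt <- de_genes(de_wt_diff, direction = "up")
  if (!length(up_wt)) return(NA_integer_)
  up_mut <- de_genes(de_mutant_selfrenewal, direction = "up")
  as.integer(round_half_up(100 * length(intersect(up_wt, up_mut)) /
                             length(up_wt)))
}
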