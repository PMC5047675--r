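#' Construct a protein intensity table
#'
#' Label-free (LFQ) intensities per protein per run, with run-group labels
#' (bait IP vs control) and theoretical tryptic peptide counts for
#' iBAQ-style normalisation.
#'
#' @param intensities numeric protein-by-run matrix; `NA` marks values
#'   missing at low abundance; present values must be positive.
#' @param groups character vector along the columns, `"bait"` or
#'   `"control"`.
#' @param peptide_counts named integer vector (>= 1) per protein; defaults
#'   to 1 for every protein (identity normalisation).
#' @return Object of class `protein_intensity_table`.
#' @export
protein_intensity_table <- function(intensities, groups,
                                    peptide_counts = NULL) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities))) stop("proteins must be named")
  if (length(groups) != ncol(intensities))
    stop("one group label per run is required")
  if (!all(groups %in% c("bait", "control")))
    stop("groups must be 'bait' or 'control'")
  if (any(intensities <= 0, na.rm = TRUE))
    stop("present intensities must be > 0")
  if (is.null(peptide_counts))
    peptide_counts <- stats::setNames(rep(1, nrow(intensities)),
                                      rownames(intensities))
  pc <- peptide_counts[rownames(intensities)]
  if (anyNA(pc) || any(pc < 1))
    stop("peptide_counts must cover every protein with values >= 1")
  structure(list(intensities = intensities, groups = groups,
                 peptide_counts = pc),
            class = "protein_intensity_table")
}

#' @export
print.protein_intensity_table <- function(x, ...) {
  cat(sprintf("protein_intensity_table: %d proteins x %d runs (%d bait, %d control); %.1f%% missing\n",
              nrow(x$intensities), ncol(x$intensities),
              sum(x$groups == "bait"), sum(x$groups == "control"),
              100 * mean(is.na(x$intensities))))
  invisible(x)
}

#' Read an LFQ intensity table and run design from TSV
#'
#' @param intensity_path TSV: `protein`, `peptide_count`, then one column
#'   per run; empty cells or zeros are treated as missing.
#' @param design_path TSV with columns `run`, `group`.
#' @return A [protein_intensity_table()].
#' @export
read_lfq <- function(intensity_path, design_path) {
  tb <- utils::read.delim(intensity_path, check.names = FALSE)
  design <- utils::read.delim(design_path)
  m <- as.matrix(tb[, setdiff(names(tb), c("protein", "peptide_count")),
                    drop = FALSE])
  rownames(m) <- tb$protein
  m[!is.na(m) & m <= 0] <- NA
  pc <- if ("peptide_count" %in% names(tb))
    stats::setNames(tb$peptide_count, tb$protein) else NULL
  protein_intensity_table(m, design$group[match(colnames(m), design$run)], pc)
}

#' Impute left-censored missing intensities
#'
#' Missing log-intensities are drawn, per run, from a normal distribution
#' down-shifted by `downshift` observed standard deviations and narrowed to
#' `width` of the observed spread — the standard treatment for
#' missing-at-low-abundance LFQ data.
#'
#' @param t a [protein_intensity_table()].
#' @param downshift,width shift and relative width in units of the per-run
#'   observed s.d. (defaults 1.8 and 0.3).
#' @param seed integer; imputation is deterministic given the seed.
#' @return A completed [protein_intensity_table()] (no `NA`s).
#' @export
impute_missing <- function(t, downshift = 1.8, width = 0.3, seed = 1L) {
  X <- t$intensities
  if (all(is.na(X))) stop("no observed value in the whole table")
  all_missing <- colSums(!is.na(X)) == 0
  if (any(all_missing))
    stop("run(s) with no observed value: ",
         paste(colnames(X)[all_missing], collapse = ", "))
  if (!anyNA(X)) return(t)
  with_seed(seed, {
    for (j in seq_len(ncol(X))) {
      obs <- log2(X[!is.na(X[, j]), j])
      nas <- which(is.na(X[, j]))
      if (!length(nas)) next
      s <- stats::sd(obs)
      if (!is.finite(s) || s == 0) s <- 1
      X[nas, j] <- 2^stats::rnorm(length(nas), mean(obs) - downshift * s,
                                  width * s)
    }
  })
  out <- t
  out$intensities <- X
  out
}

# all distinct balanced two-group label assignments of n = n1 + n2 runs
.group_assignments <- function(n, n1) {
  idx <- utils::combn(n, n1)
  lapply(seq_len(ncol(idx)), function(k) idx[, k])
}

# moderated difference statistic with fudge factor s0 on log2 intensities
.volcano_stat <- function(lx, is_bait, s0) {
  a <- lx[, !is_bait, drop = FALSE]; b <- lx[, is_bait, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  sp2 <- (rowSums((a - ma)^2) + rowSums((b - mb)^2)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  list(diff = mb - ma, stat = (mb - ma) / (se + s0))
}

#' Volcano interactor test with permutation FDR
#'
#' Per-protein bait-vs-control comparison on log2 intensities using a
#' moderated two-sample statistic with fudge factor `s0` (guards against
#' small-variance artefacts). The null distribution is built by pooling the
#' statistic over distinct group-label permutations; p-values are converted
#' to FDR by Benjamini-Hochberg. A protein is a significant interactor when
#' its FDR is at most `fdr_alpha` and its enrichment is positive.
#'
#' @param t a [protein_intensity_table()] with >= 3 replicates per group
#'   and no missing values (see [impute_missing()]).
#' @param s0 fudge factor on the denominator (default 0.1).
#' @param fdr_alpha significance threshold (default 0.01).
#' @param n_permutations cap on permutations; all distinct balanced
#'   relabellings are used when fewer (default 1000).
#' @param seed used only when permutations must be subsampled.
#' @return Object of class `volcano_result`: data frame `protein`,
#'   `log2_enrichment`, `stat`, `pvalue`, `fdr`, `significant`.
#' @export
volcano_test <- function(t, s0 = 0.1, fdr_alpha = 0.01,
                         n_permutations = 1000, seed = 1L) {
  is_bait <- t$groups == "bait"
  if (sum(is_bait) < 3 || sum(!is_bait) < 3)
    stop("need >= 3 replicates per group")
  if (anyNA(t$intensities))
    stop("missing intensities; run impute_missing() first")
  lx <- log2(t$intensities)
  obs <- .volcano_stat(lx, is_bait, s0)
  n <- length(is_bait); n1 <- sum(is_bait)
  perms <- .group_assignments(n, n1)
  orig <- sort(which(is_bait))
  comp <- sort(which(!is_bait))
  # drop the observed partition in both orientations: its sign-flipped twin
  # would plant every true effect inside its own null
  perms <- Filter(function(p) !identical(sort(p), orig) &&
                    !identical(sort(p), comp), perms)
  if (length(perms) < 2)
    stop("fewer than 2 distinct label permutations available")
  if (length(perms) > n_permutations)
    perms <- with_seed(seed, sample(perms, n_permutations))
  null_stats <- unlist(lapply(perms, function(p) {
    g <- rep(FALSE, n); g[p] <- TRUE
    .volcano_stat(lx, g, s0)$stat
  }))
  null_abs <- sort(abs(null_stats))
  N <- length(null_abs)
  # pooled permutation p-value: rank of |stat| in the pooled null
  ge <- N - findInterval(abs(obs$stat) - 1e-12, null_abs)
  pv <- (ge + 1) / (N + 1)
  fdr <- stats::p.adjust(pv, "BH")
  res <- data.frame(protein = rownames(t$intensities),
                    log2_enrichment = obs$diff, stat = obs$stat,
                    pvalue = pv, fdr = fdr,
                    significant = fdr <= fdr_alpha & obs$diff > 0,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, s0 = s0, fdr_alpha = fdr_alpha,
            n_permutations = length(perms),
            class = c("volcano_result", "data.frame"))
}

#' @export
print.volcano_result <- function(x, ...) {
  cat(sprintf("volcano_result: %d proteins, %d significant interactor(s) at FDR <= %.2g (%d permutations)\n",
              nrow(x), sum(x$significant), attr(x, "fdr_alpha"),
              attr(x, "n_permutations")))
  invisible(x)
}

#' @export
plot.volcano_result <- function(x, ...) {
  graphics::plot(x$log2_enrichment, -log10(x$pvalue),
                 pch = ifelse(x$significant, 16, 1),
                 xlab = "log2 enrichment (bait / control)",
                 ylab = "-log10 p", ...)
  invisible(x)
}

#' Anchor-relative interaction stoichiometry
#'
#' Abundance per protein is the background-corrected mean bait-IP intensity
#' (mean control intensity subtracted, clamped at zero) divided by its
#' theoretical peptide count (iBAQ convention, approximating molar
#' amounts). Each protein's stoichiometry `S_p` is its abundance relative
#' to the summed abundance of the designated anchor proteins, which share
#' one complex slot.
#'
#' @param t a [protein_intensity_table()].
#' @param complex_members proteins to report (default: all).
#' @param anchor_proteins protein(s) defining the anchor slot.
#' @param bait the bait protein name.
#' @return Object of class `stoichiometry_table`: data frame `protein`,
#'   `abundance`, `ratio_to_anchor`, with attributes `bait`, `anchors` and
#'   `S_bait`.
#' @export
stoichiometry <- function(t, complex_members = rownames(t$intensities),
                          anchor_proteins, bait) {
  miss <- setdiff(anchor_proteins, rownames(t$intensities))
  if (length(miss))
    stop("anchor protein(s) absent from table: ", paste(miss, collapse = ", "))
  if (!bait %in% rownames(t$intensities))
    stop("bait '", bait, "' absent from table")
  is_bait <- t$groups == "bait"
  mean_na0 <- function(x) { x <- x[!is.na(x)]; if (length(x)) mean(x) else 0 }
  ip <- apply(t$intensities[, is_bait, drop = FALSE], 1, mean_na0)
  ctrl <- apply(t$intensities[, !is_bait, drop = FALSE], 1, mean_na0)
  abundance <- pmax(ip - ctrl, 0) / t$peptide_counts
  anchor_ab <- sum(abundance[anchor_proteins])
  if (anchor_ab <= 0)
    stop("anchor abundance is zero; stoichiometry has no denominator")
  keep <- union(complex_members, c(anchor_proteins, bait))
  keep <- keep[keep %in% names(abundance)]
  res <- data.frame(protein = keep, abundance = abundance[keep],
                    ratio_to_anchor = abundance[keep] / anchor_ab,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, bait = bait, anchors = anchor_proteins,
            S_bait = abundance[[bait]] / anchor_ab,
            class = c("stoichiometry_table", "data.frame"))
}

#' @export
print.stoichiometry_table <- function(x, ...) {
  cat(sprintf("stoichiometry_table: %d proteins; bait %s at %.2f x anchor (%s)\n",
              nrow(x), attr(x, "bait"), attr(x, "S_bait"),
              paste(attr(x, "anchors"), collapse = "+")))
  print.data.frame(utils::head(
    as.data.frame(x)[order(-x$ratio_to_anchor), ], 10), digits = 3)
  invisible(x)
}

#' Fraction of bait resident in the complex
#'
#' Under the one-bait-copy, one-anchor-copy-per-complex assumption, a bait
#' purified at `S_bait`-fold molar excess over the anchor has `1 / S_bait`
#' of its molecules inside the complex. Returned as a percentage rounded to
#' the nearest integer (half away from zero).
#'
#' @param S_bait bait:anchor stoichiometry, >= 1 (also accepts a
#'   [stoichiometry()] result).
#' @return Integer percentage.
#' @export
fraction_in_complex <- function(S_bait) {
  if (inherits(S_bait, "stoichiometry_table"))
    S_bait <- attr(S_bait, "S_bait")
  if (S_bait < 1)
    stop("S_bait < 1 is inconsistent with one bait copy per complex ",
         "(more complexes than bait)")
  as.integer(round_half_up(100 / S_bait))
}
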