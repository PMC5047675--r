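#' Construct a gene-by-sample count matrix
#'
#' @param counts integer matrix, genes in rows (named), samples in columns.
#' @param gene_lengths named vector of summed exonic bp per gene.
#' @param design data frame with columns `sample`, `condition` (and
#'   optionally more); every column of `counts` must appear.
#' @return Object of class `count_matrix`: list with `counts`,
#'   `gene_lengths`, `design`.
#' @export
count_matrix <- function(counts, gene_lengths, design) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  if (is.null(rownames(counts))) stop("counts must have gene row names")
  if (!all(colnames(counts) %in% design$sample))
    stop("every sample (column) must appear in the design table")
  gl <- gene_lengths[rownames(counts)]
  if (anyNA(gl) || any(gl <= 0))
    stop("every gene needs a positive length")
  design <- design[match(colnames(counts), design$sample), , drop = FALSE]
  structure(list(counts = counts, gene_lengths = gl, design = design),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", names(table(x$design$condition)),
                            table(x$design$condition)), collapse = ", ")))
  invisible(x)
}

#' Read counts and design tables from TSV
#'
#' @param counts_path TSV with a `gene_id` first column, then one column
#'   per sample.
#' @param design_path TSV with `sample` and `condition` columns.
#' @param lengths_path optional TSV (`gene_id`, `length`); defaults to
#'   1 kb per gene when absent.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, design_path, lengths_path = NULL) {
  ct <- utils::read.delim(counts_path, check.names = FALSE)
  m <- as.matrix(ct[, -1, drop = FALSE])
  rownames(m) <- ct[[1]]
  design <- utils::read.delim(design_path)
  gl <- if (is.null(lengths_path))
    stats::setNames(rep(1000, nrow(m)), rownames(m))
  else {
    lt <- utils::read.delim(lengths_path)
    stats::setNames(lt[[2]], lt[[1]])
  }
  count_matrix(m, gl, design)
}

#' Fragments per kilobase per million mapped reads
#'
#' `FPKM = count / (length_kb * mapped_millions)` per sample, with a
#' sample's mapped total taken as its column sum.
#'
#' @param m a [count_matrix()].
#' @return Gene-by-sample numeric matrix.
#' @export
fpkm <- function(m) {
  depth <- colSums(m$counts)
  if (any(depth <= 0)) stop("every sample must have a positive column sum")
  if (any(m$gene_lengths <= 0)) stop("zero-length gene")
  sweep(m$counts / (m$gene_lengths / 1000), 2, depth / 1e6, "/")
}

#' Median-of-ratios size factors
#'
#' The classic normalisation: each sample's factor is the median across
#' genes of its ratio to the per-gene geometric mean, computed over genes
#' with all-positive counts, then rescaled so the median factor is 1. When
#' no gene has all-positive counts, falls back to upper-quartile scaling
#' with a warning.
#'
#' @param m a [count_matrix()] or a bare counts matrix.
#' @return Named per-sample size factors.
#' @export
size_factors <- function(m) {
  counts <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no gene with all-positive counts; using upper-quartile scaling")
    uq <- apply(counts, 2, function(x) stats::quantile(x[x > 0], 0.75))
    s <- uq / stats::median(uq)
    return(stats::setNames(s, colnames(counts)))
  }
  lg <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  s <- apply(lg, 2, function(x) exp(stats::median(x - geo)))
  s <- s / stats::median(s)
  stats::setNames(s, colnames(counts))
}

# shrink per-gene MoM dispersions halfway (in log space) to a mean trend
.dispersion_estimates <- function(norm, cond) {
  mu_bar <- rowMeans(norm)
  lev <- unique(cond)
  n <- length(cond)
  ss <- rowSums(vapply(lev, function(l) {
    x <- norm[, cond == l, drop = FALSE]
    rowSums((x - rowMeans(x))^2)
  }, numeric(nrow(norm))))
  v <- ss / (n - length(lev))
  phi_raw <- pmax((v - mu_bar) / mu_bar^2, 0)
  ok <- mu_bar > 0
  if (sum(ok) >= 10) {
    fit <- stats::lowess(log(mu_bar[ok]), phi_raw[ok], f = 0.5)
    trend <- stats::approx(fit$x, fit$y, xout = log(pmax(mu_bar, 1e-8)),
                           rule = 2, ties = mean)$y
  } else {
    trend <- rep(mean(phi_raw), length(phi_raw))
  }
  trend <- pmax(trend, 1e-6)
  # 50/50 shrink toward the trend, floored at the trend: a gene is never
  # granted less dispersion than its expression stratum typically shows,
  # which keeps the plug-in exact test conservative at small n
  phi <- pmax(0.5 * phi_raw + 0.5 * trend, trend)
  list(phi = pmax(phi, 1e-8), mu_bar = mu_bar)
}

# exact-style conditional NB test for one gene (edgeR-flavoured):
# sums per condition modelled as NB; p-value is the total probability of
# splits of the observed sum no more likely than the observed one
.nb_exact_p <- function(a, b, n_a, n_b, phi) {
  s <- a + b
  if (s == 0) return(1)
  mu0 <- s / (n_a + n_b)
  size_a <- n_a / phi; size_b <- n_b / phi
  lo <- max(0, stats::qnbinom(1e-12, mu = n_a * mu0, size = size_a),
            s - stats::qnbinom(1 - 1e-12, mu = n_b * mu0, size = size_b))
  hi <- min(s, stats::qnbinom(1 - 1e-12, mu = n_a * mu0, size = size_a),
            s - stats::qnbinom(1e-12, mu = n_b * mu0, size = size_b))
  if (lo > hi) { lo <- 0; hi <- s }
  k <- lo:hi
  lp <- stats::dnbinom(k, mu = n_a * mu0, size = size_a, log = TRUE) +
    stats::dnbinom(s - k, mu = n_b * mu0, size = size_b, log = TRUE)
  m <- max(lp)
  p_all <- exp(lp - m)
  p_obs <- exp(stats::dnbinom(a, mu = n_a * mu0, size = size_a, log = TRUE) +
                 stats::dnbinom(b, mu = n_b * mu0, size = size_b, log = TRUE) - m)
  min(1, sum(p_all[p_all <= p_obs * (1 + 1e-10)]) / sum(p_all))
}

#' Negative-binomial differential expression test
#'
#' Two-group exact-style test on size-factor-normalised counts: per-gene
#' method-of-moments dispersions are shrunk 50/50 (in log space) toward a
#' lowess trend on the mean, condition sums are modelled as negative
#' binomial, and the p-value is the conditional probability of splits of
#' the observed total no more likely than the observed split.
#' Benjamini-Hochberg correction gives the FDR.
#'
#' @param m a [count_matrix()].
#' @param contrast length-2 character vector `(conditionA, conditionB)`;
#'   fold changes are B over A.
#' @param alpha_fdr FDR threshold stored on the result (default 0.05).
#' @return Object of class `de_result`: data frame with `gene`,
#'   `mean_expr`, `log2fc`, `pvalue`, `fdr`, `dispersion`, plus attributes
#'   `size_factors`, `contrast` and `alpha_fdr`.
#' @export
de_test <- function(m, contrast, alpha_fdr = 0.05) {
  cond <- m$design$condition
  if (!all(contrast %in% cond))
    stop("contrast conditions not found in design: ",
         paste(setdiff(contrast, cond), collapse = ", "))
  keep <- cond %in% contrast
  counts <- m$counts[, keep, drop = FALSE]
  cond <- cond[keep]
  if (any(table(cond)[contrast] < 2))
    stop("need >= 2 replicates per condition to estimate dispersion")
  s <- size_factors(counts)
  norm <- sweep(counts, 2, s, "/")
  disp <- .dispersion_estimates(norm, cond)
  ia <- cond == contrast[1]; ib <- cond == contrast[2]
  n_a <- sum(ia); n_b <- sum(ib)
  mean_a <- rowMeans(norm[, ia, drop = FALSE])
  mean_b <- rowMeans(norm[, ib, drop = FALSE])
  log2fc <- log2((mean_b + 0.5) / (mean_a + 0.5))
  a <- round(rowSums(norm[, ia, drop = FALSE]))
  b <- round(rowSums(norm[, ib, drop = FALSE]))
  pv <- vapply(seq_len(nrow(counts)), function(g)
    .nb_exact_p(a[g], b[g], n_a, n_b, disp$phi[g]), numeric(1))
  res <- data.frame(gene = rownames(counts),
                    mean_expr = disp$mu_bar,
                    log2fc = log2fc, pvalue = pv,
                    fdr = stats::p.adjust(pv, "BH"),
                    dispersion = disp$phi,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, size_factors = s, contrast = contrast,
            alpha_fdr = alpha_fdr, class = c("de_result", "data.frame"))
}

#' @export
print.de_result <- function(x, ...) {
  ct <- attr(x, "contrast"); al <- attr(x, "alpha_fdr")
  cat(sprintf("de_result: %s vs %s | %d genes | %d DE at FDR <= %.2g\n",
              ct[2], ct[1], nrow(x), sum(x$fdr <= al), al))
  invisible(x)
}

#' @export
summary.de_result <- function(object, ...) {
  print(object)
  de <- de_genes(object)
  up <- sum(object$fdr <= attr(object, "alpha_fdr") & object$log2fc > 0)
  cat(sprintf("  up: %d  down: %d\n", up, length(de) - up))
  invisible(object)
}

#' @export
plot.de_result <- function(x, ...) {
  graphics::plot(x$log2fc, -log10(pmax(x$pvalue, 1e-300)),
                 pch = 16, cex = 0.4,
                 col = ifelse(x$fdr <= attr(x, "alpha_fdr"), "red", "grey40"),
                 xlab = "log2 fold change", ylab = "-log10 p", ...)
  invisible(x)
}

#' Differentially expressed genes of a result
#'
#' @param de a [de_test()] result.
#' @param alpha_fdr FDR threshold; defaults to the one stored on the result.
#' @param direction `"both"`, `"up"` (log2fc > 0) or `"down"`.
#' @return Character vector of gene ids.
#' @export
de_genes <- function(de, alpha_fdr = attr(de, "alpha_fdr"),
                     direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  keep <- de$fdr <= alpha_fdr
  if (direction == "up") keep <- keep & de$log2fc > 0
  if (direction == "down") keep <- keep & de$log2fc < 0
  de$gene[keep]
}

#' PCA embedding of RNA-seq samples
#'
#' Samples are embedded by singular-value decomposition of
#' `log2(FPKM + 1)` restricted to the most variable genes, gene-centred.
#' Component signs are fixed so the loading of the first retained gene on
#' each component is non-negative.
#'
#' @param m a [count_matrix()] with >= 3 samples.
#' @param n_top_variable how many genes to keep by variance (default 500).
#' @return List with `coords` (sample x PC matrix, first two components),
#'   `var_explained` (all components) and `genes` (the genes used).
#' @export
pca_embed <- function(m, n_top_variable = 500) {
  if (ncol(m$counts) < 3) stop("PCA needs >= 3 samples")
  x <- log2(fpkm(m) + 1)
  v <- apply(x, 1, stats::var)
  if (n_top_variable > nrow(x)) {
    warning("fewer genes than requested; using all ", nrow(x))
    n_top_variable <- nrow(x)
  }
  top <- order(-v)[seq_len(n_top_variable)]
  xt <- t(x[top, , drop = FALSE])              # samples x genes
  xt <- sweep(xt, 2, colMeans(xt))             # centre genes
  sv <- svd(xt)
  flip <- ifelse(sv$v[1, ] < 0, -1, 1)
  scores <- sweep(sv$u %*% diag(sv$d, length(sv$d)), 2, flip, "*")
  rownames(scores) <- colnames(m$counts)
  colnames(scores) <- sprintf("PC%d", seq_len(ncol(scores)))
  list(coords = scores[, 1:2, drop = FALSE],
       var_explained = sv$d^2 / sum(sv$d^2),
       genes = rownames(m$counts)[top])
}

#' Construct a single-cell qPCR Ct matrix
#'
#' @param ct numeric gene-by-cell matrix of cycle-threshold values; `NA`
#'   marks dropouts.
#' @param housekeeping character vector of housekeeping gene names present
#'   in the matrix (default Atp5a1, Ppia, Gapdh).
#' @return Object of class `ct_matrix`: list with `ct` and `housekeeping`.
#' @export
ct_matrix <- function(ct, housekeeping = c("Atp5a1", "Ppia", "Gapdh")) {
  ct <- as.matrix(ct)
  if (is.null(rownames(ct))) stop("Ct matrix needs gene row names")
  if (!length(housekeeping)) stop("housekeeping gene set must be non-empty")
  miss <- setdiff(housekeeping, rownames(ct))
  if (length(miss))
    stop("housekeeping gene(s) absent from matrix: ",
         paste(miss, collapse = ", "))
  structure(list(ct = ct, housekeeping = housekeeping), class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d genes x %d cells (%.1f%% missing)\n",
              nrow(x$ct), ncol(x$ct), 100 * mean(is.na(x$ct))))
  invisible(x)
}

#' Per-cell -dCt normalisation against housekeeping genes
#'
#' `-dCt = -(Ct_gene - mean Ct_housekeeping)` per cell; higher means more
#' expressed. Missing Ct values stay missing, and cells in which no
#' housekeeping gene was measured are dropped with a warning.
#'
#' @param c a [ct_matrix()].
#' @return Gene-by-cell matrix of -dCt values (housekeeping rows included).
#' @export
delta_ct_normalize <- function(c) {
  hk <- c$ct[c$housekeeping, , drop = FALSE]
  ref <- colMeans(hk, na.rm = TRUE)
  bad <- !is.finite(ref)
  if (any(bad)) {
    warning(sum(bad), " cell(s) lack all housekeeping measurements; dropped")
  }
  x <- c$ct[, !bad, drop = FALSE]
  -sweep(x, 2, ref[!bad])
}

#' Hierarchical clustering of genes and cells
#'
#' Average-linkage clustering on Euclidean distance with pairwise-complete
#' handling of missing values (base `dist()` semantics). Rows or columns
#' sharing fewer than 2 observations with every other one get undefined
#' distances; those are placed last and flagged.
#'
#' @param x numeric matrix (e.g. -dCt values), genes in rows.
#' @return List with `row_order`, `col_order` (leaf orders) and
#'   `flagged_rows` / `flagged_cols` (indices with undefined distances).
#' @export
hcluster_genes_cells <- function(x) {
  if (nrow(x) < 2) stop("need >= 2 rows to cluster")
  one_way <- function(mat) {
    d <- stats::dist(mat)
    dm <- as.matrix(d)
    diag(dm) <- NA
    bad <- which(apply(dm, 1, function(r) all(!is.finite(r))))
    ok <- setdiff(seq_len(nrow(mat)), bad)
    dm_ok <- dm[ok, ok, drop = FALSE]
    dm_ok[!is.finite(dm_ok)] <- max(dm_ok[is.finite(dm_ok)], 1) * 2
    ord <- if (length(ok) > 2) {
      diag(dm_ok) <- 0
      ok[stats::hclust(stats::as.dist(dm_ok), method = "average")$order]
    } else ok
    list(order = c(ord, bad), flagged = bad)
  }
  r <- one_way(x)
  cl <- one_way(t(x))
  list(row_order = r$order, col_order = cl$order,
       flagged_rows = r$flagged, flagged_cols = cl$flagged)
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,treated - Ct_hk,treated) -
#' (Ct_target,control - Ct_hk,control)`; the returned fold change is
#' `2^-ddCt`. Any missing input yields a missing output.
#'
#' @param ct_treated,ct_control target-gene Ct values (vectors recycle).
#' @param hk_treated,hk_control housekeeping (mean) Ct values.
#' @return Fold change(s) relative to control.
#' @export
relative_expression <- function(ct_treated, ct_control, hk_treated,
                                hk_control) {
  ddct <- (ct_treated - hk_treated) - (ct_control - hk_control)
  2^(-ddct)
}
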