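#' Signal profile matrix around peak centres
#'
#' One row per peak, one column per position bin spanning `flank` bp either
#' side of the peak centre (default 80 bins of 50 bp over +/- 2 kb). Rows
#' are sorted by descending row sum — the usual heat-map convention — and
#' the original order is recorded. Peaks too close to a chromosome edge are
#' padded with the genome-wide median background and flagged.
#'
#' @param peaks a [peak_set()].
#' @param track a [signal_track()]; its bin width must divide `bin_width`.
#' @param flank bp either side of the centre; must be a multiple of
#'   `bin_width`.
#' @param bin_width profile bin width in bp.
#' @return Object of class `profile_matrix`: the numeric matrix with
#'   attributes `peak_names` (row order after sorting), `padded` (logical
#'   per row) and `bin_mid` (bin midpoints relative to the centre).
#' @export
profile_matrix <- function(peaks, track, flank = 2000, bin_width = 50) {
  if (flank %% bin_width != 0) stop("flank must be a multiple of bin_width")
  tw <- track$bin_width
  if (bin_width %% tw != 0)
    stop("track bin width (", tw, ") must divide profile bin_width (",
         bin_width, ")")
  k <- bin_width %/% tw
  n_bins <- 2L * flank %/% bin_width
  bg <- stats::median(unlist(track$signal, use.names = FALSE))
  m <- matrix(NA_real_, nrow(peaks), n_bins)
  padded <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ch <- peaks$chrom[i]
    v <- track$signal[[ch]]
    if (is.null(v)) stop("track does not cover chromosome ", ch)
    centre <- floor((peaks$start[i] + peaks$end[i]) / 2)
    lo_bin <- (centre - flank) %/% tw + 1L   # track-bin index of window start
    idx <- lo_bin + seq_len(2L * flank %/% tw) - 1L
    out <- idx < 1L | idx > length(v)
    padded[i] <- any(out)
    vals <- ifelse(out, bg, v[pmin(pmax(idx, 1L), length(v))])
    m[i, ] <- colMeans(matrix(vals, nrow = k))
  }
  ord <- order(-rowSums(m))
  structure(m[ord, , drop = FALSE],
            peak_names = peaks$name[ord], padded = padded[ord],
            bin_mid = seq(-flank + bin_width / 2, flank - bin_width / 2,
                          by = bin_width),
            class = c("profile_matrix", "matrix"))
}

#' Meta-profile (column means) of a profile matrix
#'
#' @param m a [profile_matrix()] (any numeric matrix with >= 1 row works).
#' @return Numeric vector of per-bin means.
#' @export
metaprofile <- function(m) {
  if (!nrow(m)) stop("cannot compute a meta-profile of an empty matrix")
  colMeans(m)
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d peak(s) x %d bins\n", nrow(x), ncol(x)))
  invisible(x)
}

#' @export
plot.profile_matrix <- function(x, ...) {
  graphics::plot(attr(x, "bin_mid"), metaprofile(x), type = "l",
                 xlab = "distance from peak centre (bp)",
                 ylab = "mean signal", ...)
  invisible(x)
}

#' Occupancy correlation between ChIP datasets
#'
#' Each dataset is reduced to a binary occupancy vector over the merged
#' union of all peaks (the "universe"); datasets are compared by Pearson
#' correlation of those vectors and ordered by average-linkage hierarchical
#' clustering on distance `1 - r`.
#'
#' @param datasets named list of [peak_set()]s (>= 2).
#' @param universe optional [peak_set()] of universe intervals; defaults to
#'   the merged union of all datasets.
#' @return Object of class `correlation_result`: list with `matrix`
#'   (symmetric Pearson r), `order` (leaf order from clustering) and
#'   `hclust` (the tree).
#' @export
occupancy_correlation <- function(datasets, universe = NULL) {
  if (length(datasets) < 2) stop("need >= 2 datasets")
  if (is.null(names(datasets)) || any(names(datasets) == ""))
    stop("datasets must be named")
  if (is.null(universe)) {
    all_df <- do.call(rbind, lapply(datasets, as.data.frame))
    universe <- merge_intervals(peak_set(all_df$chrom, all_df$start,
                                         all_df$end))
  }
  occ <- vapply(names(datasets), function(nm) {
    v <- overlap_any(universe, datasets[[nm]])
    if (!any(v) || all(v))
      stop("dataset '", nm, "' has constant occupancy over the universe; ",
           "correlation is undefined")
    as.numeric(v)
  }, numeric(nrow(universe)))
  r <- stats::cor(occ)
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  structure(list(matrix = r, order = hc$order, hclust = hc),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("occupancy correlation:\n")
  print(round(x$matrix[x$order, x$order], 3))
  invisible(x)
}

#' @export
plot.correlation_result <- function(x, ...) {
  r <- x$matrix[x$order, x$order]
  graphics::image(seq_len(nrow(r)), seq_len(ncol(r)), r[, rev(seq_len(ncol(r)))],
                  axes = FALSE, xlab = "", ylab = "", zlim = c(-1, 1), ...)
  graphics::axis(1, seq_len(nrow(r)), rownames(r), las = 2)
  graphics::axis(2, seq_len(ncol(r)), rev(colnames(r)), las = 2)
  invisible(x)
}

#' Binned-signal correlation between tracks
#'
#' Alternative correlation mode: Pearson correlation of genome-wide binned
#' signal vectors rather than binary peak occupancy.
#'
#' @param tracks named list of [signal_track()]s on the same binning.
#' @return A `correlation_result` (see [occupancy_correlation()]).
#' @export
signal_correlation <- function(tracks) {
  if (length(tracks) < 2) stop("need >= 2 tracks")
  vecs <- vapply(tracks, function(tr) unlist(tr$signal, use.names = FALSE),
                 numeric(sum(lengths(tracks[[1]]$signal))))
  r <- stats::cor(vecs)
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  structure(list(matrix = r, order = hc$order, hclust = hc),
            class = "correlation_result")
}
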