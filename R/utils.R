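# Run code with a local RNG state so generators are pure functions of their
# seed and never disturb the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# round half away from zero (the reporting convention for percentages;
# base round() rounds half to even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Construct a binned signal track
#'
#' Genome-wide coverage for one mark or factor, stored as one value per
#' fixed-width bin per chromosome. Bin `i` of a chromosome covers bases
#' `[(i-1) * bin_width, i * bin_width)`.
#'
#' @param signal named list: one numeric vector per chromosome.
#' @param bin_width bin width in bp.
#' @param mark label of the mark/factor.
#' @return Object of class `signal_track`.
#' @export
signal_track <- function(signal, bin_width, mark = NA_character_) {
  stopifnot(is.list(signal), length(signal) > 0, bin_width > 0)
  if (is.null(names(signal)) || any(names(signal) == ""))
    stop("signal list must be named by chromosome")
  structure(list(signal = lapply(signal, as.numeric),
                 bin_width = as.integer(bin_width), mark = mark),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  nb <- sum(lengths(x$signal))
  cat(sprintf("signal_track%s: %d chromosome(s), %d bins of %d bp\n",
              if (is.na(x$mark)) "" else sprintf(" [%s]", x$mark),
              length(x$signal), nb, x$bin_width))
  invisible(x)
}

#' Read and write bedGraph signal tracks
#'
#' `write_bedgraph()` serialises a [signal_track()] (one line per bin);
#' `read_bedgraph()` reads it back, requiring a constant bin width.
#'
#' @param track a [signal_track()].
#' @param path file path.
#' @param mark label for the returned track.
#' @export
write_bedgraph <- function(track, path) {
  nb <- lengths(track$signal)
  starts <- unlist(lapply(nb, function(n)
    (seq_len(n) - 1L) * track$bin_width + 1L), use.names = FALSE)
  gr <- GenomicRanges::GRanges(
    rep(names(track$signal), nb),
    IRanges::IRanges(start = starts, width = track$bin_width),
    score = unlist(track$signal, use.names = FALSE))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path, mark = NA_character_) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  w <- unique(GenomicRanges::width(gr))
  if (length(w) != 1) stop("bedGraph does not have a constant bin width")
  sig <- lapply(split(gr, GenomicRanges::seqnames(gr)), function(g) {
    idx <- (GenomicRanges::start(g) - 1L) / w + 1L
    v <- numeric(max(idx))
    v[idx] <- g$score
    v
  })
  signal_track(sig[lengths(sig) > 0], bin_width = w, mark = mark)
}

#' Write a matrix or data frame as TSV
#'
#' @param x matrix or data frame.
#' @param path file path.
#' @param rownames_as column name under which to keep row names; `NULL`
#'   drops them.
#' @export
write_tsv_table <- function(x, path, rownames_as = NULL) {
  df <- as.data.frame(x)
  if (!is.null(rownames_as)) {
    df <- cbind(stats::setNames(data.frame(rownames(df)), rownames_as), df)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
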