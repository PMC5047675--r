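#' Classification thresholds for the five-class peak partition
#'
#' @param promoter_window bp either side of a TSS that makes a peak
#'   promoter-associated (default 1000).
#' @param tau_k4me3,tau_k4me1,tau_k27ac minimum mean fold enrichment over
#'   background for H3K4me3, H3K4me1 and H3K27ac (defaults 4, 2, 2).
#' @return Object of class `classification_thresholds`.
#' @export
classification_thresholds <- function(promoter_window = 1000,
                                      tau_k4me3 = 4, tau_k4me1 = 2,
                                      tau_k27ac = 2) {
  if (promoter_window <= 0) stop("promoter_window must be > 0")
  if (any(c(tau_k4me3, tau_k4me1, tau_k27ac) <= 0))
    stop("all enrichment thresholds must be > 0")
  structure(list(promoter_window = promoter_window, tau_k4me3 = tau_k4me3,
                 tau_k4me1 = tau_k4me1, tau_k27ac = tau_k27ac),
            class = "classification_thresholds")
}

#' Mean fold enrichment of peaks over track background
#'
#' Per-base mean signal within each peak (bin values weighted by the number
#' of covered bases) divided by the genome-wide median bin value of the
#' track.
#'
#' @param peaks a [peak_set()].
#' @param track a [signal_track()].
#' @return Numeric vector of fold enrichments along `peaks`.
#' @export
score_against_track <- function(peaks, track) {
  bg <- stats::median(unlist(track$signal, use.names = FALSE))
  if (bg <= 0) stop("track background median is zero; cannot normalise")
  bw <- track$bin_width
  vapply(seq_len(nrow(peaks)), function(i) {
    ch <- peaks$chrom[i]
    v <- track$signal[[ch]]
    if (is.null(v))
      stop("peak '", peaks$name[i], "' lies on chromosome '", ch,
           "' which the track does not cover")
    s <- peaks$start[i]; e <- peaks$end[i]
    if (e > length(v) * bw)
      stop("peak '", peaks$name[i], "' extends beyond the track extent on ", ch)
    lo <- floor(s / bw) + 1L
    hi <- ceiling(e / bw)
    bins <- lo:hi
    # per-base weights: first/last bins may be partially covered
    w <- rep(bw, length(bins))
    w[1] <- w[1] - (s - (lo - 1L) * bw)
    w[length(w)] <- w[length(w)] - (hi * bw - e)
    sum(v[bins] * w) / sum(w) / bg
  }, numeric(1))
}

#' Classify a single peak into one of five chromatin classes
#'
#' Decision cascade: (1) a peak whose centre lies within `promoter_window`
#' of any TSS, or whose H3K4me3 enrichment reaches `tau_k4me3`, is a
#' `promoter`; else (2) H3K4me1 at or above `tau_k4me1` (with H3K4me3 below
#' `tau_k4me3`) makes it an enhancer — `active_enhancer` when H3K27ac
#' reaches `tau_k27ac`, otherwise `poised_enhancer`; else (3) a centre
#' within a gene extent is `gene_body`; else (4) `intergenic`. The promoter
#' test deliberately precedes the enhancer test so a K4me3-high TSS peak is
#' never called an enhancer.
#'
#' @param peak one-row [peak_set()] slice (or list with `chrom`, `start`,
#'   `end`).
#' @param enrichments named numeric vector with at least `H3K4me3`,
#'   `H3K4me1`, `H3K27ac` fold enrichments for this peak.
#' @param ann a [gene_annotation()].
#' @param thr a [classification_thresholds()].
#' @return One of `"promoter"`, `"gene_body"`, `"intergenic"`,
#'   `"poised_enhancer"`, `"active_enhancer"`.
#' @export
classify_peak <- function(peak, enrichments, ann,
                          thr = classification_thresholds()) {
  need <- c("H3K4me3", "H3K4me1", "H3K27ac")
  miss <- setdiff(need, names(enrichments))
  if (length(miss))
    stop("missing mark enrichment(s): ", paste(miss, collapse = ", "),
         "; required marks are ", paste(need, collapse = ", "))
  centre <- floor((peak$start + peak$end) / 2)
  on_chrom <- ann$chrom == peak$chrom
  near_tss <- any(on_chrom & abs(ann$tss - centre) <= thr$promoter_window)
  if (near_tss || enrichments[["H3K4me3"]] >= thr$tau_k4me3)
    return("promoter")
  if (enrichments[["H3K4me1"]] >= thr$tau_k4me1) {
    return(if (enrichments[["H3K27ac"]] >= thr$tau_k27ac)
      "active_enhancer" else "poised_enhancer")
  }
  in_gene <- any(on_chrom & centre >= ann$start & centre < ann$end)
  if (in_gene) return("gene_body")
  "intergenic"
}

#' Classify a whole peak set from mark tracks
#'
#' Computes per-peak fold enrichments for each supplied mark track with
#' [score_against_track()] and applies the [classify_peak()] cascade to
#' every peak. Labels are exhaustive and mutually exclusive: the class
#' counts always sum to the number of peaks.
#'
#' @param peaks a [peak_set()].
#' @param tracks named list of [signal_track()]s containing at least
#'   `H3K4me3`, `H3K4me1`, `H3K27ac`.
#' @param ann a [gene_annotation()].
#' @param thr a [classification_thresholds()].
#' @return List with `labels` (data frame: peak `name`, `class`, one
#'   enrichment column per mark) and `counts` (named vector over the five
#'   classes).
#' @export
classify_peakset <- function(peaks, tracks, ann,
                             thr = classification_thresholds()) {
  classes <- c("promoter", "gene_body", "intergenic", "poised_enhancer",
               "active_enhancer")
  need <- c("H3K4me3", "H3K4me1", "H3K27ac")
  miss <- setdiff(need, names(tracks))
  if (length(miss))
    stop("missing mark track(s): ", paste(miss, collapse = ", "))
  if (!nrow(peaks)) {
    return(list(labels = data.frame(name = character(0), class = character(0)),
                counts = stats::setNames(integer(length(classes)), classes)))
  }
  enr <- vapply(tracks[need], function(tr) score_against_track(peaks, tr),
                numeric(nrow(peaks)))
  if (nrow(peaks) == 1) enr <- matrix(enr, 1, dimnames = list(NULL, need))
  lab <- vapply(seq_len(nrow(peaks)), function(i)
    classify_peak(peaks[i, ], enr[i, ], ann, thr), character(1))
  counts <- stats::setNames(
    vapply(classes, function(cl) sum(lab == cl), integer(1)), classes)
  list(labels = cbind(data.frame(name = peaks$name, class = lab,
                                 stringsAsFactors = FALSE),
                      as.data.frame(enr)),
       counts = counts)
}
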