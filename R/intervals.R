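#' Construct a peak set
#'
#' A `peak_set` holds scored genomic intervals for one factor/mark and one
#' replicate. Coordinates are 0-based half-open throughout the package (BED
#' convention): a peak `[start, end)` covers bases `start .. end - 1`.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `start` 0-based inclusive, `end`
#'   exclusive. Must satisfy `start < end`.
#' @param score non-negative numeric peak scores (default 0).
#' @param name optional peak labels; auto-generated when `NULL`.
#' @param factor,replicate labels identifying the dataset.
#' @return An object of class `peak_set`: a data frame with columns
#'   `chrom`, `start`, `end`, `name`, `score`, sorted by `(chrom, start)`,
#'   with attributes `factor` and `replicate`.
#' @examples
#' ps <- peak_set("chr1", c(100, 500), c(300, 900), score = c(5, 7))
#' ps
#' @export
peak_set <- function(chrom, start, end, score = 0, name = NULL,
                     factor = NA_character_, replicate = NA_character_) {
  start <- as.numeric(start); end <- as.numeric(end)
  n <- max(length(chrom), length(start))
  if (length(start) != length(end))
    stop("start and end must have equal length")
  chrom <- rep_len(as.character(chrom), n)
  score <- rep_len(as.numeric(score), n)
  if (is.null(name)) name <- if (n) sprintf("peak_%d", seq_len(n)) else character(0)
  if (any(end <= start))
    stop("invalid interval(s): end <= start at index ",
         paste(utils::head(which(end <= start), 5), collapse = ", "))
  if (any(score < 0)) stop("peak scores must be >= 0")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = as.character(name), score = score,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, factor = factor, replicate = replicate,
            class = c("peak_set", "data.frame"))
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %d interval(s)", nrow(x)))
  if (!is.na(attr(x, "factor"))) cat(sprintf(" [%s", attr(x, "factor")),
                                     if (!is.na(attr(x, "replicate")))
                                       sprintf("/%s", attr(x, "replicate")), "]", sep = "")
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

.empty_peak_set <- function(factor = NA_character_, replicate = NA_character_) {
  structure(data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), name = character(0),
                       score = numeric(0), stringsAsFactors = FALSE),
            factor = factor, replicate = replicate,
            class = c("peak_set", "data.frame"))
}

# internal: peak_set -> GRanges (1-based closed)
.ps_granges <- function(ps) {
  GenomicRanges::GRanges(ps$chrom,
                         IRanges::IRanges(start = ps$start + 1, end = ps$end),
                         score = ps$score, name = ps$name)
}

#' Construct a gene annotation
#'
#' Gene models with a strand-aware transcription start site (TSS). The TSS of
#' a `+`-strand gene is its `start`; of a `-`-strand gene, `end - 1` (both in
#' 0-based coordinates).
#'
#' @param genes data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` and optionally `exon_bp` (summed exonic bases; defaults to the
#'   gene width).
#' @return Object of class `gene_annotation`: the gene table with a computed
#'   `tss` column.
#' @export
gene_annotation <- function(genes) {
  req <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(req %in% names(genes)))
    stop("gene table must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop("gene_ids must be unique")
  if (any(genes$end <= genes$start)) stop("gene end must exceed start")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (is.null(genes$exon_bp)) genes$exon_bp <- genes$end - genes$start
  if (any(genes$exon_bp <= 0)) stop("exon_bp must be positive")
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  structure(genes, class = c("gene_annotation", "data.frame"))
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d gene(s) on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Read and write BED6 peak files
#'
#' `read_bed()` parses a BED file (>= 3 columns; name and score optional)
#' into a [peak_set()]; `write_bed()` writes one back. A write/read
#' round trip is the identity on `(chrom, start, end, name, score)`.
#'
#' @param path file path.
#' @param factor,replicate labels attached to the returned set.
#' @return `read_bed()` returns a [peak_set()]; `write_bed()` returns `path`
#'   invisibly.
#' @export
read_bed <- function(path, factor = NA_character_, replicate = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = "", comment.char = "#")
  if (length(nf) && any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], " in ", path,
         ": fewer than 3 fields")
  gr <- rtracklayer::import(path, format = "BED")
  sc <- gr$score
  if (is.null(sc)) sc <- rep(0, length(gr))
  sc[is.na(sc)] <- 0
  nm <- gr$name
  if (is.null(nm) || all(is.na(nm))) nm <- NULL
  peak_set(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr) - 1, GenomicRanges::end(gr),
           score = sc, name = nm, factor = factor, replicate = replicate)
}

#' @rdname read_bed
#' @param ps a [peak_set()].
#' @export
write_bed <- function(ps, path) {
  gr <- .ps_granges(ps)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a GFF3 gene annotation
#'
#' Keeps `gene` features; exon lengths are summed from `exon` children
#' (matched by `Parent`), falling back to the gene width for exonless
#' models. GFF3 1-based closed coordinates are converted to the package's
#' 0-based half-open convention on read.
#'
#' @param path GFF3 file path.
#' @return A [gene_annotation()].
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  if (!length(genes)) stop("no gene features in ", path)
  ids <- genes$ID
  if (is.null(ids) || any(is.na(ids))) stop("gene features must carry an ID attribute")
  exon_bp <- GenomicRanges::width(genes)  # fallback
  ex <- gr[gr$type == "exon"]
  if (length(ex)) {
    par <- vapply(ex$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                  character(1))
    tot <- tapply(GenomicRanges::width(ex), par, sum)
    hit <- match(ids, names(tot))
    exon_bp[!is.na(hit)] <- tot[hit[!is.na(hit)]]
  }
  gene_annotation(data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes) - 1,
    end = GenomicRanges::end(genes),
    strand = as.character(GenomicRanges::strand(genes)),
    exon_bp = as.numeric(exon_bp),
    stringsAsFactors = FALSE))
}

#' @rdname read_gff3
#' @param ann a [gene_annotation()].
#' @param source source tag written in column 2.
#' @export
write_gff3 <- function(ann, path, source = "chromflow") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(ann))) {
    g <- ann[i, ]
    writeLines(sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, source, g$start + 1, g$end, g$strand, g$gene_id), con)
    writeLines(sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tID=%s.e1;Parent=%s",
                       g$chrom, source, g$start + 1, g$start + g$exon_bp,
                       g$strand, g$gene_id, g$gene_id), con)
  }
  invisible(path)
}

#' Merge overlapping intervals
#'
#' Collapses a peak set to the minimal set of disjoint intervals covering
#' the same bases. Intervals sharing at least one base are merged; adjacent
#' half-open intervals (`[a,b)`, `[b,c)`) share no base and stay separate.
#' Scores of merged constituents are summed.
#'
#' @param ps a [peak_set()].
#' @return A [peak_set()] of disjoint intervals.
#' @export
merge_intervals <- function(ps) {
  if (!nrow(ps)) return(ps)
  gr <- .ps_granges(ps)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  ov <- GenomicRanges::findOverlaps(gr, red, minoverlap = 1L)
  sc <- tapply(ps$score[S4Vectors::queryHits(ov)], S4Vectors::subjectHits(ov), sum)
  score <- numeric(length(red)); score[as.integer(names(sc))] <- sc
  peak_set(as.character(GenomicRanges::seqnames(red)),
           GenomicRanges::start(red) - 1, GenomicRanges::end(red),
           score = score,
           factor = attr(ps, "factor"), replicate = attr(ps, "replicate"))
}

#' Any-overlap test between two peak sets
#'
#' @param a,b [peak_set()] objects.
#' @return Logical vector along `a`: `TRUE` where the interval shares at
#'   least one base with any interval of `b`.
#' @export
overlap_any <- function(a, b) {
  if (!nrow(a)) return(logical(0))
  if (!nrow(b)) return(rep(FALSE, nrow(a)))
  # sets on disjoint chromosomes are a legitimate comparison, not a warning
  suppressWarnings(
    GenomicRanges::countOverlaps(.ps_granges(a), .ps_granges(b),
                                 minoverlap = 1L) > 0)
}

#' Assign each peak to its nearest gene
#'
#' Distance is measured from the peak centre, `floor((start + end) / 2)`, to
#' the strand-aware TSS; strand is ignored for the distance itself. Ties are
#' broken toward the lexicographically smaller `gene_id`. Peaks on
#' chromosomes with no annotated gene map to `NA`.
#'
#' @param peaks a [peak_set()].
#' @param ann a [gene_annotation()].
#' @return Data frame with one row per peak: `name`, `gene_id`, `distance`.
#' @export
nearest_gene <- function(peaks, ann) {
  centre <- floor((peaks$start + peaks$end) / 2)
  out <- data.frame(name = peaks$name, gene_id = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  for (ch in unique(peaks$chrom)) {
    gi <- which(ann$chrom == ch)
    pi <- which(peaks$chrom == ch)
    if (!length(gi)) next
    # order genes by TSS, then gene_id so ties resolve lexicographically
    gi <- gi[order(ann$tss[gi], ann$gene_id[gi])]
    tss <- ann$tss[gi]
    ids <- ann$gene_id[gi]
    for (p in pi) {
      d <- abs(tss - centre[p])
      best <- which(d == min(d))
      k <- best[order(ids[best])][1]
      out$gene_id[p] <- ids[k]
      out$distance[p] <- d[k]
    }
  }
  out
}

#' Peaks lost between conditions
#'
#' The subset of `wt` intervals with no base-pair overlap in `ko` — the unit
#' of recruitment-dependency analyses (e.g. Mbd3 peaks lost in knockout
#' cells).
#'
#' @param wt,ko [peak_set()] objects.
#' @return A [peak_set()]: rows of `wt` absent from `ko`.
#' @export
peaks_lost <- function(wt, ko) {
  if (!nrow(wt)) return(wt)
  keep <- !overlap_any(wt, ko)
  out <- wt[keep, , drop = FALSE]
  structure(out, factor = attr(wt, "factor"), replicate = attr(wt, "replicate"),
            class = c("peak_set", "data.frame"))
}

#' Three-way Venn region cardinalities
#'
#' @param a,b,c vectors of labels (coerced to sets).
#' @return Named integer vector of the 7 disjoint region sizes:
#'   `a_only`, `b_only`, `c_only`, `ab_only`, `ac_only`, `bc_only`, `abc`.
#'   The counts sum to `|a U b U c|`.
#' @export
venn3 <- function(a, b, c) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  u <- unique(c(a, b, c))
  ina <- u %in% a; inb <- u %in% b; inc <- u %in% c
  c(a_only  = sum(ina & !inb & !inc),
    b_only  = sum(!ina & inb & !inc),
    c_only  = sum(!ina & !inb & inc),
    ab_only = sum(ina & inb & !inc),
    ac_only = sum(ina & !inb & inc),
    bc_only = sum(!ina & inb & inc),
    abc     = sum(ina & inb & inc))
}
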