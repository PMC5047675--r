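# Quadratic / per-base reference implementations used as independent
# oracles for the interval algebra, plus small fixture builders.

random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                         max_len = 300) {
  start <- sample.int(max_pos, n, replace = TRUE)
  peak_set(sample(chroms, n, replace = TRUE), start,
           start + sample.int(max_len, n, replace = TRUE),
           score = stats::runif(n, 0, 10))
}

# per-base union tally
oracle_union_bases <- function(ps) {
  sum(vapply(unique(ps$chrom), function(ch) {
    sub <- ps[ps$chrom == ch, ]
    covered <- logical(max(sub$end))
    for (i in seq_len(nrow(sub)))
      covered[(sub$start[i] + 1):sub$end[i]] <- TRUE
    sum(covered)
  }, numeric(1)))
}

# all-pairs overlap test
oracle_overlap_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & a$start[i] < b$end)
  }, logical(1))
}

# exhaustive nearest-TSS search with lexicographic tie-break
oracle_nearest <- function(peaks, ann) {
  vapply(seq_len(nrow(peaks)), function(i) {
    centre <- floor((peaks$start[i] + peaks$end[i]) / 2)
    g <- ann[ann$chrom == peaks$chrom[i], ]
    if (!nrow(g)) return(NA_character_)
    d <- abs(g$tss - centre)
    cand <- g$gene_id[d == min(d)]
    sort(cand)[1]
  }, character(1))
}

# membership-table venn
oracle_venn3 <- function(a, b, c) {
  u <- unique(c(a, b, c))
  m <- cbind(u %in% a, u %in% b, u %in% c)
  key <- m %*% c(1, 2, 4)
  cnt <- function(k) sum(key == k)
  c(a_only = cnt(1), b_only = cnt(2), c_only = cnt(4), ab_only = cnt(3),
    ac_only = cnt(5), bc_only = cnt(6), abc = cnt(7))
}

# tiny annotation on two chromosomes
toy_annotation <- function() {
  gene_annotation(data.frame(
    gene_id = c("gA", "gB", "gC", "gD"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(1000, 6000, 12000, 2000),
    end = c(3000, 9000, 14000, 5000),
    strand = c("+", "-", "+", "-"),
    exon_bp = c(1500, 2000, 1000, 2500)))
}

# flat track fixture
flat_track <- function(value = 5, n_bins = 400, bw = 50,
                       chroms = c("chr1", "chr2")) {
  signal_track(stats::setNames(
    lapply(chroms, function(ch) rep(value, n_bins)), chroms), bw)
}

# paired peaks drawn straight from the IDR mixture model
model_pairs <- function(n, pi1, mu = 2, rho = 0.8, seed = 1) {
  set.seed(seed)
  lab <- stats::runif(n) < pi1
  z1 <- ifelse(lab, mu + stats::rnorm(n), stats::rnorm(n))
  z2 <- ifelse(lab, mu + rho * (z1 - mu) + sqrt(1 - rho^2) * stats::rnorm(n),
               stats::rnorm(n))
  structure(list(pairs = data.frame(
    chrom = "chr1", start1 = seq_len(n) * 1000,
    end1 = seq_len(n) * 1000 + 400, start2 = seq_len(n) * 1000,
    end2 = seq_len(n) * 1000 + 400, score1 = exp(z1), score2 = exp(z2),
    name1 = sprintf("p%d", seq_len(n)), name2 = sprintf("q%d", seq_len(n)),
    stringsAsFactors = FALSE),
    unpaired = list(rep1 = peak_set("chr1", 1, 2)[0, ],
                    rep2 = peak_set("chr1", 1, 2)[0, ])),
    class = "paired_peaks") -> pp
  attr(pp, "labels") <- lab
  pp
}

# fabricate a de_result from known per-gene values
fake_de <- function(genes, log2fc, fdr, alpha = 0.05) {
  structure(data.frame(gene = genes, mean_expr = 100, log2fc = log2fc,
                       pvalue = fdr, fdr = fdr, dispersion = 0.05,
                       stringsAsFactors = FALSE),
            size_factors = NULL, contrast = c("A", "B"), alpha_fdr = alpha,
            class = c("de_result", "data.frame"))
}

de_design <- function(n_per = 3) {
  data.frame(sample = sprintf("s%d", seq_len(2 * n_per)),
             condition = rep(c("WT", "KO"), each = n_per))
}
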