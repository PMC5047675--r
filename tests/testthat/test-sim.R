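test_that("sim_config validates probabilities and complex parameters", {
  expect_error(sim_config(pi1 = 1.5), "probabilities")
  expect_error(sim_config(chrom_length = 0), "chrom_length")
  expect_error(sim_config(complex_spec = list(copies = c(Sall4 = 1, Mbd3 = 1),
                                              bait = "Sall4",
                                              anchors = "Mbd3", S = 0.5)),
               "S must be >= 1")
  expect_error(sim_config(factors = character(0)), "non-empty")
})

test_that("make_genome is deterministic with forced cardinality and errors", {
  cfg <- sim_config(seed = 7, n_genes = 200)
  ann <- make_genome(cfg)
  expect_equal(nrow(ann), 200)
  expect_equal(length(unique(ann$gene_id)), 200)
  expect_true(all(ann$tss >= ann$start & ann$tss < ann$end))
  # genes never overlap within a chromosome
  for (ch in unique(ann$chrom)) {
    sub <- ann[ann$chrom == ch, ]
    expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
  }
  ann2 <- make_genome(cfg)
  expect_identical(as.data.frame(ann), as.data.frame(ann2))
  expect_identical(attr(ann, "enhancers"), attr(ann2, "enhancers"))
  expect_error(make_genome(sim_config(n_genes = 2000, chrom_length = 1e6)),
               "too small")
})

test_that("peak replicates carry the planted reproducible fraction", {
  cfg <- sim_config(seed = 3, pi1 = 0.7, n_peaks = 1000, factors = "Sall4")
  ann <- make_genome(cfg)
  pk <- simulate_peak_replicates(ann, cfg)
  frac <- mean(pk$Sall4$truth$reproducible)
  # binomial 99% CI around 0.7 at n = 1000
  expect_lt(abs(frac - 0.7), 2.58 * sqrt(0.7 * 0.3 / 1000))
  # pi1 = 1: every replicate-1 peak has an overlapping replicate-2 peak
  cfg1 <- sim_config(seed = 3, pi1 = 1, n_peaks = 300, factors = "Sall4")
  pk1 <- simulate_peak_replicates(make_genome(cfg1), cfg1)
  expect_true(all(overlap_any(pk1$Sall4$rep1, pk1$Sall4$rep2)))
  # full co-occupancy forces identical loci
  cooc <- matrix(1, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  cfg2 <- sim_config(seed = 5, factors = c("A", "B"), cooccupancy = cooc,
                     n_peaks = 200)
  pk2 <- simulate_peak_replicates(make_genome(cfg2), cfg2)
  expect_setequal(pk2$A$truth$centre, pk2$B$truth$centre)
  expect_error(simulate_peak_replicates(ann, sim_config(pi1 = 0)), "pi1")
})

test_that("signal tracks show background rate and planted mark enrichment", {
  cfg <- sim_config(seed = 9)
  ann <- make_genome(cfg)
  # zero enrichment multiplier: pure Poisson background
  cfg0 <- sim_config(seed = 9, enrichment = 1, marks = "H3K4me3")
  tr0 <- simulate_signal(ann, config = cfg0)
  v <- unlist(tr0$H3K4me3$signal)
  se <- sqrt(cfg$background_rate / length(v))
  expect_lt(abs(mean(v) - cfg$background_rate), 3 * se)
  # promoter windows enriched for H3K4me3 over random background windows
  tr <- simulate_signal(ann, config = cfg)
  prom <- peak_set(ann$chrom, pmax(ann$tss - 250, 0), ann$tss + 250)
  enr <- score_against_track(prom, tr$H3K4me3)
  expect_gt(mean(enr), 4)  # planted 8x, strictly above background
  expect_error(simulate_signal(ann, config = sim_config(marks = "H3K9me3")),
               "unknown mark")
  # determinism
  tr2 <- simulate_signal(ann, config = cfg)
  expect_identical(tr$H3K4me1$signal, tr2$H3K4me1$signal)
})

test_that("simulated counts recover planted fold changes and the Poisson limit", {
  design <- de_design()
  cfg0 <- sim_config(seed = 2, n_genes = 100, planted_lfc = list(KO = numeric(0)))
  ann <- make_genome(cfg0)
  cm0 <- simulate_counts(ann, design, cfg0)
  expect_true(all(attr(cm0, "truth")$true_lfc == 0))
  expect_error(simulate_counts(ann, design, sim_config(planted_lfc = list())),
               "absent from planted_lfc")
  expect_error(simulate_counts(ann, design[c(1, 4), ],
                               sim_config(planted_lfc = list(KO = numeric(0)))),
               ">= 2 samples")
  # planted lfc = 2 at high means: empirical log2 ratio within +/- 0.5
  genes <- ann$gene_id[1:50]
  cfg <- sim_config(seed = 2, n_genes = 100, mean_log = 6, mean_sdlog = 0.3,
                    planted_lfc = list(KO = stats::setNames(rep(2, 50), genes)))
  cm <- simulate_counts(ann, design, cfg)
  is_ko <- cm$design$condition == "KO"
  sf <- attr(cm, "truth")$size_factors
  norm <- sweep(cm$counts, 2, sf, "/")
  ratio <- log2(rowMeans(norm[genes, is_ko]) / rowMeans(norm[genes, !is_ko]))
  expect_lt(abs(mean(ratio) - 2), 0.5)
  # dispersion -> 0 at large mean: variance/mean ratio approaches 1
  cfgp <- sim_config(seed = 4, n_genes = 100, nb_dispersion = 0,
                     mean_log = 7, mean_sdlog = 0.1, libsize_sdlog = 0,
                     planted_lfc = list(KO = numeric(0)))
  cmp <- simulate_counts(ann, design, cfgp)
  vm <- apply(cmp$counts, 1, stats::var) / rowMeans(cmp$counts)
  expect_lt(abs(mean(vm) - 1), 0.5)
})

test_that("LFQ tables encode the complex composition with bait excess", {
  # noiseless, no background, no censoring: ratios recovered exactly
  cfg <- sim_config(seed = 1, noise_cv = 0, censor_q = 0, n_background = 0)
  lfq <- simulate_lfq(cfg)
  st <- stoichiometry(lfq, anchor_proteins = c("Mbd2", "Mbd3"), bait = "Sall4")
  copies <- cfg$complex_spec$copies
  non_bait <- setdiff(names(copies), "Sall4")
  expect_equal(st$ratio_to_anchor[match(non_bait, st$protein)],
               unname(copies[non_bait]), tolerance = 1e-12)
  expect_equal(attr(st, "S_bait"), 14, tolerance = 1e-12)
  # bait:anchor ratio recovered within 20% under noise
  lfq2 <- simulate_lfq(sim_config(seed = 11, noise_cv = 0.2))
  st2 <- stoichiometry(lfq2, anchor_proteins = c("Mbd2", "Mbd3"),
                       bait = "Sall4")
  expect_lt(abs(attr(st2, "S_bait") - 14) / 14, 0.2)
  # censoring strikes only the low end: compare against the uncensored twin
  lfq3 <- simulate_lfq(sim_config(seed = 5))
  full <- simulate_lfq(sim_config(seed = 5, censor_q = 0))
  X <- lfq3$intensities; X0 <- full$intensities
  for (j in seq_len(ncol(X))) {
    censored <- is.na(X[, j]) & !is.na(X0[, j])
    if (any(censored)) {
      lo <- stats::quantile(X0[!is.na(X0[, j]), j], 0.15)
      hi <- stats::quantile(X0[!is.na(X0[, j]), j], 0.75)
      expect_true(all(X0[censored, j] <= lo + 1e-9))
      expect_true(all(is.na(X[!is.na(X0[, j]) & X0[, j] >= hi, j]) == FALSE))
    }
  }
  expect_error(simulate_lfq(sim_config(
    complex_spec = list(copies = c(A = 1), bait = "B", anchors = "A", S = 2))),
    "bait")
})

test_that("Ct matrices carry two separable populations and honest dropouts", {
  cfg0 <- sim_config(seed = 4, dropout_p = 0)
  ct0 <- simulate_ct(cfg0)
  expect_false(anyNA(ct0$ct))
  # 2-means on -dCt recovers >= 95% of latent labels
  nd <- delta_ct_normalize(ct0)
  km <- stats::kmeans(t(nd), 2, nstart = 10)
  lab <- attr(ct0, "truth")$population
  acc <- max(mean(km$cluster == lab), mean(km$cluster == 3 - lab))
  expect_gte(acc, 0.95)
  # determinism
  ct0b <- simulate_ct(cfg0)
  expect_identical(ct0$ct, ct0b$ct)
  expect_error(simulate_ct(sim_config(housekeeping = "Gapdh")),
               "housekeeping")
})

test_that("generators never disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  cfg <- sim_config(seed = 1, n_genes = 20, n_enhancers = 10, n_peaks = 50)
  invisible(make_genome(cfg))
  expect_identical(.Random.seed, before)
})
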