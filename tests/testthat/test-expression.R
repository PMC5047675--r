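toy_counts <- function(counts, lengths = NULL, conds = NULL) {
  n <- ncol(counts)
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("s%d", seq_len(n))
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("g%d", seq_len(nrow(counts)))
  if (is.null(lengths)) lengths <- stats::setNames(rep(1000, nrow(counts)),
                                                   rownames(counts))
  if (is.null(conds)) conds <- rep(c("WT", "KO"), length.out = n)
  count_matrix(counts, lengths,
               data.frame(sample = colnames(counts), condition = conds))
}

test_that("fpkm matches the closed form and its scale properties", {
  # 1000 counts on a 1 kb gene in a 10M-read sample -> FPKM 100
  m <- toy_counts(matrix(c(1000, 1000, 9999000, 9999000), 2, 2, byrow = TRUE),
                  lengths = c(g1 = 1000, g2 = 999900))
  expect_equal(fpkm(m)["g1", 1], 100, ignore_attr = TRUE)
  # doubling all counts of one sample leaves its FPKM unchanged
  m2 <- toy_counts(cbind(m$counts[, 1], m$counts[, 1] * 2),
                   lengths = c(g1 = 1000, g2 = 999900))
  f2 <- fpkm(m2)
  expect_equal(f2[, 1], f2[, 2])
  # zero counts give FPKM zero
  expect_equal(unname(fpkm(toy_counts(matrix(c(0, 5, 0, 7), 2)))[1, ]),
               c(0, 0))
})

test_that("size factors follow median-of-ratios with its forced cases", {
  x <- matrix(rpois(600, 50) + 1, 100, 6)
  same <- toy_counts(cbind(x[, 1], x[, 1], x[, 1]), conds = rep("A", 3))
  expect_equal(unname(size_factors(same)), rep(1, 3))
  tripled <- toy_counts(cbind(x[, 1], x[, 1] * 3), conds = c("A", "A"))
  s <- size_factors(tripled)
  expect_equal(unname(s[2] / s[1]), 3)
  # independent recomputation on a random NB matrix
  set.seed(61)
  y <- matrix(rnbinom(1200, mu = 100, size = 10) + 1, 200, 6)
  m <- toy_counts(y)
  geo <- exp(rowMeans(log(y)))
  raw <- apply(y, 2, function(col) exp(median(log(col / geo))))
  expect_equal(unname(size_factors(m)), unname(raw / median(raw)),
               tolerance = 1e-10)
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(62)
  y <- matrix(rnbinom(1200, mu = 80, size = 5) + 1, 200, 6)
  ours <- size_factors(toy_counts(y))
  ref <- DESeq2::estimateSizeFactorsForMatrix(y)
  # both use median-of-ratios; scales differ by a constant
  expect_equal(unname(ours / ours[1]), unname(ref / ref[1]),
               tolerance = 1e-10)
})

test_that("de_test flags planted effects, keeps nulls quiet, needs replicates", {
  design <- de_design()
  cfg0 <- sim_config(seed = 71, n_genes = 300, chrom_length = 4e6,
                     n_enhancers = 30, planted_lfc = list(KO = numeric(0)))
  ann <- make_genome(cfg0)
  genes <- ann$gene_id[1:30]
  cfg <- sim_config(seed = 71, n_genes = 300, chrom_length = 4e6,
                    n_enhancers = 30, mean_log = 5.5, mean_sdlog = 0.5,
                    planted_lfc = list(KO = stats::setNames(rep(c(2, -2), 15),
                                                            genes)))
  de <- de_test(simulate_counts(ann, design, cfg), c("WT", "KO"))
  expect_s3_class(de, "de_result")
  # BH property: fdr is non-decreasing along the p-value ranking
  ord <- order(de$pvalue)
  expect_true(all(diff(cummax(de$fdr[ord])) >= 0))
  expect_true(all(de$fdr >= de$pvalue))
  hits <- de_genes(de)
  expect_gte(mean(genes %in% hits), 0.8)
  # sign of log2fc matches the planted direction for detected genes
  det <- intersect(genes, hits)
  planted_sign <- sign(cfg$planted_lfc$KO[det])
  expect_equal(unname(sign(de$log2fc[match(det, de$gene)])),
               unname(planted_sign))
  # a gene with identical counts in every sample is a clean null
  flat <- toy_counts(matrix(c(rep(50, 6), rep(120, 6)), 2, 6, byrow = TRUE),
                     conds = design$condition)
  de_flat <- de_test(flat, c("WT", "KO"))
  expect_equal(de_flat$log2fc[1], 0)
  expect_gte(de_flat$pvalue[1], 0.5)
  single <- toy_counts(matrix(rpois(30, 50), 10, 3),
                       conds = c("WT", "WT", "KO"))
  expect_error(de_test(single, c("WT", "KO")), "replicates")
})

test_that("PCA embedding separates planted transcriptome clusters", {
  design <- de_design()
  cfg <- sim_config(seed = 81, n_genes = 300, chrom_length = 4e6,
                    n_enhancers = 30)
  ann <- make_genome(cfg)
  cfg <- sim_config(seed = 81, n_genes = 300, chrom_length = 4e6,
                    n_enhancers = 30,
                    planted_lfc = list(KO = stats::setNames(
                      rep(3, 60), ann$gene_id[1:60])))
  cm <- simulate_counts(ann, design, cfg)
  p <- pca_embed(cm, 100)
  d <- as.matrix(dist(p$coords))
  within <- c(d[1, 2], d[1, 3], d[2, 3], d[4, 5], d[4, 6], d[5, 6])
  between <- as.numeric(d[1:3, 4:6])
  expect_gte(mean(outer(between, within, ">")), 0.9)
  # variance explained is a non-increasing sub-unit partition
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1 + 1e-12)
  # duplicated sample lands on identical coordinates
  cm2 <- cm
  cm2$counts <- cbind(cm$counts, dup = cm$counts[, 1])
  cm2$design <- rbind(cm$design, data.frame(sample = "dup", condition = "WT"))
  p2 <- pca_embed(cm2, 100)
  expect_equal(p2$coords["dup", ], p2$coords[1, ], ignore_attr = TRUE)
  expect_warning(pca_embed(cm, 1e5), "fewer genes")
})

test_that("-dCt normalisation matches its definition and keeps NAs", {
  ct <- matrix(c(20, 18, NA,
                 18, 18, 18,
                 18, 18, 18), 3, byrow = TRUE,
               dimnames = list(c("Nanog", "Atp5a1", "Ppia"),
                               c("c1", "c2", "c3")))
  cm <- ct_matrix(ct, housekeeping = c("Atp5a1", "Ppia"))
  nd <- delta_ct_normalize(cm)
  expect_equal(nd["Nanog", "c1"], -2)   # 2 cycles above housekeeping
  expect_equal(nd["Nanog", "c2"], 0)
  expect_true(is.na(nd["Nanog", "c3"]))
  # a gene 3 cycles below the housekeeping mean scores +3
  ct2 <- rbind(ct, Sox2 = c(15, 15, 15))
  nd2 <- delta_ct_normalize(ct_matrix(ct2, c("Atp5a1", "Ppia")))
  expect_equal(unname(nd2["Sox2", ]), c(3, 3, 3))
  # cells without any housekeeping measurement are dropped with a warning
  ct3 <- ct
  ct3[c("Atp5a1", "Ppia"), "c3"] <- NA
  expect_warning(nd3 <- delta_ct_normalize(ct_matrix(ct3, c("Atp5a1", "Ppia"))),
                 "dropped")
  expect_equal(ncol(nd3), 2)
  expect_error(ct_matrix(ct, housekeeping = character(0)), "non-empty")
})

test_that("hierarchical clustering recovers the planted cell populations", {
  cfg <- sim_config(seed = 91, dropout_p = 0.05)
  ctm <- simulate_ct(cfg)
  nd <- delta_ct_normalize(ctm)
  hc <- hcluster_genes_cells(nd)
  lab <- attr(ctm, "truth")$population[hc$col_order]
  # contiguity: cutting the leaf order at the population boundary
  n1 <- sum(lab == 1)
  block_acc <- max(mean(lab[1:n1] == 1), mean(lab[1:n1] == 2))
  expect_gte(block_acc, 0.9)
  # identical rows cluster adjacent
  x <- matrix(rnorm(40), 4, 10)
  x <- rbind(x, x[2, , drop = FALSE])
  hc2 <- hcluster_genes_cells(x)
  pos <- match(c(2, 5), hc2$row_order)
  expect_equal(abs(diff(pos)), 1)
  # leaf order stable under input permutation, up to reflection
  perm <- sample(ncol(nd))
  hc3 <- hcluster_genes_cells(nd[, perm])
  reordered <- perm[hc3$col_order]
  expect_true(identical(reordered, hc$col_order) ||
                identical(rev(reordered), hc$col_order) ||
                # allow tie-driven local swaps: same population blocks
                mean(attr(ctm, "truth")$population[reordered] ==
                       attr(ctm, "truth")$population[hc$col_order]) > 0.9)
})

test_that("relative expression follows 2^-ddCt", {
  expect_equal(relative_expression(20, 20, 18, 18), 1)
  # two cycles earlier than control after housekeeping correction: fold 4
  expect_equal(relative_expression(18, 20, 18, 18), 4)
  expect_true(is.na(relative_expression(NA, 20, 18, 18)))
  set.seed(101)
  ct_t <- runif(50, 18, 30); ct_c <- runif(50, 18, 30)
  hk_t <- runif(50, 17, 19); hk_c <- runif(50, 17, 19)
  expect_equal(relative_expression(ct_t, ct_c, hk_t, hk_c),
               2^(-((ct_t - hk_t) - (ct_c - hk_c))))
})
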