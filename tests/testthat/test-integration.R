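test_that("peak_gene_set deduplicates nearest-gene assignments", {
  ann <- toy_annotation()
  two_on_one <- peak_set("chr1", c(900, 1100), c(1000, 1300))
  expect_equal(peak_gene_set(two_on_one, ann), "gA")
  expect_equal(peak_gene_set(two_on_one[0, ], ann), character(0))
  set.seed(111)
  pk <- random_peaks(100, max_pos = 14000)
  expect_setequal(peak_gene_set(pk, ann),
                  unique(oracle_nearest(pk, ann)[!is.na(oracle_nearest(pk, ann))]))
})

test_that("overlap_report counts, rounds and splits direction like the worked examples", {
  a <- sprintf("g%d", 1:40)
  expect_equal(overlap_report(a, a)$percentage, 100L)
  # the published dependency-analysis arithmetic: 1073 of 4422 is 24%
  big_a <- sprintf("g%05d", 1:4422)
  big_b <- c(sprintf("g%05d", 1:1073), sprintf("x%d", 1:500))
  rep1 <- overlap_report(big_a, big_b)
  expect_equal(rep1$n_intersect, 1073L)
  expect_equal(rep1$percentage, 24L)
  # and the bound-gene arithmetic: 315 of 1527 is 21% by our rounding
  rep2 <- overlap_report(sprintf("g%d", 1:1527), sprintf("g%d", 1:315))
  expect_equal(rep2$percentage, as.integer(round(100 * 315 / 1527)))
  expect_true(is.na(overlap_report(character(0), a)$percentage))
  # direction split via an attached DE result
  de <- fake_de(sprintf("g%d", 1:10), log2fc = rep(c(2, -1), 5),
                fdr = c(rep(0.01, 6), rep(0.5, 4)))
  r <- overlap_report(sprintf("g%d", 1:8), sprintf("g%d", 5:10), de)
  # intersection g5..g8; DE-passing among them: g5, g6 (one up, one down)
  expect_equal(r$up, 1)
  expect_equal(r$down, 1)
  # enumeration oracle on random sets
  set.seed(121)
  for (rep in 1:5) {
    x <- sample(sprintf("m%d", 1:200), 80)
    y <- sample(sprintf("m%d", 1:200), 120)
    r <- overlap_report(x, y)
    expect_equal(r$n_intersect, sum(x %in% y))
    expect_equal(r$percentage, as.integer(round(100 * sum(x %in% y) / 80)))
  }
})

test_that("direction correlation separates the null and correlated regimes", {
  genes <- sprintf("g%03d", 1:300)
  de_x <- fake_de(genes, log2fc = rnorm(300, sd = 2), fdr = 0.01)
  # identical inputs give an exact fit (lm warns about it; that is the point)
  self <- suppressWarnings(direction_correlation(de_x, de_x))
  expect_equal(self$r_squared, 1)
  # independent effects: mean R-squared near zero over 20 seeds
  r2 <- vapply(1:20, function(s) {
    set.seed(s)
    dx <- fake_de(genes, rnorm(300, sd = 2), fdr = 0.01)
    dy <- fake_de(genes, rnorm(300, sd = 2), fdr = 0.01)
    direction_correlation(dx, dy)$r_squared
  }, numeric(1))
  expect_lte(mean(r2), 0.05)
  # planted linear relation recovers high R-squared and the slope
  set.seed(9)
  fx <- rnorm(300, sd = 2)
  dy <- fake_de(genes, 0.8 * fx + rnorm(300, sd = 0.1), fdr = 0.01)
  fit <- direction_correlation(fake_de(genes, fx, fdr = 0.01), dy)
  expect_gte(fit$r_squared, 0.9)
  expect_equal(fit$slope, 0.8, tolerance = 0.05)
  # r_squared equals the squared Pearson correlation of the pairs
  expect_equal(fit$r_squared,
               cor(fit$pairs$log2fc_x, fit$pairs$log2fc_y)^2,
               tolerance = 1e-12)
  few <- fake_de(genes[1:2], c(1, 2), fdr = 0.01)
  expect_error(direction_correlation(few, few), ">= 3")
})

test_that("dependency analysis reproduces the published worked example", {
  # fixture scaled to the printed numbers: 4422 lost peaks, 1073 bound
  starts <- seq(0, by = 1000, length.out = 5000)
  wt <- peak_set("chr1", starts, starts + 400)
  ko <- wt[4423:5000, ]                         # keep 578, lose 4422
  sall4 <- wt[1:1073, ]                         # binds the first 1073 lost
  rep <- dependency_analysis(wt, ko, sall4)
  expect_equal(rep$n_lost, 4422L)
  expect_equal(rep$n_lost_bound, 1073L)
  expect_equal(rep$pct_lost_bound, 24L)
  # nothing lost: undefined percentage
  none <- dependency_analysis(wt, wt, sall4)
  expect_equal(none$n_lost, 0L)
  expect_true(is.na(none$pct_lost_bound))
  # random fixtures equal the composition of the two primitive oracles
  set.seed(131)
  for (rep_i in 1:3) {
    w <- random_peaks(300); k <- random_peaks(200); s <- random_peaks(250)
    got <- dependency_analysis(w, k, s)
    lost_idx <- !oracle_overlap_any(w, k)
    bound <- sum(oracle_overlap_any(w[lost_idx, ], s))
    expect_equal(got$n_lost, sum(lost_idx))
    expect_equal(got$n_lost_bound, bound)
  }
})

test_that("fold_gain reports the published ratio at one decimal", {
  starts <- seq(0, by = 1000, length.out = 17739)
  a <- peak_set("chr1", starts, starts + 400)
  b <- a[1:5062, ]
  expect_equal(fold_gain(a, b), 3.5)
  expect_equal(fold_gain(a, a), 1)
  expect_equal(fold_gain(a[0, ], b), 0)
  expect_error(fold_gain(a, a[0, ]), "empty")
})

test_that("premature activation fraction matches planted shared-up fractions", {
  genes <- sprintf("g%03d", 1:500)
  de_same <- fake_de(genes, log2fc = rep(1, 500), fdr = 0.01)
  expect_equal(premature_activation_fraction(de_same, de_same), 100L)
  de_down <- fake_de(genes, log2fc = rep(-1, 500), fdr = 0.01)
  expect_equal(premature_activation_fraction(de_same, de_down), 0L)
  # planted 40% shared-up fixture
  up_wt <- genes[1:200]
  up_mut <- c(genes[1:80], genes[301:400])   # 80 of the 200 -> 40%
  de_wt <- fake_de(genes, ifelse(genes %in% up_wt, 2, -2), fdr = 0.01)
  de_mut <- fake_de(genes, ifelse(genes %in% up_mut, 2, -2), fdr = 0.01)
  expect_equal(premature_activation_fraction(de_wt, de_mut), 40L)
  expect_true(is.na(premature_activation_fraction(de_down, de_same)))
})

test_that("full pipeline reports are reproducible from a fixed seed", {
  run_once <- function() {
    cfg <- sim_config(seed = 19, n_peaks = 300, n_genes = 100)
    ann <- make_genome(cfg)
    pk <- simulate_peak_replicates(ann, cfg)
    sall4 <- merge_replicates(pk$Sall4$rep1, pk$Sall4$rep2)
    mbd3 <- merge_replicates(pk$Mbd3$rep1, pk$Mbd3$rep2)
    list(genes = peak_gene_set(sall4, ann),
         rep = overlap_report(peak_gene_set(sall4, ann),
                              peak_gene_set(mbd3, ann)))
  }
  a <- run_once(); b <- run_once()
  expect_identical(a, b)
})
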