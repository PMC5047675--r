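#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators in one validated
#' object. Defaults describe a compact two-chromosome genome with a
#' realistic mouse-ESC-like regulatory layout: genes with strand-aware TSS,
#' intergenic/intragenic enhancer loci (half active), two ChIP'd factors with
#' configurable co-occupancy, histone-mark tracks enriched by peak class,
#' negative-binomial RNA-seq counts with planted fold changes, an AP-MS
#' experiment built from a known complex composition with the bait in molar
#' excess, and bimodal single-cell qPCR Ct tables.
#'
#' @param seed integer seed; every generator is a pure function of its
#'   config including this seed.
#' @param n_chrom,chrom_length genome shape (bp per chromosome).
#' @param n_genes,gene_length gene count and min/max gene length (bp).
#' @param n_enhancers,enhancer_width,active_frac enhancer loci: count, width
#'   and the fraction flagged transcriptionally active (H3K27ac-positive).
#' @param factors character vector of ChIP'd factor names; the first is the
#'   reference for co-occupancy.
#' @param cooccupancy square matrix (factors x factors) of co-occupancy
#'   probabilities in `[0,1]`; entry `[f, 1]` is the fraction of factor `f`
#'   loci shared with the reference factor.
#' @param n_peaks latent true peaks per factor.
#' @param peak_width peak interval width (bp).
#' @param pi1 fraction of latent peak pairs that are truly reproducible.
#' @param repro_shift,repro_rho log-score mean shift and correlation of the
#'   reproducible component (background scores are standard log-normal).
#' @param n_unpaired extra per-replicate-only noise peaks (default 0).
#' @param bin_width,background_rate,enrichment signal tracks: bin size (bp),
#'   Poisson background rate per bin, and the fold enrichment multiplier at
#'   marked loci.
#' @param marks histone-mark/cofactor tracks to simulate.
#' @param nb_dispersion NB overdispersion `phi` (`var = mu + phi mu^2`),
#'   scalar or per-gene.
#' @param mean_log,mean_sdlog log-normal parameters of baseline gene means.
#' @param libsize_sdlog spread of per-sample library-size factors.
#' @param planted_lfc named list: condition -> named vector gene_id -> log2
#'   fold change versus the reference (first) condition.
#' @param complex_spec list with `copies` (named vector, copies of each
#'   subunit per complex), `bait`, `anchors` (subunits sharing the anchor
#'   slot) and `S` (bait molar excess over complexes, >= 1).
#' @param n_background,noise_cv,censor_q,n_rep AP-MS: background binders,
#'   log-normal noise CV, left-censoring quantile for missing-at-low-
#'   abundance, and IP/control replicates per group.
#' @param ct_markers list of marker panels (two populations differ on
#'   them); `housekeeping` names the reference genes; `n_cells` per
#'   population; `ct_sep` the between-population Ct shift; `ct_noise`,
#'   `cell_offset_sd` technical spreads; `dropout_p` missingness.
#' @param housekeeping,n_cells,ct_sep,ct_noise,cell_offset_sd,dropout_p see
#'   `ct_markers`.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L, chrom_length = 1e6,
                       n_genes = 200L, gene_length = c(2000, 8000),
                       n_enhancers = 150L, enhancer_width = 500L,
                       active_frac = 0.5,
                       factors = c("Sall4", "Mbd3"),
                       cooccupancy = NULL,
                       n_peaks = 1000L, peak_width = 400L,
                       pi1 = 0.7, repro_shift = 2, repro_rho = 0.8,
                       n_unpaired = 0L,
                       bin_width = 50L, background_rate = 5,
                       enrichment = 8,
                       marks = c("H3K4me3", "H3K4me1", "H3K27ac", "Ep300"),
                       nb_dispersion = 0.05,
                       mean_log = 4, mean_sdlog = 1.5, libsize_sdlog = 0.15,
                       planted_lfc = list(),
                       complex_spec = list(
                         copies = c(Chd4 = 1, Hdac1 = 1, Hdac2 = 1,
                                    Mta1 = 0.7, Mta2 = 0.9, Mta3 = 0.4,
                                    Mbd2 = 0.4, Mbd3 = 0.6,
                                    Gatad2a = 1, Gatad2b = 1,
                                    Rbbp4 = 2, Rbbp7 = 1, Cdk2ap1 = 0.5,
                                    Sall4 = 1),
                         bait = "Sall4", anchors = c("Mbd2", "Mbd3"),
                         S = 14),
                       n_background = 100L, noise_cv = 0.2,
                       censor_q = 0.15, n_rep = 3L,
                       ct_markers = list(
                         pluripotency = c("Pou5f1", "Nanog", "Sox2",
                                          "Esrrb", "Klf4"),
                         neural = c("Pax6", "Sox1", "Nes", "Tubb3")),
                       housekeeping = c("Atp5a1", "Ppia", "Gapdh"),
                       n_cells = c(40L, 35L), ct_sep = 6,
                       ct_noise = 0.3, cell_offset_sd = 0.5,
                       dropout_p = 0.1) {
  if (is.null(cooccupancy)) {
    k <- length(factors)
    cooccupancy <- matrix(0.5, k, k, dimnames = list(factors, factors))
    diag(cooccupancy) <- 1
  }
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_length = chrom_length, n_genes = as.integer(n_genes),
              gene_length = gene_length, n_enhancers = as.integer(n_enhancers),
              enhancer_width = as.integer(enhancer_width),
              active_frac = active_frac, factors = factors,
              cooccupancy = cooccupancy, n_peaks = as.integer(n_peaks),
              peak_width = as.integer(peak_width), pi1 = pi1,
              repro_shift = repro_shift, repro_rho = repro_rho,
              n_unpaired = as.integer(n_unpaired),
              bin_width = as.integer(bin_width),
              background_rate = background_rate, enrichment = enrichment,
              marks = marks, nb_dispersion = nb_dispersion,
              mean_log = mean_log, mean_sdlog = mean_sdlog,
              libsize_sdlog = libsize_sdlog, planted_lfc = planted_lfc,
              complex_spec = complex_spec,
              n_background = as.integer(n_background), noise_cv = noise_cv,
              censor_q = censor_q, n_rep = as.integer(n_rep),
              ct_markers = ct_markers, housekeeping = housekeeping,
              n_cells = as.integer(n_cells), ct_sep = ct_sep,
              ct_noise = ct_noise, cell_offset_sd = cell_offset_sd,
              dropout_p = dropout_p)
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_sim_config <- function(cfg) {
  if (cfg$chrom_length <= 0) stop("chrom_length must be > 0")
  probs <- c(cfg$pi1, cfg$active_frac, cfg$dropout_p, cfg$censor_q,
             as.vector(cfg$cooccupancy))
  if (any(probs < 0 | probs > 1))
    stop("all probabilities (pi1, active_frac, dropout_p, censor_q, ",
         "co-occupancy) must lie in [0, 1]")
  if (cfg$repro_rho < 0 || cfg$repro_rho >= 1)
    stop("repro_rho must lie in [0, 1)")
  if (!is.null(cfg$complex_spec$S) && cfg$complex_spec$S < 1)
    stop("bait excess S must be >= 1")
  if (any(cfg$nb_dispersion < 0)) stop("nb_dispersion must be >= 0")
  if (!length(cfg$factors)) stop("factor list must be non-empty")
  if (!identical(dim(cfg$cooccupancy),
                 c(length(cfg$factors), length(cfg$factors))))
    stop("cooccupancy must be a factors x factors matrix")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: seed %d | %d x %.2g bp genome, %d genes, ",
                     "%d enhancers | factors: %s | pi1 = %.2f\n"),
              x$seed, x$n_chrom, x$chrom_length, x$n_genes, x$n_enhancers,
              paste(x$factors, collapse = ", "), x$pi1))
  invisible(x)
}

#' Generate a synthetic genome annotation
#'
#' Places non-overlapping gene models on random strands and designates
#' enhancer loci (inter- and intragenic, away from promoters). Deterministic
#' under `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A [gene_annotation()] with attributes `enhancers` (data frame
#'   `chrom`, `start`, `end`, `active`) and `chrom_lengths` (named vector).
#' @export
make_genome <- function(config) {
  with_seed(config$seed, {
    chroms <- sprintf("chr%d", seq_len(config$n_chrom))
    n_per <- rep(config$n_genes %/% config$n_chrom, config$n_chrom)
    extra <- config$n_genes %% config$n_chrom
    if (extra) n_per[seq_len(extra)] <- n_per[seq_len(extra)] + 1L
    genes <- NULL
    gid <- 0L
    for (ci in seq_len(config$n_chrom)) {
      n <- n_per[ci]
      if (!n) next
      len <- round(stats::runif(n, config$gene_length[1], config$gene_length[2]))
      free <- config$chrom_length - sum(len)
      if (free < 0)
        stop("genome too small: cannot place ", n, " genes of total ",
             sum(len), " bp on a ", config$chrom_length, " bp chromosome")
      gaps <- diff(c(0, sort(stats::runif(n)))) * free
      starts <- round(cumsum(gaps) + cumsum(c(0, len[-n])))
      genes <- rbind(genes, data.frame(
        gene_id = sprintf("g%04d", gid + seq_len(n)),
        chrom = chroms[ci], start = starts, end = starts + len,
        strand = sample(c("+", "-"), n, replace = TRUE),
        exon_bp = pmax(200, round(len * stats::runif(n, 0.4, 0.9))),
        stringsAsFactors = FALSE))
      gid <- gid + n
    }
    ann <- gene_annotation(genes)
    # enhancers: anywhere except promoter neighbourhoods; non-overlapping
    prom_lo <- ann$tss - 1500; prom_hi <- ann$tss + 1500
    enh <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), active = logical(0))
    tries <- 0L
    ew <- config$enhancer_width
    while (nrow(enh) < config$n_enhancers) {
      tries <- tries + 1L
      if (tries > 200L * max(1L, config$n_enhancers))
        stop("genome too small: could not place ", config$n_enhancers,
             " enhancers clear of promoters")
      ch <- sample(chroms, 1)
      s <- round(stats::runif(1, 0, config$chrom_length - ew))
      ctr <- s + ew / 2
      near_prom <- any(ann$chrom == ch & ctr >= prom_lo & ctr <= prom_hi)
      clash <- any(enh$chrom == ch & s < enh$end & enh$start < s + ew)
      if (!near_prom && !clash)
        enh <- rbind(enh, data.frame(chrom = ch, start = s, end = s + ew,
                                     active = NA))
    }
    enh <- enh[order(enh$chrom, enh$start), , drop = FALSE]
    enh$active <- stats::runif(nrow(enh)) < config$active_frac
    rownames(enh) <- NULL
    attr(ann, "enhancers") <- enh
    attr(ann, "chrom_lengths") <- stats::setNames(
      rep(config$chrom_length, config$n_chrom), chroms)
    ann
  })
}

# candidate peak loci: enhancer centres, TSS, and random filler positions
.peak_locus_pool <- function(ann, config, n_needed) {
  enh <- attr(ann, "enhancers")
  pool <- data.frame(
    chrom = c(enh$chrom, ann$chrom),
    centre = c(floor((enh$start + enh$end) / 2), ann$tss),
    stringsAsFactors = FALSE)
  n_extra <- max(0L, n_needed - nrow(pool))
  if (n_extra) {
    chroms <- names(attr(ann, "chrom_lengths"))
    pool <- rbind(pool, data.frame(
      chrom = sample(chroms, n_extra, replace = TRUE),
      centre = round(stats::runif(n_extra, config$peak_width,
                                  config$chrom_length - config$peak_width))))
  }
  pool[sample(nrow(pool)), , drop = FALSE]
}

#' Simulate replicated ChIP-seq peak sets with latent reproducibility labels
#'
#' Each factor receives a latent set of true binding loci drawn from the
#' annotation (enhancers, promoters, filler positions); factors beyond the
#' first reuse a `cooccupancy[f, 1]` fraction of the reference factor's
#' loci. Every latent locus appears in both replicates: with probability
#' `pi1` its two scores are drawn from a correlated bivariate log-normal
#' (the reproducible component), otherwise independently from the
#' background marginal. `n_unpaired` extra noise peaks per replicate have no
#' partner at all.
#'
#' @param ann a [make_genome()] annotation.
#' @param config a [sim_config()].
#' @return Named list (one entry per factor) of lists with elements `rep1`,
#'   `rep2` ([peak_set()]s) and `truth` (data frame `name`, `chrom`,
#'   `centre`, `reproducible`).
#' @export
simulate_peak_replicates <- function(ann, config) {
  if (!length(config$factors)) stop("factor list must be non-empty")
  if (config$pi1 <= 0 || config$pi1 > 1) stop("pi1 must lie in (0, 1]")
  with_seed(config$seed + 1L, {
    n <- config$n_peaks
    pool <- .peak_locus_pool(ann, config, n * (length(config$factors) + 1L))
    ref_idx <- seq_len(n)
    out <- list()
    for (fi in seq_along(config$factors)) {
      f <- config$factors[fi]
      if (fi == 1) {
        idx <- ref_idx
      } else {
        n_shared <- round(config$cooccupancy[fi, 1] * n)
        shared <- sample(ref_idx, n_shared)
        avail <- setdiff(seq_len(nrow(pool)), ref_idx)
        idx <- c(shared, sample(avail, n - n_shared))
      }
      loci <- pool[idx, , drop = FALSE]
      repro <- stats::runif(n) < config$pi1
      # reproducible: correlated bivariate normal on the log scale
      z1 <- stats::rnorm(n); e <- stats::rnorm(n)
      z2 <- config$repro_rho * z1 + sqrt(1 - config$repro_rho^2) * e
      s1 <- ifelse(repro, exp(config$repro_shift + z1), stats::rlnorm(n))
      s2 <- ifelse(repro, exp(config$repro_shift + z2), stats::rlnorm(n))
      hw <- config$peak_width / 2
      mk <- function(scores, jit) {
        ctr <- loci$centre + jit
        st <- pmax(0, round(ctr - hw))
        peak_set(loci$chrom, st, st + config$peak_width, score = scores,
                 name = sprintf("%s_locus%04d", f, seq_len(n)),
                 factor = f)
      }
      r1 <- mk(s1, round(stats::runif(n, -50, 50)))
      r2 <- mk(s2, round(stats::runif(n, -50, 50)))
      if (config$n_unpaired > 0) {
        add_noise <- function(ps, tag) {
          m <- config$n_unpaired
          ctr <- round(stats::runif(m, config$peak_width,
                                    config$chrom_length - config$peak_width))
          st <- pmax(0, ctr - hw)
          noise <- peak_set(sample(names(attr(ann, "chrom_lengths")), m,
                                   replace = TRUE),
                            st, st + config$peak_width,
                            score = stats::rlnorm(m),
                            name = sprintf("%s_noise%s_%04d", f, tag, seq_len(m)),
                            factor = f)
          ps2 <- rbind(as.data.frame(ps), as.data.frame(noise))
          peak_set(ps2$chrom, ps2$start, ps2$end, score = ps2$score,
                   name = ps2$name, factor = f)
        }
        r1 <- add_noise(r1, "a"); r2 <- add_noise(r2, "b")
      }
      attr(r1, "replicate") <- "rep1"; attr(r2, "replicate") <- "rep2"
      out[[f]] <- list(rep1 = r1, rep2 = r2,
                       truth = data.frame(
                         name = sprintf("%s_locus%04d", f, seq_len(n)),
                         chrom = loci$chrom, centre = loci$centre,
                         reproducible = repro, stringsAsFactors = FALSE))
    }
    out
  })
}

# multiply the Poisson rate once over the union of the intervals' bins
# (overlapping loci, e.g. adjacent promoter windows, do not compound)
.enrich_bins <- function(rate, chrom, start, end, bw, mult) {
  for (ch in unique(chrom)) {
    v <- rate[[ch]]
    mask <- logical(length(v))
    idx <- which(chrom == ch)
    for (i in idx) {
      lo <- max(1L, floor(start[i] / bw) + 1L)
      hi <- min(length(v), ceiling(end[i] / bw))
      if (hi >= lo) mask[lo:hi] <- TRUE
    }
    v[mask] <- v[mask] * mult
    rate[[ch]] <- v
  }
  rate
}

#' Simulate binned signal tracks for histone marks and factors
#'
#' Poisson background everywhere; promoter windows (TSS +/- 500 bp) enriched
#' `enrichment`-fold for H3K4me3; enhancer loci enriched for H3K4me1, with
#' H3K27ac (and, at half strength, Ep300) added only at loci flagged active.
#' If `peaks` is supplied, one track per factor is generated with enrichment
#' over the union of its replicate peak intervals.
#'
#' @param ann a [make_genome()] annotation.
#' @param peaks optional output of [simulate_peak_replicates()].
#' @param config a [sim_config()].
#' @return Named list of [signal_track()]s.
#' @export
simulate_signal <- function(ann, peaks = NULL, config) {
  known <- c("H3K4me3", "H3K4me1", "H3K27ac", "Ep300")
  bad <- setdiff(config$marks, known)
  if (length(bad))
    stop("unknown mark name(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  cl <- attr(ann, "chrom_lengths")
  bw <- config$bin_width
  if (any(cl %% bw != 0)) stop("bin_width must divide chrom_length")
  enh <- attr(ann, "enhancers")
  with_seed(config$seed + 2L, {
    base_rate <- lapply(cl, function(L) rep(config$background_rate, L / bw))
    mult <- config$enrichment
    rate_for <- function(mark) {
      r <- base_rate
      if (mark == "H3K4me3")
        r <- .enrich_bins(r, ann$chrom, ann$tss - 500, ann$tss + 500, bw, mult)
      if (mark == "H3K4me1")
        r <- .enrich_bins(r, enh$chrom, enh$start, enh$end, bw, mult)
      if (mark == "H3K27ac") {
        a <- enh[enh$active, , drop = FALSE]
        r <- .enrich_bins(r, a$chrom, a$start, a$end, bw, mult)
      }
      if (mark == "Ep300") {
        a <- enh[enh$active, , drop = FALSE]
        r <- .enrich_bins(r, a$chrom, a$start, a$end, bw, mult / 2)
      }
      r
    }
    draw <- function(rate, mark)
      signal_track(lapply(rate, function(v) stats::rpois(length(v), v)),
                   bin_width = bw, mark = mark)
    tracks <- stats::setNames(
      lapply(config$marks, function(m) draw(rate_for(m), m)), config$marks)
    if (!is.null(peaks)) {
      for (f in names(peaks)) {
        u <- merge_intervals(merge_replicates(peaks[[f]]$rep1, peaks[[f]]$rep2))
        r <- .enrich_bins(base_rate, u$chrom, u$start, u$end, bw, mult)
        tracks[[f]] <- draw(r, f)
      }
    }
    tracks
  })
}

#' Simulate an RNA-seq count matrix with planted fold changes
#'
#' Counts are negative-binomial (`var = mu + phi mu^2`) around log-normal
#' baseline gene means, scaled by per-sample library-size factors, with
#' per-gene log2 fold changes planted between the reference (first) and the
#' other conditions per `config$planted_lfc`.
#'
#' @param ann a [make_genome()] annotation (supplies gene ids and lengths).
#' @param design data frame with columns `sample` and `condition`; at least
#'   two samples per condition.
#' @param config a [sim_config()].
#' @return A [count_matrix()] with attribute `truth`: list with `true_lfc`
#'   (gene x condition matrix) and `size_factors`.
#' @export
simulate_counts <- function(ann, design, config) {
  stopifnot(all(c("sample", "condition") %in% names(design)))
  tab <- table(design$condition)
  if (any(tab < 2)) stop("design must list >= 2 samples per condition")
  conds <- unique(design$condition)
  ref <- conds[1]
  for (cn in setdiff(conds, ref))
    if (!cn %in% names(config$planted_lfc))
      stop("condition '", cn, "' absent from planted_lfc mapping")
  with_seed(config$seed + 3L, {
    g <- ann$gene_id
    n_g <- length(g); n_s <- nrow(design)
    base_mu <- stats::rlnorm(n_g, config$mean_log, config$mean_sdlog)
    sf <- stats::rlnorm(n_s, 0, config$libsize_sdlog)
    sf <- sf / exp(mean(log(sf)))
    lfc <- matrix(0, n_g, length(conds), dimnames = list(g, conds))
    for (cn in setdiff(conds, ref)) {
      v <- config$planted_lfc[[cn]]
      hit <- intersect(names(v), g)
      lfc[hit, cn] <- v[hit]
    }
    phi <- rep_len(config$nb_dispersion, n_g)
    counts <- matrix(0L, n_g, n_s, dimnames = list(g, design$sample))
    for (j in seq_len(n_s)) {
      mu <- sf[j] * base_mu * 2^lfc[, design$condition[j]]
      counts[, j] <- if (all(phi == 0)) stats::rpois(n_g, mu)
        else stats::rnbinom(n_g, mu = mu, size = ifelse(phi > 0, 1 / phi, 1e8))
    }
    cm <- count_matrix(counts, gene_lengths = stats::setNames(ann$exon_bp, g),
                       design = design)
    attr(cm, "truth") <- list(true_lfc = lfc, size_factors = sf,
                              base_mean = stats::setNames(base_mu, g))
    cm
  })
}

#' Simulate a label-free AP-MS intensity table
#'
#' Bait-IP intensities follow the iBAQ convention: molar amount (copies per
#' complex, bait at `S`-fold molar excess over complexes) times theoretical
#' tryptic peptide count. Control IPs carry background binders only.
#' Log-normal noise at `noise_cv`; per-run left-censoring below the
#' `censor_q` intensity quantile produces missing-at-low-abundance values.
#'
#' @param config a [sim_config()]; uses `complex_spec`, `n_background`,
#'   `noise_cv`, `censor_q`, `n_rep`.
#' @return A [protein_intensity_table()] with attribute `truth` (`copies`,
#'   `S`, `bait`, `anchors`).
#' @export
simulate_lfq <- function(config) {
  cs <- config$complex_spec
  if (is.null(cs$copies) || !cs$bait %in% names(cs$copies))
    stop("complex_spec must contain the bait among its copies")
  if (!all(cs$anchors %in% names(cs$copies)) ||
      sum(cs$copies[cs$anchors]) < 1 - 1e-9)
    stop("complex_spec must designate anchor protein(s) with copies >= 1")
  if (cs$S < 1) stop("bait excess S must be >= 1")
  with_seed(config$seed + 4L, {
    members <- names(cs$copies)
    moles <- cs$copies
    moles[cs$bait] <- cs$S              # bait at S-fold excess over complexes
    pep <- stats::setNames(
      sample(10:60, length(members) + config$n_background, replace = TRUE),
      c(members, if (config$n_background)
        sprintf("bg%03d", seq_len(config$n_background))))
    unit <- 1e4
    runs <- c(sprintf("bait_%d", seq_len(config$n_rep)),
              sprintf("control_%d", seq_len(config$n_rep)))
    groups <- rep(c("bait", "control"), each = config$n_rep)
    prots <- names(pep)
    X <- matrix(NA_real_, length(prots), length(runs),
                dimnames = list(prots, runs))
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    noise <- function(n) if (sdlog == 0) rep(1, n)
      else stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    for (j in seq_along(runs)) {
      if (groups[j] == "bait")
        X[members, j] <- moles * pep[members] * unit * noise(length(members))
    }
    # per-protein background level shared across runs (nonspecific binders)
    if (config$n_background) {
      bg <- setdiff(prots, members)
      lvl <- stats::rlnorm(length(bg), log(0.05), 0.5)
      for (j in seq_along(runs))
        X[bg, j] <- lvl * pep[bg] * unit * noise(length(bg))
    }
    if (config$censor_q > 0) {
      for (j in seq_along(runs)) {
        obs <- X[, j]
        thr <- stats::quantile(obs, config$censor_q, na.rm = TRUE)
        X[!is.na(obs) & obs < thr, j] <- NA_real_
      }
    }
    t <- protein_intensity_table(X, groups = groups, peptide_counts = pep)
    attr(t, "truth") <- list(copies = cs$copies, S = cs$S, bait = cs$bait,
                             anchors = cs$anchors)
    t
  })
}

#' Simulate a single-cell qPCR Ct matrix with two latent populations
#'
#' Two cell populations differ by `ct_sep` cycles on the marker panels
#' (population 1 high on the first panel, population 2 on the second);
#' housekeeping genes are constant apart from per-cell offsets emulating
#' capture efficiency. Entries drop out (missing) with probability
#' `dropout_p`.
#'
#' @param config a [sim_config()].
#' @return A [ct_matrix()] (genes x cells) with attribute `truth`: the
#'   latent population label per cell.
#' @export
simulate_ct <- function(config) {
  if (config$dropout_p < 0 || config$dropout_p > 1)
    stop("dropout_p must lie in [0, 1]")
  if (length(config$housekeeping) < 2)
    stop("at least 2 housekeeping genes must be configured")
  with_seed(config$seed + 5L, {
    p1 <- config$ct_markers[[1]]; p2 <- config$ct_markers[[2]]
    genes <- c(p1, p2, config$housekeeping)
    n_cells <- sum(config$n_cells)
    pop <- rep(seq_along(config$n_cells), config$n_cells)
    offs <- stats::rnorm(n_cells, 0, config$cell_offset_sd)
    base <- matrix(NA_real_, length(genes), n_cells,
                   dimnames = list(genes, sprintf("cell_%03d", seq_len(n_cells))))
    hi <- 22; lo <- 22 + config$ct_sep   # lower Ct = more expressed
    base[p1, ] <- ifelse(rep(pop == 1, each = length(p1)), hi, lo)
    base[p2, ] <- ifelse(rep(pop == 2, each = length(p2)), hi, lo)
    base[config$housekeeping, ] <- 18
    ct <- base + rep(offs, each = length(genes)) +
      stats::rnorm(length(base), 0, config$ct_noise)
    if (config$dropout_p > 0)
      ct[stats::runif(length(ct)) < config$dropout_p] <- NA_real_
    m <- ct_matrix(ct, housekeeping = config$housekeeping)
    attr(m, "truth") <- list(population = pop)
    m
  })
}

#' Write a full synthetic study to disk
#'
#' Serialises every generated input in its standard plain-text format:
#' genes as GFF3, peak replicates as BED6, signal tracks as bedGraph, and
#' counts/design/LFQ/Ct plus all truth tables as TSV.
#'
#' @param dir output directory (created if needed).
#' @param config a [sim_config()].
#' @param design optional RNA-seq design; defaults to 3 vs 3 WT/KO.
#' @return Invisibly, the list of generated objects.
#' @export
write_simulation <- function(dir, config = sim_config(), design = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(design))
    design <- data.frame(sample = sprintf("s%d", 1:6),
                         condition = rep(c("WT", "KO"), each = 3))
  if (!"KO" %in% names(config$planted_lfc) && "KO" %in% design$condition)
    config$planted_lfc$KO <- stats::setNames(numeric(0), character(0))
  ann <- make_genome(config)
  peaks <- simulate_peak_replicates(ann, config)
  tracks <- simulate_signal(ann, peaks, config)
  counts <- simulate_counts(ann, design, config)
  lfq <- simulate_lfq(config)
  ct <- simulate_ct(config)
  write_gff3(ann, file.path(dir, "genes.gff3"))
  write_tsv_table(attr(ann, "enhancers"), file.path(dir, "enhancers.tsv"))
  for (f in names(peaks)) {
    write_bed(peaks[[f]]$rep1, file.path(dir, sprintf("%s_rep1.bed", f)))
    write_bed(peaks[[f]]$rep2, file.path(dir, sprintf("%s_rep2.bed", f)))
    write_tsv_table(peaks[[f]]$truth, file.path(dir, sprintf("%s_truth.tsv", f)))
  }
  for (m in names(tracks))
    write_bedgraph(tracks[[m]], file.path(dir, sprintf("%s.bedGraph", m)))
  write_tsv_table(counts$counts, file.path(dir, "counts.tsv"), "gene_id")
  write_tsv_table(design, file.path(dir, "design.tsv"))
  write_tsv_table(attr(counts, "truth")$true_lfc,
                  file.path(dir, "counts_truth.tsv"), "gene_id")
  write_tsv_table(lfq$intensities, file.path(dir, "lfq.tsv"), "protein")
  write_tsv_table(data.frame(run = colnames(lfq$intensities),
                             group = lfq$groups),
                  file.path(dir, "lfq_design.tsv"))
  write_tsv_table(ct$ct, file.path(dir, "ct.tsv"), "gene")
  write_tsv_table(data.frame(cell = colnames(ct$ct),
                             population = attr(ct, "truth")$population),
                  file.path(dir, "ct_truth.tsv"))
  invisible(list(annotation = ann, peaks = peaks, tracks = tracks,
                 counts = counts, lfq = lfq, ct = ct))
}
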