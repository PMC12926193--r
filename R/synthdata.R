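#' Simulation configuration for synthetic single-cell caQTL data
#'
#' Builds a validated configuration describing a multi-donor, multi-library,
#' multi-study single-cell ATAC experiment with planted genotype effects on
#' peak accessibility, latent topic (cell-state) structure, dynamic
#' genotype-by-state effects, and local LD among SNPs.  The defaults describe
#' the desk-scale study conditions used throughout the package's calibration
#' and recovery analyses: 40 donors across 3 studies, roughly 100 cells per
#' donor (~4,000 cells), 600 peaks of which half carry a caQTL, and 8 SNPs
#' per peak.
#'
#' @param n_donors number of donors.
#' @param n_studies number of studies; donors are assigned round-robin.
#' @param n_libraries_per_study sequencing libraries per study; a donor's
#'   cells are spread randomly over the libraries of its study.
#' @param cells_per_donor length-2 integer range; each donor's cell count is
#'   drawn uniformly from it.
#' @param n_peaks number of accessibility peaks.
#' @param snps_per_peak SNPs simulated in the window of each peak.
#' @param n_topics number K of latent topics (>= 2).
#' @param concentration Dirichlet concentration of the per-cell topic
#'   loadings (smaller = more single-topic cells).
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param ld_rho AR(1) latent-Gaussian correlation between adjacent SNPs,
#'   in \[0, 1).
#' @param frac_caqtl_peaks fraction of peaks with a planted caQTL.
#' @param beta_sd SD of the planted per-allele log-rate effect (log-rate
#'   units per alt allele).
#' @param frac_dynamic fraction of caQTL peaks whose effect additionally
#'   varies with the dynamic-topic loading.
#' @param delta_sd SD of the planted interaction effect (log-rate units per
#'   alt allele per unit loading).
#' @param sigma_donor,sigma_library SDs of the donor and library random
#'   log-rate intercepts.
#' @param depth_lognormal_params `c(meanlog, sdlog)` of the per-cell
#'   sequencing depth (total unique fragments).
#' @param baseline_rate_range range of per-peak mean fragment counts per
#'   10^4 fragments of depth; sets relative peak abundances and, together
#'   with depth, absolute count levels.
#' @param frac_repeat_donors fraction of donors sampled at two visits
#'   (emits a `visit` column so repeated-measure deduplication can be
#'   exercised).
#' @param seed integer master seed; all internal seeds are derived from it
#'   by fixed offsets.
#'
#' @return a named list of class `SimConfig`.
#' @examples
#' cfg <- simConfig(n_donors = 10, n_peaks = 20, cells_per_donor = c(20, 30))
#' @export
simConfig <- function(n_donors = 40L,
                      n_studies = 3L,
                      n_libraries_per_study = 2L,
                      cells_per_donor = c(80L, 120L),
                      n_peaks = 600L,
                      snps_per_peak = 8L,
                      n_topics = 4L,
                      concentration = 0.3,
                      maf_range = c(0.05, 0.5),
                      ld_rho = 0.5,
                      frac_caqtl_peaks = 0.5,
                      beta_sd = 0.5,
                      frac_dynamic = 0.2,
                      delta_sd = 0.5,
                      sigma_donor = 0.2,
                      sigma_library = 0.1,
                      depth_lognormal_params = c(log(1e4), 0.5),
                      baseline_rate_range = c(0.05, 0.5),
                      frac_repeat_donors = 0,
                      seed = 1L) {
  cfg <- list(n_donors = as.integer(n_donors),
              n_studies = as.integer(n_studies),
              n_libraries_per_study = as.integer(n_libraries_per_study),
              cells_per_donor = as.integer(cells_per_donor),
              n_peaks = as.integer(n_peaks),
              snps_per_peak = as.integer(snps_per_peak),
              n_topics = as.integer(n_topics),
              concentration = concentration,
              maf_range = maf_range, ld_rho = ld_rho,
              frac_caqtl_peaks = frac_caqtl_peaks, beta_sd = beta_sd,
              frac_dynamic = frac_dynamic, delta_sd = delta_sd,
              sigma_donor = sigma_donor, sigma_library = sigma_library,
              depth_lognormal_params = depth_lognormal_params,
              baseline_rate_range = baseline_rate_range,
              frac_repeat_donors = frac_repeat_donors,
              seed = as.integer(seed))
  fracs <- c(cfg$frac_caqtl_peaks, cfg$frac_dynamic, cfg$frac_repeat_donors)
  if (any(fracs < 0 | fracs > 1))
    stop("fractions must lie in [0, 1]")
  if (any(c(cfg$beta_sd, cfg$delta_sd, cfg$sigma_donor,
            cfg$sigma_library) < 0))
    stop("effect and random-intercept SDs must be >= 0")
  if (length(cfg$maf_range) != 2L || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || diff(cfg$maf_range) < 0)
    stop("maf_range must be an increasing pair within (0, 0.5]")
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1)
    stop("ld_rho must lie in [0, 1)")
  if (length(cfg$cells_per_donor) != 2L ||
      cfg$cells_per_donor[1] > cfg$cells_per_donor[2])
    stop("cells_per_donor must be c(min, max) with min <= max")
  if (cfg$n_topics < 2L) stop("n_topics must be >= 2")
  if (cfg$concentration <= 0) stop("concentration must be > 0")
  class(cfg) <- "SimConfig"
  cfg
}

## Seeds for the sub-generators are fixed offsets of the master seed so that
## a SimConfig fully determines every draw.
.simSeed <- function(seed, offset) (as.integer(seed) + offset) %% .Machine$integer.max

#' Simulate donor genotype dosages with local LD
#'
#' Draws hard genotype dosages in \{0, 1, 2\} from per-SNP binomial(2, MAF)
#' margins coupled by an AR(1) Gaussian copula on the latent (haplotype)
#' scale, so adjacent SNPs are correlated with monotone decay, mimicking
#' local linkage disequilibrium.
#'
#' @param n_donors number of donors (>= 2).
#' @param n_snps number of SNPs in one LD chain.
#' @param maf_range MAF range, within (0, 0.5]; per-SNP MAFs are uniform in
#'   this range.
#' @param ld_rho latent AR(1) correlation between adjacent SNPs, in \[0, 1).
#' @param seed integer seed.
#' @param chrom chromosome label for the emitted SNP table.
#' @param positions optional strictly increasing integer positions; defaults
#'   to random gaps averaging ~1 kb.
#' @return list with `dosages` (donors x SNPs integer matrix) and `snps`
#'   (data.frame: snp, chrom, pos, maf, ea, oa).  The effect allele `ea` is
#'   the minor (counted) allele.
#' @examples
#' g <- simulateGenotypes(20, 10, c(0.1, 0.5), 0.5, seed = 1)
#' @export
simulateGenotypes <- function(n_donors, n_snps, maf_range = c(0.05, 0.5),
                              ld_rho = 0, seed = 1L, chrom = "chr1",
                              positions = NULL) {
  if (n_donors < 2) stop("n_donors must be >= 2")
  if (any(maf_range <= 0) || any(maf_range > 0.5))
    stop("maf outside (0,0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0,1)")
  set.seed(seed)
  maf <- runif(n_snps, maf_range[1], maf_range[2])
  thr <- qnorm(maf)
  ## two independent latent AR(1) chains per donor, one per haplotype
  hap <- function() {
    z <- matrix(rnorm(n_donors * n_snps), n_donors, n_snps)
    if (ld_rho > 0 && n_snps > 1) {
      for (j in 2:n_snps)
        z[, j] <- ld_rho * z[, j - 1] + sqrt(1 - ld_rho^2) * z[, j]
    }
    sweep(z, 2, thr, "<") + 0L
  }
  dos <- hap() + hap()
  storage.mode(dos) <- "integer"
  if (is.null(positions))
    positions <- cumsum(sample(500:1500, n_snps, replace = TRUE))
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, n_snps, replace = TRUE)
  oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1), "")
  snps <- data.frame(snp = sprintf("snp%05d", seq_len(n_snps)),
                     chrom = chrom, pos = as.integer(positions),
                     maf = maf, ea = ea, oa = unname(oa),
                     stringsAsFactors = FALSE)
  dimnames(dos) <- list(sprintf("donor%03d", seq_len(n_donors)), snps$snp)
  list(dosages = dos, snps = snps, maf = maf, ld_rho = ld_rho)
}

#' Simulate latent cell states (topic loadings and peak profiles)
#'
#' Per-cell topic loadings are Dirichlet(`concentration`) draws; per-topic
#' peak profiles are sparse non-negative columns (a shared per-peak baseline
#' abundance times topic-specific enrichment of a random ~20% marker-peak
#' subset), normalized so each column sums to 1.
#'
#' @param n_cells number of cells.
#' @param K number of topics (>= 2).
#' @param concentration Dirichlet concentration (> 0).
#' @param n_peaks number of peaks for the profiles.
#' @param seed integer seed.
#' @param baseline_rate_range per-peak relative abundance range (see
#'   [simConfig()]).
#' @return list with `loadings` (cells x K, rows sum to 1) and `profiles`
#'   (peaks x K, columns sum to 1).
#' @examples
#' st <- simulateCellStates(100, 4, 0.3, n_peaks = 50, seed = 1)
#' @export
simulateCellStates <- function(n_cells, K, concentration, n_peaks,
                               seed = 1L,
                               baseline_rate_range = c(0.05, 0.5)) {
  if (K < 2) stop("K must be >= 2")
  if (concentration <= 0) stop("concentration must be > 0")
  set.seed(seed)
  gam <- matrix(rgamma(n_cells * K, shape = concentration), n_cells, K)
  ## guard against all-zero rows at tiny concentration
  zero <- rowSums(gam) == 0
  if (any(zero)) gam[zero, ] <- 1 / K
  loadings <- gam / rowSums(gam)
  base <- runif(n_peaks, baseline_rate_range[1], baseline_rate_range[2])
  profiles <- matrix(base, n_peaks, K)
  for (k in seq_len(K)) {
    marker <- runif(n_peaks) < 0.2
    profiles[marker, k] <- profiles[marker, k] *
      exp(rnorm(sum(marker), mean = 1.5, sd = 0.5))
  }
  profiles <- sweep(profiles, 2, colSums(profiles), "/")
  colnames(loadings) <- colnames(profiles) <- sprintf("k%d", seq_len(K))
  list(loadings = loadings, profiles = profiles)
}

## Internal: draw ground truth effects given config + genotype block map.
.simulateTruth <- function(cfg, snp_block) {
  set.seed(.simSeed(cfg$seed, 3L))
  n_peaks <- cfg$n_peaks
  n_ca <- round(cfg$frac_caqtl_peaks * n_peaks)
  ca_peaks <- sort(sample.int(n_peaks, n_ca))
  beta <- numeric(n_peaks)
  beta[ca_peaks] <- rnorm(n_ca, 0, cfg$beta_sd)
  causal <- rep(NA_integer_, n_peaks)
  causal[ca_peaks] <- vapply(ca_peaks, function(j) sample(snp_block[[j]], 1), 1L)
  n_dyn <- round(cfg$frac_dynamic * n_ca)
  dyn_peaks <- if (n_dyn > 0) sort(sample(ca_peaks, n_dyn)) else integer(0)
  delta <- numeric(n_peaks)
  delta[dyn_peaks] <- rnorm(n_dyn, 0, cfg$delta_sd)
  list(causal_snp_per_peak = causal, beta_true = beta, delta_true = delta,
       caqtl_peaks = ca_peaks, dynamic_peaks = dyn_peaks,
       dynamic_topic = cfg$n_topics)
}

#' Simulate a cell-by-peak fragment count matrix
#'
#' Draws Poisson fragment counts under the generative form assumed by the
#' single-cell Poisson mixed-effects (sc-PME) model:
#' \deqn{\log \mu_{ic} = \log s_i + \log\textstyle\sum_k l_{ik}\phi_{ck} +
#'   \beta_c g_{d(i)} + \delta_c g_{d(i)} t_i + a_{d(i)} + b_{\ell(i)}}
#' with per-cell in-peak library size \eqn{s_i}, topic loadings \eqn{l},
#' peak profiles \eqn{\phi}, per-allele effect \eqn{\beta_c}, interaction
#' effect \eqn{\delta_c} with the dynamic-topic loading \eqn{t_i}, and donor
#' and library random intercepts.  QC covariates (TSS enrichment,
#' mitochondrial fraction, log10 fragments) are drawn jointly with depth
#' (correlation 0.5) so covariate adjustment is exercised non-trivially.
#'
#' @param config a [simConfig()] object.
#' @param genotypes output of [simulateGenotypes()].
#' @param truth ground-truth list (see [simulateCaqtlData()]), containing
#'   per-peak `beta_true`, `delta_true`, `causal_snp_per_peak`, topic
#'   loadings/profiles, donor/library effects and cell assignments.
#' @return a [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   `counts` assay (peaks x cells), peak `rowRanges`, and cell `colData`
#'   (cell_id, donor, library, study, visit, TSSEnrichment, MTratio,
#'   log10nFrags, depth).
#' @export
simulateCounts <- function(config, genotypes, truth) {
  cfg <- config
  n_cells <- length(truth$cell_donor)
  if (nrow(truth$topic_loadings_true) != n_cells)
    stop("dimension mismatch between truth loadings and cells")
  if (nrow(truth$topic_profiles_true) != cfg$n_peaks)
    stop("dimension mismatch between truth profiles and n_peaks")
  set.seed(.simSeed(cfg$seed, 4L))
  donor_idx <- truth$cell_donor
  lib_idx <- truth$cell_library
  L <- truth$topic_loadings_true
  Phi <- truth$topic_profiles_true
  ## depth and correlated QC covariates
  dp <- cfg$depth_lognormal_params
  z_depth <- rnorm(n_cells)
  depth <- exp(dp[1] + dp[2] * z_depth)
  rho_qc <- 0.5
  qc_mix <- function() rho_qc * z_depth + sqrt(1 - rho_qc^2) * rnorm(n_cells)
  TSSEnrichment <- 8 + 2 * qc_mix()
  MTratio <- plogis(-2.2 + 0.6 * qc_mix())
  log10nFrags <- log10(depth)
  ## expected in-peak total per cell: depth scaled by summed per-peak rates
  ## (baseline_rate_range is per 1e4 fragments of depth)
  scale_total <- sum(truth$peak_baseline) / 1e4
  s <- depth * scale_total
  ## per-cell genotype at each peak's causal SNP
  g_cell <- matrix(0, n_cells, cfg$n_peaks)
  has_snp <- !is.na(truth$causal_snp_per_peak)
  if (any(has_snp))
    g_cell[, has_snp] <- genotypes$dosages[donor_idx,
      truth$causal_snp_per_peak[has_snp], drop = FALSE]
  t_i <- L[, truth$dynamic_topic]
  base <- L %*% t(Phi)                      # cells x peaks, rows sum to 1
  eta <- log(pmax(base, 1e-300)) +
    sweep(g_cell, 2, truth$beta_true, "*") +
    sweep(g_cell * t_i, 2, truth$delta_true, "*") +
    log(s) + truth$donor_effects[donor_idx] +
    truth$library_effects[lib_idx]
  y <- matrix(rpois(length(eta), exp(eta)), n_cells, cfg$n_peaks)
  counts <- methods::as(Matrix::Matrix(t(y), sparse = TRUE), "CsparseMatrix")
  peak_width <- 500L
  centers <- 1e4 * seq_len(cfg$n_peaks)
  peaks <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = centers - peak_width %/% 2, width = peak_width))
  names(peaks) <- sprintf("peak%05d", seq_len(cfg$n_peaks))
  rownames(counts) <- names(peaks)
  colnames(counts) <- sprintf("cell%05d", seq_len(n_cells))
  cd <- S4Vectors::DataFrame(
    cell_id = colnames(counts),
    donor = rownames(genotypes$dosages)[donor_idx],
    library = truth$library_names[lib_idx],
    study = truth$study_of_library[lib_idx],
    visit = truth$cell_visit,
    TSSEnrichment = TSSEnrichment, MTratio = MTratio,
    log10nFrags = log10nFrags, depth = depth)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), rowRanges = peaks, colData = cd)
}

#' Simulate a complete synthetic caQTL dataset
#'
#' Drives the full generator: genotypes with LD, latent topic structure,
#' planted caQTL and dynamic (genotype-by-state) effects, donor/library
#' random intercepts, and the Poisson count matrix, all determined by a
#' single [simConfig()].
#'
#' @param config a [simConfig()] object.
#' @return list with elements `sce` (the [SingleCellExperiment::SingleCellExperiment]),
#'   `genotypes` (see [simulateGenotypes()]), `truth` (planted ground truth:
#'   `beta_true`, `delta_true`, `causal_snp_per_peak`, `caqtl_peaks`,
#'   `dynamic_peaks`, `dynamic_topic`, `topic_loadings_true`,
#'   `topic_profiles_true`, `donor_effects`, `library_effects`, cell
#'   assignments), `snp_block` (per-peak SNP index windows) and `config`.
#' @examples
#' sim <- simulateCaqtlData(simConfig(n_donors = 8, n_peaks = 12,
#'   cells_per_donor = c(10, 15), seed = 7))
#' @export
simulateCaqtlData <- function(config) {
  cfg <- config
  stopifnot(inherits(cfg, "SimConfig"))
  n_snps <- cfg$n_peaks * cfg$snps_per_peak
  ## SNP positions clustered around peak centers (peaks every 10 kb)
  set.seed(.simSeed(cfg$seed, 1L))
  centers <- 1e4 * seq_len(cfg$n_peaks)
  pos <- sort(unlist(lapply(centers, function(cc)
    cc + sample(seq(-4000L, 4000L), cfg$snps_per_peak))))
  genotypes <- simulateGenotypes(cfg$n_donors, n_snps, cfg$maf_range,
                                 cfg$ld_rho, seed = .simSeed(cfg$seed, 1L),
                                 positions = pos)
  snp_block <- split(seq_len(n_snps),
                     rep(seq_len(cfg$n_peaks), each = cfg$snps_per_peak))
  ## donor -> study, libraries, cells
  set.seed(.simSeed(cfg$seed, 2L))
  donor_study <- rep(seq_len(cfg$n_studies), length.out = cfg$n_donors)
  n_lib <- cfg$n_studies * cfg$n_libraries_per_study
  study_of_library <- rep(seq_len(cfg$n_studies),
                          each = cfg$n_libraries_per_study)
  library_names <- sprintf("study%d_lib%d", study_of_library,
                           sequence(rep(cfg$n_libraries_per_study,
                                        cfg$n_studies)))
  n_per_donor <- sample(seq(cfg$cells_per_donor[1], cfg$cells_per_donor[2]),
                        cfg$n_donors, replace = TRUE)
  repeat_donors <- which(runif(cfg$n_donors) < cfg$frac_repeat_donors)
  cell_donor <- rep(seq_len(cfg$n_donors), n_per_donor)
  cell_visit <- rep(1L, length(cell_donor))
  if (length(repeat_donors)) {
    extra <- sample(seq(cfg$cells_per_donor[1], cfg$cells_per_donor[2]),
                    length(repeat_donors), replace = TRUE)
    cell_donor <- c(cell_donor, rep(repeat_donors, extra))
    cell_visit <- c(cell_visit, rep(2L, sum(extra)))
  }
  n_cells <- length(cell_donor)
  ## a cell's library is drawn among its donor's study's libraries
  cell_library <- vapply(cell_donor, function(d) {
    libs <- which(study_of_library == donor_study[d])
    libs[sample.int(length(libs), 1)]
  }, 1L)
  states <- simulateCellStates(n_cells, cfg$n_topics, cfg$concentration,
                               cfg$n_peaks, seed = .simSeed(cfg$seed, 2L),
                               baseline_rate_range = cfg$baseline_rate_range)
  truth <- .simulateTruth(cfg, snp_block)
  set.seed(.simSeed(cfg$seed, 3L) + 1L)
  truth$donor_effects <- rnorm(cfg$n_donors, 0, cfg$sigma_donor)
  truth$library_effects <- rnorm(n_lib, 0, cfg$sigma_library)
  truth$topic_loadings_true <- states$loadings
  truth$topic_profiles_true <- states$profiles
  ## per-peak baseline on the "per 1e4 depth" scale; only its sum enters the
  ## count model (relative peak abundances live in the profiles)
  set.seed(.simSeed(cfg$seed, 5L))
  truth$peak_baseline <- runif(cfg$n_peaks, cfg$baseline_rate_range[1],
                               cfg$baseline_rate_range[2])
  truth$cell_donor <- cell_donor
  truth$cell_library <- cell_library
  truth$cell_visit <- cell_visit
  truth$library_names <- library_names
  truth$study_of_library <- sprintf("study%d", study_of_library)
  truth$donor_study <- donor_study
  sce <- simulateCounts(cfg, genotypes, truth)
  list(sce = sce, genotypes = genotypes, truth = truth,
       snp_block = snp_block, config = cfg)
}

#' Simulate paired per-SNP summary statistics for colocalization tests
#'
#' Simulates two quantitative traits on fresh individual-level genotypes
#' drawn from the same MAF/LD model as a donor panel, then computes marginal
#' per-SNP regression effects, standard errors and p-values for each trait.
#' The causal architecture is configurable: a shared causal SNP, distinct
#' causal SNPs, a causal SNP in trait 1 only, or no causal SNP.
#'
#' @param genotypes output of [simulateGenotypes()] (supplies SNP ids,
#'   positions, MAFs and the LD parameter).
#' @param causal_config one of `"shared"`, `"distinct"`, `"single"`,
#'   `"null"`.
#' @param n1,n2 trait sample sizes.
#' @param h2 per-trait variance explained by the causal SNP, in \[0, 1).
#' @param seed integer seed.
#' @param causal_snp optional index of the causal SNP (and, for
#'   `"distinct"`, a length-2 vector).
#' @return list with `ss1`, `ss2` (data.frames: snp, chrom, pos, ea, oa,
#'   beta, se, p, maf, n) and `causal` (indices used).
#' @export
simulateSummaryStats <- function(genotypes, causal_config = "shared",
                                 n1 = 10000L, n2 = 10000L, h2 = 0.2,
                                 seed = 1L, causal_snp = NULL) {
  if (h2 < 0 || h2 >= 1) stop("h2 must lie in [0, 1)")
  causal_config <- match.arg(causal_config,
                             c("shared", "distinct", "single", "null"))
  set.seed(seed)
  m <- nrow(genotypes$snps)
  causal <- switch(causal_config,
    shared = rep(if (is.null(causal_snp)) sample.int(m, 1) else causal_snp[1], 2),
    distinct = if (is.null(causal_snp)) sample.int(m, 2) else causal_snp[1:2],
    single = c(if (is.null(causal_snp)) sample.int(m, 1) else causal_snp[1], NA),
    null = c(NA, NA))
  one_trait <- function(n, ci, sd_seed) {
    G <- simulateGenotypes(n, m, range(genotypes$maf), genotypes$ld_rho,
                           seed = sd_seed,
                           positions = genotypes$snps$pos)$dosages
    ## overwrite per-SNP MAFs with the panel's (positions shared)
    y <- rnorm(n)
    if (!is.na(ci)) {
      g <- G[, ci]
      vg <- var(g)
      b <- sqrt(h2 / ((1 - h2) * vg))
      y <- y + b * g
    }
    gv <- apply(G, 2, var)
    gv[gv == 0] <- NA
    beta <- as.vector(crossprod(scale(G, scale = FALSE), y - mean(y))) /
      (gv * (n - 1))
    resid_var <- (var(y) * (n - 1) - beta^2 * gv * (n - 1)) / (n - 2)
    se <- sqrt(resid_var / (gv * (n - 1)))
    p <- 2 * pnorm(-abs(beta / se))
    data.frame(snp = genotypes$snps$snp, chrom = genotypes$snps$chrom,
               pos = genotypes$snps$pos, ea = genotypes$snps$ea,
               oa = genotypes$snps$oa, beta = beta, se = se, p = p,
               maf = colMeans(G) / 2, n = n, stringsAsFactors = FALSE)
  }
  ss1 <- one_trait(n1, causal[1], .simSeed(seed, 11L))
  ss2 <- one_trait(n2, causal[2], .simSeed(seed, 12L))
  list(ss1 = ss1, ss2 = ss2, causal = causal)
}
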