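test_that("sc-PME reduces to a plain Poisson GLM when variance components vanish", {
  set.seed(1)
  for (rep in 1:5) {
    px <- simOnePeak(n_donors = 25, cells = 30, beta = 0.3,
                     sigma_donor = 0, sigma_library = 0, seed = rep)
    glm_fit <- glm(px$y ~ px$g + px$design$X + offset(px$design$offset),
                   family = poisson)
    b_glm <- coef(glm_fit)[["px$g"]]
    ## exact reduction: variance components pinned at zero
    f0 <- fitSCPME(px$y, px$design, px$g, method = "pql",
                   null_fit = list(theta = c(0, 0), converged = TRUE))
    expect_lt(abs(f0$beta - b_glm), 1e-3)
    ## freely estimated fits stay close (sigma-hat is near but not at 0)
    f_glmer <- fitSCPME(px$y, px$design, px$g, method = "glmer")
    expect_lt(abs(f_glmer$beta - b_glm), 0.05)
    f_pql <- fitSCPME(px$y, px$design, px$g, method = "pql")
    expect_lt(abs(f_pql$beta - b_glm), 0.05)
  }
})

test_that("PQL and glmer agree on effect estimates with real variance components", {
  px <- simOnePeak(beta = 0.4, seed = 3)
  f1 <- fitSCPME(px$y, px$design, px$g, method = "pql")
  f2 <- fitSCPME(px$y, px$design, px$g, method = "glmer")
  expect_lt(abs(f1$beta - f2$beta), 0.03)
  expect_equal(f1$z, f1$beta / f1$se, tolerance = 1e-8)
  expect_true(f1$se > 0 && f2$se > 0)
})

test_that("planted allelic effect beta = 0.5 is recovered without bias", {
  est <- vapply(1:20, function(s) {
    px <- simOnePeak(beta = 0.5, seed = 100 + s)
    fitSCPME(px$y, px$design, px$g, method = "pql")$beta
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.05)
})

test_that("Wald p-values are calibrated under the null", {
  ## share one null model across genotype redraws: genotype permutation
  ## within one dataset gives exchangeable null fits cheaply
  px <- simOnePeak(beta = 0, seed = 9)
  nf <- scpmeNull(px$y, px$design)
  gd <- tapply(px$g, px$donor, unique)
  set.seed(42)
  p <- vapply(1:300, function(i) {
    gp <- sample(gd)[as.integer(px$donor)]
    fitSCPME(px$y, px$design, gp, method = "pql", null_fit = nf)$p_wald
  }, numeric(1))
  rej <- mean(p < 0.05)
  expect_lt(abs(rej - 0.05), 1.96 * sqrt(0.05 * 0.95 / 300) + 0.01)
})

test_that("SNP windows respect the exact half-width boundary", {
  peak <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1500))
  ## 0-based half-open: start0 = 1000, end0 = 1500, center = 1250
  pos <- c(1250 - 125001, 1250 - 125000, 1250, 1250 + 125000, 1250 + 125001)
  expect_equal(snpWindow(peak, pos), 2:4)
  expect_length(snpWindow(peak, c(10^7)), 0)
})

test_that("minor-allele-count filter keeps MAC >= 4 and drops monomorphic SNPs", {
  d <- matrix(0, 50, 3)
  d[1:3, 1] <- 1          # 3 het -> excluded
  d[1:2, 2] <- 2          # 2 hom-alt, MAC 4 -> included
  ## column 3 monomorphic -> excluded
  expect_equal(filterSnps(d), 2L)
  dd <- matrix(2, 50, 1)  # all hom-alt: minor allele is REF with count 0
  expect_length(filterSnps(dd), 0)
})

test_that("lead SNP selection breaks ties by distance then id", {
  sim <- smallSim(); d <- smallDesign()
  y <- as.numeric(assay(sim$sce)[1, ])
  r <- scanPeak(y, SummarizedExperiment::rowRanges(sim$sce)[1], d,
                sim$genotypes, snp_idx = sim$snp_block[[1]],
                peak_id = "peak1")
  expect_equal(sum(r$is_lead), 1)
  expect_equal(r$p_bonf, pmin(1, r$p * nrow(r)))
  ## synthetic tie: identical p, different distance
  expect_equal(scaQTL:::.leadIndex(c(0.5, 0.5), c(5000, 100), c("a", "b")), 2)
  expect_equal(scaQTL:::.leadIndex(c(0.5, 0.5), c(100, 100), c("b", "a")), 2)
  ## single SNP is the lead
  r1 <- scanPeak(y, SummarizedExperiment::rowRanges(sim$sce)[1], d,
                 sim$genotypes, snp_idx = sim$snp_block[[1]][1])
  expect_true(r1$is_lead[1] && nrow(r1) == 1)
})

test_that("a strongly planted causal SNP becomes the lead when SNPs are unlinked", {
  sim <- simulateCaqtlData(simConfig(
    n_donors = 30, n_peaks = 30, cells_per_donor = c(40, 50),
    snps_per_peak = 4, ld_rho = 0, beta_sd = 0.8, frac_caqtl_peaks = 1,
    seed = 77))
  d <- makeCellDesign(sim$sce)
  tr <- sim$truth
  strong <- tr$caqtl_peaks[abs(tr$beta_true[tr$caqtl_peaks]) > 0.5]
  hits <- vapply(strong, function(i) {
    r <- scanPeak(as.numeric(assay(sim$sce)[i, ]),
                  SummarizedExperiment::rowRanges(sim$sce)[i], d,
                  sim$genotypes, snp_idx = sim$snp_block[[i]])
    r$snp_id[r$is_lead] == sim$genotypes$snps$snp[tr$causal_snp_per_peak[i]]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("caQTL calling applies Bonferroni then Storey q over leads", {
  set.seed(5)
  leads <- data.frame(peak_id = sprintf("p%03d", 1:100),
                      p_bonf = c(rep(1e-6, 10), runif(90)))
  called <- callCaqtls(leads, fdr = 0.10)
  expect_true(all(called$significant[1:10]))
  ## q is monotone in p_bonf
  o <- order(called$p_bonf)
  expect_true(!is.unsorted(called$q[o]))
  expect_error(callCaqtls(leads[1:10, ]), "unstable")
})

test_that("Bonferroni adjustment is monotone in the number of SNPs tested", {
  sim <- smallSim(); d <- smallDesign()
  y <- as.numeric(assay(sim$sce)[2, ])
  gr <- SummarizedExperiment::rowRanges(sim$sce)[2]
  r2 <- scanPeak(y, gr, d, sim$genotypes, snp_idx = sim$snp_block[[2]][1:2])
  r4 <- scanPeak(y, gr, d, sim$genotypes, snp_idx = sim$snp_block[[2]])
  shared <- intersect(r2$snp_id, r4$snp_id)
  expect_true(all(r4$p_bonf[match(shared, r4$snp_id)] >=
                  r2$p_bonf[match(shared, r2$snp_id)] - 1e-12))
})

test_that("pseudobulk aggregation is exact and the visit rule keeps the larger visit", {
  m <- Matrix::Matrix(matrix(1:12, 3, 4), sparse = TRUE)
  rownames(m) <- c("pk1", "pk2", "pk3")
  grp <- c("a", "a", "b", "b")
  pb <- aggregatePseudobulk(m, grp)
  expect_equal(unname(pb$pseudobulk["a", ]), as.integer(m[, 1] + m[, 2]))
  expect_equal(sum(pb$pseudobulk), sum(m))
  ## identity when one cell per group
  pb1 <- aggregatePseudobulk(m, as.character(1:4))
  expect_equal(unname(as.vector(t(pb1$pseudobulk))), as.integer(as.vector(m)))
  ## dedup: donor d1 has 3 cells at visit 1 and 1 cell at visit 2
  donor <- c("d1", "d1", "d1", "d1")
  visit <- c(1, 1, 1, 2)
  pbd <- aggregatePseudobulk(m, donor, dedup_by_visit = TRUE,
                             donor = donor, visit = visit)
  expect_equal(unname(pbd$pseudobulk["d1", ]),
               as.integer(m[, 1] + m[, 2] + m[, 3]))
  ## tie goes to the earlier visit
  donor2 <- c("d1", "d1", "d1", "d1")
  visit2 <- c(1, 1, 2, 2)
  pbt <- aggregatePseudobulk(m, donor2, dedup_by_visit = TRUE,
                             donor = donor2, visit = visit2)
  expect_equal(unname(pbt$pseudobulk["d1", ]), as.integer(m[, 1] + m[, 2]))
})

test_that("constant covariates are rejected and design columns are standardized", {
  d <- smallDesign()
  expect_lt(max(abs(colMeans(d$X))), 1e-6)
  expect_lt(max(abs(apply(d$X, 2, sd) - 1)), 1e-4)
  sim <- smallSim()
  cd <- as.data.frame(SummarizedExperiment::colData(sim$sce))
  expect_error(makeCellDesign(sce = NULL,
    extra = cbind(const = rep(1, nrow(cd)), ok = rnorm(nrow(cd))),
    offset = log(cd$depth), donor = cd$donor, library = cd$library),
    "constant")
})
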