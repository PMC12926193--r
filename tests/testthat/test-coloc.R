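test_that("GWAS loci are clumped greedily with the 1 Mb removal radius", {
  ss <- data.frame(snp = c("a", "b"), chrom = "chr1",
                   pos = c(1e6, 1.4e6), p = c(1e-9, 1e-8))
  loci <- defineGwasLoci(ss)
  expect_length(loci, 1)
  expect_equal(loci[[1]]$lead_snp, "a")
  expect_setequal(loci[[1]]$members, c("a", "b"))
  ## 2 Mb apart: two loci
  ss2 <- data.frame(snp = c("a", "b"), chrom = "chr1",
                    pos = c(1e6, 3.1e6), p = c(1e-9, 1e-8))
  expect_length(defineGwasLoci(ss2), 2)
  ## single SNP below threshold
  ss3 <- data.frame(snp = "a", chrom = "chr1", pos = 1e6, p = 1e-8)
  expect_length(defineGwasLoci(ss3), 1)
  ## no locus when nothing clears the threshold
  ss4 <- data.frame(snp = "a", chrom = "chr1", pos = 1e6, p = 1e-6)
  expect_length(defineGwasLoci(ss4), 0)
  ## leads of distinct loci are farther apart than the removal radius,
  ## and rerunning on the residual SNPs yields nothing new
  set.seed(1)
  ss5 <- data.frame(snp = sprintf("s%03d", 1:300), chrom = "chr1",
                    pos = sort(sample.int(2e7, 300)),
                    p = 10^-runif(300, 0, 12))
  loci5 <- defineGwasLoci(ss5)
  leads <- vapply(loci5, `[[`, 0, "lead_pos")
  if (length(leads) > 1)
    expect_gt(min(dist(leads)), 1e6)
  residual <- ss5[!ss5$snp %in% unlist(lapply(loci5, `[[`, "members")), ]
  expect_length(defineGwasLoci(residual), 0)
})

test_that("colocalization eligibility needs >150 shared SNPs including both leads", {
  mk <- function(n, lead_first = TRUE) {
    p <- runif(n, 0.2, 1)
    p[if (lead_first) 1 else n] <- 1e-10
    data.frame(snp = sprintf("s%04d", seq_len(n)), p = p)
  }
  set.seed(2)
  a <- mk(200); b <- mk(200)
  expect_true(colocEligible(a, b)$eligible)
  ## exactly 150 shared: ineligible (strictly more required)
  expect_false(colocEligible(a[1:150, ], b[1:150, ])$eligible)
  expect_true(colocEligible(a[1:151, ], b[1:151, ])$eligible)
  ## large overlap but trait-1 lead absent from it: ineligible
  a2 <- mk(200); b2 <- mk(200)
  a2$p[1] <- 1; a2$p[200] <- 1e-10   # trait-1 lead at s0200
  expect_false(colocEligible(a2, b2[1:199, ])$eligible)
})

test_that("Wakefield log ABF matches its closed form and a quadrature oracle", {
  ## closed form at z = 0 is negative (shrinkage toward the null)
  r <- 0.15^2 / (0.15^2 + 0.05^2)
  expect_equal(wakefieldLABF(0, 0.05), 0.5 * log(1 - r))
  expect_lt(wakefieldLABF(0, 0.05), 0)
  ## quadrature oracle: BF = int N(bhat; b, V) N(b; 0, W) db / N(bhat; 0, V)
  beta <- 0.1; se <- 0.02; W <- 0.15^2
  bgrid <- seq(-1, 1, length.out = 200001)
  num <- sum(dnorm(beta, bgrid, se) * dnorm(bgrid, 0, sqrt(W))) *
    diff(bgrid[1:2])
  oracle <- log(num / dnorm(beta, 0, se))
  expect_lt(abs(wakefieldLABF(beta, se, W) - oracle), 1e-6)
  ## prior collapsing to the null: labf -> 0
  expect_lt(abs(wakefieldLABF(0.1, 0.02, 1e-12)), 1e-6)
  expect_error(wakefieldLABF(0.1, 0), "se")
})

test_that("coloc posteriors match brute-force enumeration on small toys", {
  set.seed(3)
  for (i in 1:20) {
    m <- sample(3:6, 1)
    ss1 <- data.frame(snp = letters[1:m], beta = rnorm(m, 0, 0.3),
                      se = runif(m, 0.02, 0.2))
    ss2 <- data.frame(snp = letters[1:m], beta = rnorm(m, 0, 0.3),
                      se = runif(m, 0.02, 0.2))
    cc <- colocABF(ss1, ss2, check_eligibility = FALSE)
    expect_lt(max(abs(cc$pp - enumColoc(ss1, ss2))), 1e-9)
    expect_equal(sum(cc$pp), 1, tolerance = 1e-9)
  }
})

test_that("coloc separates shared from distinct causal variants and favors H0 when flat", {
  ## single shared causal SNP at z = 8
  m <- 50
  mk <- function(zvec) data.frame(snp = sprintf("s%02d", 1:m),
                                  beta = zvec * 0.05, se = 0.05)
  z1 <- rep(0, m); z1[10] <- 8
  cc4 <- colocABF(mk(z1), mk(z1), check_eligibility = FALSE)
  expect_gt(cc4$pp["PP4"], 0.95)
  ## distinct causal SNPs
  z2 <- rep(0, m); z2[40] <- 8
  cc3 <- colocABF(mk(z1), mk(z2), check_eligibility = FALSE)
  expect_gt(cc3$pp["PP3"], cc3$pp["PP4"])
  ## both flat over 1,000 well-powered SNPs (small se, so each flat z
  ## carries real evidence against association): PP0 dominates
  m2 <- 1000
  flat <- data.frame(snp = sprintf("s%04d", 1:m2), beta = 0, se = 0.005)
  cc0 <- colocABF(flat, flat, check_eligibility = FALSE)
  expect_gt(cc0$pp["PP0"], 0.99)
  ## closed form with equal ABFs: PP0 = 1 / (1 + (p1+p2) m B + ...)
  B <- exp(wakefieldLABF(0, 0.005))
  h <- c(1, 1e-4 * m2 * B, 1e-4 * m2 * B,
         1e-8 * (m2^2 - m2) * B^2, 1e-5 * m2 * B^2)
  expect_equal(unname(cc0$pp), h / sum(h), tolerance = 1e-9)
})

test_that("coloc posteriors are invariant to sign flips and SNP order", {
  set.seed(4)
  m <- 30
  ss1 <- data.frame(snp = sprintf("s%02d", 1:m), beta = rnorm(m, 0, 0.2),
                    se = runif(m, 0.02, 0.1))
  ss2 <- data.frame(snp = sprintf("s%02d", 1:m), beta = rnorm(m, 0, 0.2),
                    se = runif(m, 0.02, 0.1))
  base <- colocABF(ss1, ss2, check_eligibility = FALSE)$pp
  flip <- ss1; flip$beta <- -flip$beta
  expect_equal(colocABF(flip, ss2, check_eligibility = FALSE)$pp, base,
               tolerance = 1e-12)
  shuf <- ss2[sample(m), ]
  expect_equal(colocABF(ss1, shuf, check_eligibility = FALSE)$pp, base,
               tolerance = 1e-12)
})

test_that("distinct simulated causal variants in linkage equilibrium yield PP3 > PP4", {
  g <- simulateGenotypes(300, 40, c(0.2, 0.5), 0, seed = 5)
  st <- simulateSummaryStats(g, "distinct", n1 = 5000, n2 = 5000,
                             h2 = 0.05, seed = 5)
  cc <- colocABF(st$ss1, st$ss2, check_eligibility = FALSE)
  expect_gt(cc$pp["PP3"], cc$pp["PP4"])
  ## and a shared causal variant yields PP4 on top
  st2 <- simulateSummaryStats(g, "shared", n1 = 5000, n2 = 5000,
                              h2 = 0.05, seed = 6)
  cc2 <- colocABF(st2$ss1, st2$ss2, check_eligibility = FALSE)
  expect_gt(cc2$pp["PP4"], max(cc2$pp[c("PP0", "PP1", "PP2", "PP3")]))
})

test_that("locus categorization uses PP4 threshold and context mapping", {
  res <- data.frame(
    locus = c("L1", "L2", "L2", "L3", "L3", "L4"),
    modality = c("caQTL", "caQTL", "eQTL", "caQTL", "eQTL", "eQTL"),
    context = c("mono", "mono", "mono", "CD4", "mono", "B"),
    pp4 = c(0.9, 0.8, 0.85, 0.9, 0.95, 0.2))
  out <- categorizeColocContexts(res)
  expect_equal(out$category[out$locus == "L1"], "caQTL-only")
  expect_equal(out$category[out$locus == "L2"], "both-same-context")
  expect_equal(out$category[out$locus == "L3"], "both-different-context")
  expect_equal(out$category[out$locus == "L4"], "none")
})
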