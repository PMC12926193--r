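test_that("rank-1 data are factorized essentially exactly at K = 1", {
  set.seed(1)
  a <- rexp(30, 1 / 5); b <- rexp(20, 1 / 5)
  Y <- outer(a, b)
  Y <- matrix(round(Y), 30, 20)   # integer counts close to rank-1
  fit <- fitPoissonNMF(Y, K = 1, n_main = 200, n_refine = 100)
  M <- topicLoadings(fit) %*% t(peakScores(fit))
  ## at K = 1 the MLE matches the rank-1 structure: row/col sums agree
  expect_lt(max(abs(rowSums(M) - rowSums(Y)) / pmax(rowSums(Y), 1)), 1e-3)
  expect_lt(max(abs(colSums(M) - colSums(Y)) / pmax(colSums(Y), 1)), 1e-3)
})

test_that("the objective is monotone through EM and the full schedule never worsens", {
  set.seed(2)
  Y <- matrix(rpois(50 * 30, 1), 50, 30)
  fit <- fitPoissonNMF(Y, K = 3, n_main = 40, n_refine = 30, seed = 2)
  tr <- objectiveTrace(fit)
  expect_true(all(diff(tr) > -1e-8))
  expect_gte(tail(tr, 1), tr[1])
})

test_that("non-integer or negative counts are rejected", {
  expect_error(fitPoissonNMF(matrix(c(0.5, 1, 2, 3), 2, 2), K = 2),
               "non-negative integers")
  expect_error(fitPoissonNMF(matrix(c(-1L, 1L, 2L, 3L), 2, 2), K = 2),
               "non-negative integers")
})

test_that("planted topics are recovered at K = 4 (matched factor correlation >= 0.9)", {
  sim <- simulateCaqtlData(simConfig(
    n_donors = 10, n_peaks = 200, cells_per_donor = c(60, 80),
    snps_per_peak = 2, frac_caqtl_peaks = 0, seed = 5))
  fit <- fitPoissonNMF(sim$sce, K = 4, n_main = 100, n_refine = 100,
                       seed = 1)
  Phi <- peakScores(toMultinomial(fit))
  cc <- matchColumns(Phi, sim$truth$topic_profiles_true)
  expect_true(all(cc >= 0.9))
})

test_that("expanding the topic ladder preserves earlier topic identities", {
  sim <- simulateCaqtlData(simConfig(
    n_donors = 10, n_peaks = 150, cells_per_donor = c(40, 50),
    snps_per_peak = 2, frac_caqtl_peaks = 0, n_topics = 4, seed = 6))
  f4 <- fitPoissonNMF(sim$sce, K = 4, n_main = 60, n_refine = 60, seed = 1)
  f6 <- expandAndRefit(f4, 6, sim$sce, n_main = 60, n_refine = 60)
  expect_error(expandAndRefit(f4, 4, sim$sce), "K_new")
  ## original columns stay in place and remain recognisable
  phi4 <- sweep(f4@F, 2, colSums(f4@F), "/")
  phi6 <- sweep(f6@F, 2, colSums(f6@F), "/")
  for (k in 1:4) expect_gte(cor(phi4[, k], phi6[, k]), 0.8)
  ## refit from its own expanded init cannot be worse
  expect_gte(tail(objectiveTrace(f6), 1), objectiveTrace(f6)[1])
  ## a second expansion keeps earlier identity too
  f8 <- expandAndRefit(f6, 8, sim$sce, n_main = 40, n_refine = 40)
  phi8 <- sweep(f8@F, 2, colSums(f8@F), "/")
  expect_gte(cor(phi4[, 3], phi8[, 3]), 0.8)
})

test_that("projection reproduces training loadings and handles degenerate cells", {
  set.seed(7)
  Y <- matrix(rpois(80 * 60, 2), 80, 60)
  fit <- fitPoissonNMF(Y, K = 3, n_main = 80, n_refine = 40, seed = 3)
  L2 <- projectLoadings(peakScores(fit), Y)
  cs <- vapply(seq_len(nrow(Y)), function(i)
    cor(L2[i, ], topicLoadings(fit)[i, ]), numeric(1))
  expect_gte(median(cs, na.rm = TRUE), 0.95)
  ## a cell proportional to one topic profile loads on it
  F <- peakScores(fit)
  pure <- matrix(rpois(60, 1e3 * F[, 2] / sum(F[, 2])), 1, 60)
  Lp <- projectLoadings(F, pure)
  u <- colSums(F)
  q <- Lp[1, ] * u / sum(Lp[1, ] * u)
  expect_gte(q[2], 0.95)
  ## all-zero cell: uniform with warning
  expect_warning(Lz <- projectLoadings(F, matrix(0L, 1, 60)), "all-zero")
  expect_equal(unname(Lz[1, ]), rep(1 / 3, 3))
})

test_that("multinomial conversion obeys its algebraic identities", {
  set.seed(8)
  Y <- matrix(rpois(40 * 25, 2), 40, 25)
  fit <- fitPoissonNMF(Y, K = 3, n_main = 30, n_refine = 10, seed = 4)
  tm <- toMultinomial(fit)
  Q <- topicLoadings(tm); Phi <- peakScores(tm)
  expect_true(all(abs(rowSums(Q) - 1) < 1e-8))
  expect_true(all(abs(colSums(Phi) - 1) < 1e-10))
  ## round trip: per-cell scale times Q Phi^T reproduces L F^T exactly
  M <- fit@L %*% t(fit@F)
  scale_i <- rowSums(sweep(fit@L, 2, colSums(fit@F), "*"))
  M2 <- (Q * scale_i) %*% t(Phi)
  expect_lt(max(abs(M - M2)), 1e-10 * max(M))
  ## K = 1 degenerate case
  f1 <- fitPoissonNMF(Y, K = 1, n_main = 10, n_refine = 0, seed = 5)
  t1 <- toMultinomial(f1)
  expect_true(all(abs(topicLoadings(t1) - 1) < 1e-12))
  expect_equal(peakScores(t1)[, 1], f1@F[, 1] / sum(f1@F[, 1]))
  ## zero topic column errors
  f1@F[, 1] <- 0
  expect_error(toMultinomial(f1), "u_k = 0")
})

test_that("downsampling rescues peaks that would lose all counts", {
  set.seed(9)
  mat <- Matrix::Matrix(rpois(20 * 50, 2), 20, 50, sparse = TRUE)
  rownames(mat) <- sprintf("p%02d", 1:20)
  ## peak 1 non-zero only in cell 17
  mat[1, ] <- 0; mat[1, 17] <- 3
  ds <- downsampleForFit(mat, 10, seed = 42)
  expect_gte(length(ds$cell_index), 10)
  expect_true(all(Matrix::rowSums(ds$counts) > 0))
  if (!(17 %in% ds$cell_index[1:10]))
    expect_true(17 %in% ds$cell_index)
  ## full coverage in the subset: exactly n_cells returned
  mat2 <- Matrix::Matrix(rpois(5 * 30, 5), 5, 30, sparse = TRUE)
  ds2 <- downsampleForFit(mat2, 8, seed = 1)
  expect_length(ds2$cell_index, 8)
  ## an unrescuable peak errors with its name
  mat[1, ] <- 0
  expect_error(downsampleForFit(mat, 10, seed = 1), "p01")
})

test_that("top-peak selection sizes and tie-breaking are deterministic", {
  Phi <- cbind(k1 = c(0.3, 0.3, 0.2, 0.1, 0.1))
  expect_equal(selectTopPeaks(Phi, 1, frac = 1), c(1, 2, 3, 4, 5))
  expect_equal(selectTopPeaks(Phi, 1, frac = 0.2), 1)   # tie -> lower row
  Phi10 <- cbind(k1 = c(10, 1:9) / sum(c(10, 1:9)))
  expect_equal(selectTopPeaks(Phi10, 1, frac = 0.10), 1)
  expect_error(selectTopPeaks(Phi, 1, frac = 0), "frac")
})

test_that("technical topics are flagged by QC correlation", {
  set.seed(10)
  qc <- data.frame(MTratio = runif(300), TSSEnrichment = rnorm(300))
  Q <- cbind(k1 = plogis(3 * scale(qc$MTratio) + rnorm(300, 0, 0.5)),
             k2 = runif(300))
  colnames(Q) <- c("k1", "k2")
  fl <- flagTechnicalTopics(Q, qc)
  expect_true(fl$technical[fl$topic == "k1"])
  expect_false(fl$technical[fl$topic == "k2"])
})
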