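test_that("trajectories are rank-percentile scaled with reversal and loading filter", {
  Q <- cbind(k1 = c(0.1, 0.5, 0.9), k2 = c(0.9, 0.5, 0.1))
  expect_equal(as.numeric(trajectoryFromLoading(Q, "k1")), c(0, 50, 100))
  expect_equal(as.numeric(trajectoryFromLoading(Q, "k1", reverse = TRUE)),
               c(100, 50, 0))
  Qf <- cbind(k1 = c(0.05, 0.2, 0.8))
  expect_equal(as.numeric(trajectoryFromLoading(Qf, "k1",
                                                min_loading = 0.1)),
               c(NA, 0, 100))
  expect_error(trajectoryFromLoading(Qf, "k1", min_loading = 0.5),
               "fewer than 2")
})

test_that("trajectories are invariant to strictly monotone loading transforms", {
  set.seed(1)
  Q <- cbind(k1 = runif(200))
  t1 <- as.numeric(trajectoryFromLoading(Q, "k1"))
  for (f in list(function(x) x^3, function(x) exp(5 * x),
                 function(x) log(x + 1))) {
    t2 <- as.numeric(trajectoryFromLoading(cbind(k1 = f(Q[, 1])), "k1"))
    expect_equal(t1, t2)
  }
  expect_true(all(t1 >= 0 & t1 <= 100))
})

test_that("composition along the trajectory tracks planted enrichment and nulls", {
  set.seed(2)
  n <- 5000
  Q <- cbind(k1 = runif(n))
  traj <- trajectoryFromLoading(Q, "k1")
  ## all target
  expect_equal(compositionAlong(traj, rep("m", n), "m"), rep(1, 100))
  ## independent labels: proportions hover around 0.3
  lab0 <- ifelse(runif(n) < 0.3, "m", "o")
  prop0 <- compositionAlong(traj, lab0, "m")
  expect_lt(abs(mean(prop0, na.rm = TRUE) - 0.3), 0.05)
  ## logistic enrichment in the trajectory
  lab1 <- ifelse(runif(n) < plogis((traj - 50) / 10), "m", "o")
  prop1 <- compositionAlong(traj, lab1, "m", smooth_window = 5)
  expect_gt(cor(seq_along(prop1), prop1, method = "spearman",
                use = "complete.obs"), 0.9)
})

test_that("feature-trajectory matrices filter variance and localize planted switches", {
  set.seed(3)
  n <- 3000
  Q <- cbind(k1 = runif(n))
  traj <- trajectoryFromLoading(Q, "k1")
  feats <- cbind(const = rep(1, n),
                 mono = traj / 100 + rnorm(n, 0, 0.05),
                 switch = as.numeric(traj > 50) + rnorm(n, 0, 0.05),
                 noise = rnorm(n))
  fm <- featureTrajectoryMatrix(traj, feats, var_cutoff = 0.5,
                                smooth_window = 3)
  expect_false("const" %in% rownames(fm))
  expect_true(all(c("mono", "switch") %in% rownames(fm)))
  expect_true(all(fm >= 0 & fm <= 1, na.rm = TRUE))
  ## largest inter-bin jump of the switch feature sits near bin 50
  jump <- which.max(abs(diff(fm["switch", ])))
  expect_lt(abs(jump - 50), 4)
  ## monotone feature row is monotone after smoothing
  expect_gt(cor(seq_len(100), fm["mono", ]), 0.95)
})

test_that("Spearman correlation with the trajectory hits the exact extremes", {
  set.seed(4)
  Q <- cbind(k1 = runif(300))
  traj <- trajectoryFromLoading(Q, "k1")
  feats <- cbind(same = as.numeric(traj), neg = -as.numeric(traj),
                 flat = rep(2, 300), indep = rnorm(300))
  rho <- spearmanWithTrajectory(feats, traj)
  expect_equal(unname(rho["same"]), 1)
  expect_equal(unname(rho["neg"]), -1)
  expect_true(is.na(rho["flat"]))
  expect_lt(abs(rho["indep"]), 0.15)
})

test_that("quintile differential activity is calibrated, powered, and antisymmetric", {
  set.seed(5)
  n <- 1000
  Q <- cbind(k1 = runif(n))
  traj <- trajectoryFromLoading(Q, "k1")
  cond <- sample(c("case", "control"), n, replace = TRUE)
  ## null features (non-negative, like activity scores): nothing
  ## significant beyond FDR
  f0 <- matrix(rexp(n * 40), n, 40,
               dimnames = list(NULL, sprintf("f%02d", 1:40)))
  r0 <- quintileDifferentialActivity(traj, f0, cond)
  expect_lte(mean(r0$fdr < 0.05), 0.05)
  ## shifted feature is detected
  r <- rank(traj, ties.method = "first")
  quint <- ceiling(r * 5 / n)
  grpA <- quint == 1
  grpB <- quint > 1 & cond == "case"
  f1 <- f0
  f1[grpB, 1] <- f1[grpB, 1] + 1
  r1 <- quintileDifferentialActivity(traj, f1, cond)
  expect_lt(r1$fdr[1], 0.05)
  expect_gt(r1$log2fc[1], 0)
  ## interchanging the two comparison groups negates log2fc, keeps p
  a <- f1[grpA, 1]; b <- f1[grpB, 1]
  eps <- 1e-9
  expect_equal(-log2((mean(a) + eps) / (mean(b) + eps)), r1$log2fc[1],
               tolerance = 1e-12)
  expect_equal(suppressWarnings(wilcox.test(a, b)$p.value), r1$p[1],
               tolerance = 1e-12)
})

test_that("mixed logistic topic association reduces to plain logistic without donor variance", {
  ## construct outcomes with no donor-level component at all (they vary
  ## freely within donor), so the fitted donor variance collapses to ~0
  ## and the mixed LRT must match ordinary logistic regression
  set.seed(6)
  n <- 1000
  donor <- rep(seq_len(20), each = n / 20)
  loading <- plogis(rnorm(n, -1))
  MTratio <- runif(n, 0, 0.2)
  nFrags <- rnorm(n)
  status <- rbinom(n, 1, plogis(-0.5 + 3 * loading))
  ## make both phenotype labels appear in >= 2 donors' majorities
  res <- mixedLogitTopicAssociation(loading, MTratio, nFrags, donor,
                                    status)
  expect_true(res$converged)
  keep <- loading > 0.01
  g_full <- glm(status[keep] ~ loading[keep] + MTratio[keep] + nFrags[keep],
                family = binomial)
  g_null <- glm(status[keep] ~ MTratio[keep] + nFrags[keep],
                family = binomial)
  lrt_glm <- 2 * (as.numeric(logLik(g_full)) - as.numeric(logLik(g_null)))
  expect_lt(abs(res$lrt_stat - lrt_glm), 0.05)
  expect_lt(res$p, 1e-4)
})

test_that("near-separation in the mixed logit is handled without crashing", {
  set.seed(7)
  n_donor <- 20; cells <- 10
  donor <- rep(seq_len(n_donor), each = cells)
  status <- rep(rep(0:1, each = n_donor / 2), each = cells)
  loading <- status + abs(rnorm(n_donor * cells, 0, 1e-3)) + 0.02
  res <- mixedLogitTopicAssociation(loading, runif(n_donor * cells),
                                    rnorm(n_donor * cells), donor, status)
  expect_lt(res$p, 1e-4)
})
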