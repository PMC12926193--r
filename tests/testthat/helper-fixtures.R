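## Shared small fixtures, built once per test run.  Sizes are chosen so the
## whole suite stays fast while still exercising multi-donor, multi-library,
## multi-study structure.

suppressMessages({
  library(Matrix)
  library(SummarizedExperiment)
})

## a compact dataset with planted caQTLs (20 donors, ~700 cells, 40 peaks)
smallSim <- local({
  sim <- NULL
  function() {
    if (is.null(sim))
      sim <<- simulateCaqtlData(simConfig(
        n_donors = 20, n_peaks = 40, cells_per_donor = c(30, 40),
        snps_per_peak = 4, seed = 11))
    sim
  }
})

smallDesign <- local({
  d <- NULL
  function() {
    if (is.null(d)) d <<- makeCellDesign(smallSim()$sce)
    d
  }
})

## simulate per-cell counts for a single peak under the sc-PME generative
## model; used for focused recovery/calibration tests
simOnePeak <- function(n_donors = 40, cells = 100, beta = 0, delta = 0,
                       sigma_donor = 0.2, sigma_library = 0.1,
                       n_lib = 6, maf = 0.3, base_rate = 2e-5,
                       seed = 1, t = NULL) {
  set.seed(seed)
  n <- n_donors * cells
  donor <- factor(rep(seq_len(n_donors), each = cells))
  lib <- factor(sample(seq_len(n_lib), n, replace = TRUE))
  depth <- rlnorm(n, log(1e4), 0.5)
  g_d <- rbinom(n_donors, 2, maf)
  g <- g_d[as.integer(donor)]
  if (is.null(t)) t <- runif(n)
  x <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("q1", "q2", "q3")))
  eta <- log(depth) + log(base_rate) + beta * g + delta * g * t +
    rnorm(n_donors, 0, sigma_donor)[as.integer(donor)] +
    rnorm(n_lib, 0, sigma_library)[as.integer(lib)] +
    0.1 * x[, 1]
  y <- rpois(n, exp(eta))
  design <- makeCellDesign(sce = NULL, extra = x, offset = log(depth),
                           donor = donor, library = lib)
  list(y = y, design = design, g = g, t = t, donor = donor)
}

## brute-force coloc posterior for small SNP sets (direct enumeration)
enumColoc <- function(ss1, ss2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      W1 = 0.15^2, W2 = 0.15^2) {
  bf1 <- exp(wakefieldLABF(ss1$beta, ss1$se, W1))
  bf2 <- exp(wakefieldLABF(ss2$beta, ss2$se, W2))
  h <- c(1,
         p1 * sum(bf1),
         p2 * sum(bf2),
         p1 * p2 * (sum(outer(bf1, bf2)) - sum(bf1 * bf2)),
         p12 * sum(bf1 * bf2))
  setNames(h / sum(h), paste0("PP", 0:4))
}

## dense 2-D grid-search oracle for the RE2 likelihood-ratio statistic;
## two zooming passes around the coarse argmax keep it purely grid-based
## while pushing the discretization error well below 1e-4
gridRE2 <- function(betas, ses, n_mu = 200, n_t2 = 200) {
  ll2d <- function(mu_g, t2_g) {
    best <- -Inf; arg <- c(NA, NA)
    for (t2 in t2_g) {
      v <- ses^2 + t2
      c1 <- sum(-0.5 * log(2 * pi * v))
      ll <- vapply(mu_g, function(mu)
        c1 - sum((betas - mu)^2 / (2 * v)), numeric(1))
      i <- which.max(ll)
      if (ll[i] > best) { best <- ll[i]; arg <- c(mu_g[i], t2) }
    }
    list(best = best, mu = arg[1], t2 = arg[2])
  }
  mu_g <- seq(min(betas) - 1, max(betas) + 1, length.out = n_mu)
  t2_g <- c(0, exp(seq(log(1e-8), log(100 * max(ses^2)),
                       length.out = n_t2)))
  r <- ll2d(mu_g, t2_g)
  for (pass in 1:2) {
    dmu <- diff(range(mu_g)) / n_mu
    mu_g <- seq(r$mu - 2 * dmu, r$mu + 2 * dmu, length.out = n_mu)
    t2_lo <- max(r$t2 / 4, 1e-10)
    t2_g <- unique(c(0, exp(seq(log(t2_lo), log(4 * r$t2 + 1e-8),
                                length.out = n_t2))))
    r <- ll2d(mu_g, t2_g)
  }
  l0 <- sum(-0.5 * log(2 * pi * ses^2) - betas^2 / (2 * ses^2))
  2 * (r$best - l0)
}

## best column matching (enumeration over permutations, K <= 8) between two
## factor matrices; returns per-column correlations under the best total
matchColumns <- function(A, B) {
  K <- ncol(A)
  stopifnot(K == ncol(B), K <= 8)
  cmat <- cor(A, B)
  perms <- .permutations(K)
  best <- -Inf; bestcor <- NULL
  for (r in seq_len(nrow(perms))) {
    cc <- cmat[cbind(perms[r, ], seq_len(K))]
    if (sum(cc) > best) { best <- sum(cc); bestcor <- cc }
  }
  bestcor
}

.permutations <- function(K) {
  if (K == 1) return(matrix(1, 1, 1))
  sub <- .permutations(K - 1)
  out <- matrix(0L, 0, K)
  for (i in seq_len(K)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}
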