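#' Harmonize per-study effect estimates to a common effect allele
#'
#' Aligns per-study summary effects to the effect/other allele coding of the
#' first study.  Effects with swapped effect/other alleles are sign-flipped;
#' strand flips (allele pair equal to the reverse complement) are resolved by
#' complementing before comparison; strand-ambiguous SNPs (A/T or C/G) whose
#' alleles do not match directly are dropped, as are irreconcilable allele
#' pairs.
#'
#' @param records data.frame with columns `snp`, `study`, `ea`, `oa`,
#'   `beta`, `se` (one row per SNP per study).
#' @return the input with `beta` aligned, plus an attribute
#'   `n_dropped` (count of dropped SNP-study rows); dropped rows are removed.
#' @examples
#' d <- data.frame(snp = "rs1", study = c("a", "b"), ea = c("A", "G"),
#'                 oa = c("G", "A"), beta = c(0.5, -0.5), se = 0.1)
#' harmonizeEffects(d)
#' @export
harmonizeEffects <- function(records) {
  stopifnot(all(c("snp", "study", "ea", "oa", "beta", "se") %in%
                colnames(records)))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ambiguous <- function(a, b) comp[a] == b
  out <- records
  keep <- rep(TRUE, nrow(out))
  for (s in unique(out$snp)) {
    idx <- which(out$snp == s)
    ref <- idx[1]
    ea0 <- out$ea[ref]; oa0 <- out$oa[ref]
    for (i in idx[-1]) {
      ea <- out$ea[i]; oa <- out$oa[i]
      if (ea == ea0 && oa == oa0) next
      if (ea == oa0 && oa == ea0) {           # swapped coding
        if (ambiguous(ea0, oa0)) { keep[i] <- FALSE; next }
        out$beta[i] <- -out$beta[i]
        out$ea[i] <- ea0; out$oa[i] <- oa0
      } else if (comp[ea] == ea0 && comp[oa] == oa0) {   # strand flip
        if (ambiguous(ea0, oa0)) { keep[i] <- FALSE; next }
        out$ea[i] <- ea0; out$oa[i] <- oa0
      } else if (comp[ea] == oa0 && comp[oa] == ea0) {   # strand flip + swap
        if (ambiguous(ea0, oa0)) { keep[i] <- FALSE; next }
        out$beta[i] <- -out$beta[i]
        out$ea[i] <- ea0; out$oa[i] <- oa0
      } else {
        keep[i] <- FALSE                       # irreconcilable
      }
    }
  }
  res <- out[keep, , drop = FALSE]
  attr(res, "n_dropped") <- sum(!keep)
  res
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' @param betas,ses per-study effect estimates and standard errors.
#' @return list with `beta_fe`, `se_fe`, `z_fe`, `p_fe`.
#' @examples
#' feMeta(c(0.4, 0.6), c(0.1, 0.1))
#' @export
feMeta <- function(betas, ses) {
  stopifnot(length(betas) == length(ses), length(betas) >= 1,
            all(ses > 0))
  w <- 1 / ses^2
  beta_fe <- sum(w * betas) / sum(w)
  se_fe <- 1 / sqrt(sum(w))
  z <- beta_fe / se_fe
  list(beta_fe = beta_fe, se_fe = se_fe, z_fe = z,
       p_fe = 2 * pnorm(-abs(z)))
}

## Profile log-likelihood of the random-effects model at tau2 (mu profiled
## out analytically).
.re2Profile <- function(tau2, betas, ses) {
  v <- ses^2 + tau2
  mu <- sum(betas / v) / sum(1 / v)
  sum(-0.5 * log(2 * pi * v) - (betas - mu)^2 / (2 * v))
}

#' Han-Eskin RE2 random-effects meta-analysis
#'
#' Tests the joint null of no mean effect and no heterogeneity
#' (\eqn{\mu = 0, \tau^2 = 0}) against the random-effects alternative by a
#' likelihood ratio.  The likelihood
#' \eqn{l(\mu, \tau^2) = \sum_s [-\tfrac12\log(2\pi(se_s^2+\tau^2)) -
#' (\beta_s-\mu)^2 / (2(se_s^2+\tau^2))]}
#' is maximized over \eqn{\mu \in R, \tau^2 \ge 0} by a log-spaced profile
#' grid in \eqn{\tau^2} followed by golden-section refinement; the statistic
#' is \eqn{S = 2(l_{max} - l(0, 0))} with asymptotic null
#' \eqn{p = \tfrac12 P(\chi^2_1 > S) + \tfrac12 P(\chi^2_2 > S)}.
#' The asymptotic mixture is anti-conservative for very small numbers of
#' studies compared with tabulated small-sample nulls; calibration analyses
#' in this package rely on simulation, not on exact small-sample p-values.
#'
#' @param betas,ses per-study effect estimates (>= 2 studies) and standard
#'   errors.
#' @param n_grid number of log-spaced tau2 grid points.
#' @return list with fixed-effects fields (`beta_fe`, `se_fe`, `z_fe`,
#'   `p_fe`), `tau2_hat`, `mu_hat`, `S_re2`, `p_re2`.
#' @examples
#' re2Meta(c(0.5, 0.1, 0.6), c(0.1, 0.1, 0.12))
#' @export
re2Meta <- function(betas, ses, n_grid = 50L) {
  stopifnot(length(betas) == length(ses), length(betas) >= 2)
  if (any(!is.finite(betas)) || any(!is.finite(ses)) || any(ses <= 0))
    stop("betas and ses must be finite with ses > 0")
  fe <- feMeta(betas, ses)
  l0 <- sum(-0.5 * log(2 * pi * ses^2) - betas^2 / (2 * ses^2))
  grid <- c(0, exp(seq(log(1e-8), log(100 * max(ses^2)),
                       length.out = n_grid)))
  ll <- vapply(grid, .re2Profile, numeric(1), betas = betas, ses = ses)
  i <- which.max(ll)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  if (hi > lo) {
    opt <- optimize(.re2Profile, c(lo, hi), betas = betas, ses = ses,
                    maximum = TRUE, tol = 1e-12)
    tau2_hat <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
  } else tau2_hat <- grid[i]
  l1 <- .re2Profile(tau2_hat, betas, ses)
  v <- ses^2 + tau2_hat
  mu_hat <- sum(betas / v) / sum(1 / v)
  S <- max(2 * (l1 - l0), 0)
  p <- 0.5 * pchisq(S, df = 1, lower.tail = FALSE) +
       0.5 * pchisq(S, df = 2, lower.tail = FALSE)
  c(fe, list(tau2_hat = tau2_hat, mu_hat = mu_hat, S_re2 = S, p_re2 = p))
}

#' Meta-analyze a table of per-study caQTL effects
#'
#' Convenience driver: harmonizes allele coding, then computes FE and RE2
#' statistics per SNP (optionally per peak-SNP pair via the `by` columns).
#'
#' @param records data.frame with `snp`, `study`, `ea`, `oa`, `beta`, `se`
#'   and optionally `peak_id`.
#' @return data.frame with one row per SNP (and peak if present): FE and
#'   RE2 fields.
#' @export
metaAnalyze <- function(records) {
  records <- harmonizeEffects(records)
  key <- if ("peak_id" %in% colnames(records))
    paste(records$peak_id, records$snp) else records$snp
  rows <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    r <- records[idx, , drop = FALSE]
    if (nrow(r) < 2) return(NULL)
    m <- re2Meta(r$beta, r$se)
    cbind(r[1, setdiff(colnames(r), c("study", "beta", "se")),
            drop = FALSE],
          as.data.frame(m), n_studies = nrow(r))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}
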