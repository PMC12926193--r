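#' Permute the donor-to-genotype assignment
#'
#' Shuffles whole genotype rows across donors, preserving within-donor LD
#' structure while breaking every genotype-phenotype link.
#'
#' @param genotypes list with `dosages` (donor x SNP) as from
#'   [simulateGenotypes()].
#' @param seed integer seed.
#' @return the genotype list with permuted `dosages` rows (row names, i.e.
#'   donor labels, stay in place).
#' @export
permuteGenotypes <- function(genotypes, seed = 1L) {
  set.seed(seed)
  perm <- sample.int(nrow(genotypes$dosages))
  d <- genotypes$dosages[perm, , drop = FALSE]
  rownames(d) <- rownames(genotypes$dosages)
  genotypes$dosages <- d
  genotypes
}

#' Permutation calibration of the sc-PME scan
#'
#' Permutes the donor-to-genotype assignment, reruns the full sc-PME scan
#' with per-peak Bonferroni correction and Storey q-values over the lead
#' SNPs, and summarizes two null exceedance fractions at `level`:
#'
#' * `frac_lead_bonf`: the fraction of peaks whose lead-SNP
#'   Bonferroni-adjusted p falls below `level`.  This is the calibration
#'   diagnostic with a non-degenerate null expectation — for m independent
#'   SNPs per peak the lead Bonferroni p satisfies
#'   \eqn{P(m\,p_{(1)} < t) = 1-(1-t/m)^m \approx 1-e^{-t}}, i.e. 9.52
#'   percent at level 0.1, slightly less under LD — and is the quantity a
#'   well-calibrated model should place near the nominal level.
#' * `frac_q`: the fraction of peaks with Storey q below `level`.  Under a
#'   complete null an FDR procedure yields essentially zero discoveries, so
#'   this fraction is expected near 0, not near `level`.
#'
#' Null-model fits are shared across permutations (they do not involve
#' genotype), so extra permutations mainly cost per-SNP PQL solves.
#'
#' @param counts peaks x cells matrix or `SingleCellExperiment`.
#' @param design a [makeCellDesign()] object.
#' @param genotypes list with `dosages` and `snps`.
#' @param peaks `GRanges` of peaks to scan.
#' @param snp_sets optional per-peak SNP index list (see [scanPeaks()]).
#' @param n_perm number of independent donor permutations to average over.
#' @param seed integer seed; permutation r uses `seed + r`.
#' @param level the threshold (default 0.1).
#' @param method,half_width,min_mac see [scanPeaks()].
#' @param null_fits optional precomputed per-peak [scpmeNull()] fits.
#' @return list of class `CalibrationReport`: `frac_lead_bonf`, `frac_q`
#'   (means over permutations, as fractions), `per_perm` (data.frame),
#'   `n_peaks_tested`, `n_perm`, `level`.
#' @export
permuteAndCalibrate <- function(counts, design, genotypes, peaks = NULL,
                                snp_sets = NULL, n_perm = 1L, seed = 1L,
                                level = 0.1, method = "pql",
                                half_width = 125000, min_mac = 4,
                                null_fits = NULL) {
  if (is(counts, "SummarizedExperiment")) {
    if (is.null(peaks)) peaks <- SummarizedExperiment::rowRanges(counts)
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  if (is.null(null_fits) && method == "pql") {
    null_fits <- lapply(seq_len(nrow(counts)), function(i)
      scpmeNull(as.numeric(counts[i, ]), design))
  }
  per_perm <- lapply(seq_len(n_perm), function(r) {
    gp <- permuteGenotypes(genotypes, seed = seed + r)
    sc <- scanPeaks(counts, design, gp, peaks = peaks,
                    snp_sets = snp_sets, null_fits = null_fits,
                    method = method, half_width = half_width,
                    min_mac = min_mac)
    leads <- callCaqtls(sc$leads, fdr = level,
                        min_peaks = min(20L, nrow(sc$leads)))
    data.frame(perm = r,
               n_tested = nrow(leads),
               frac_lead_bonf = mean(leads$p_bonf < level),
               frac_q = mean(leads$q < level))
  })
  per_perm <- do.call(rbind, per_perm)
  structure(list(frac_lead_bonf = mean(per_perm$frac_lead_bonf),
                 frac_q = mean(per_perm$frac_q),
                 per_perm = per_perm,
                 n_peaks_tested = per_perm$n_tested[1],
                 n_perm = n_perm, level = level),
            class = "CalibrationReport")
}

#' @export
print.CalibrationReport <- function(x, ...) {
  cat(sprintf(
    "Permutation calibration over %d peak(s), %d permutation(s):\n",
    x$n_peaks_tested, x$n_perm))
  cat(sprintf("  lead Bonferroni p < %.2g: %.2f%% (null expectation ~%.2f%%)\n",
              x$level, 100 * x$frac_lead_bonf,
              100 * (1 - exp(-x$level))))
  cat(sprintf("  Storey q < %.2g: %.2f%% (null expectation ~0%%)\n",
              x$level, 100 * x$frac_q))
  invisible(x)
}

#' Per-peak sparsity and mean-count features
#'
#' @param counts peaks x cells matrix or `SingleCellExperiment`.
#' @return data.frame with `sparsity` (fraction of zero cells) and
#'   `mean_count` per peak.
#' @export
peakFeatures <- function(counts) {
  if (is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  data.frame(sparsity = 1 - Matrix::rowMeans(counts > 0),
             mean_count = Matrix::rowMeans(counts),
             row.names = rownames(counts))
}

#' Match control peaks to target peaks on count features
#'
#' Greedy nearest-neighbour matching without replacement on z-scaled
#' features (by default per-peak sparsity and mean count), with covariate
#' balance reported as standardized mean differences before and after
#' matching.
#'
#' @param target_features,candidate_features data.frames of per-peak
#'   features (rows = peaks); candidates must be disjoint from targets and
#'   at least as numerous.
#' @return list with `matched` (row indices into the candidates, one per
#'   target), `smd_pre`, `smd_post` (named per-feature standardized mean
#'   differences).
#' @export
matchControlPeaks <- function(target_features, candidate_features) {
  tf <- as.matrix(target_features)
  cf <- as.matrix(candidate_features)
  if (nrow(tf) > nrow(cf))
    stop("more target peaks than candidate controls")
  all_f <- rbind(tf, cf)
  mu <- colMeans(all_f); s <- apply(all_f, 2, sd)
  s[s < 1e-12] <- 1
  tz <- sweep(sweep(tf, 2, mu), 2, s, "/")
  cz <- sweep(sweep(cf, 2, mu), 2, s, "/")
  smd <- function(a, b) {
    sp <- sqrt((apply(a, 2, var) + apply(b, 2, var)) / 2)
    sp[sp < 1e-12] <- 1
    abs(colMeans(a) - colMeans(b)) / sp
  }
  smd_pre <- smd(tf, cf)
  avail <- rep(TRUE, nrow(cz))
  matched <- integer(nrow(tz))
  for (i in seq_len(nrow(tz))) {
    d2 <- rowSums(sweep(cz, 2, tz[i, ])^2)
    d2[!avail] <- Inf
    matched[i] <- which.min(d2)
    avail[matched[i]] <- FALSE
  }
  smd_post <- smd(tf, cf[matched, , drop = FALSE])
  list(matched = matched, smd_pre = smd_pre, smd_post = smd_post)
}

#' Empirical significance from pooled permutation statistics
#'
#' For statistics where larger means more significant (e.g. -log10
#' q-values), the empirical p-value of each observed statistic against the
#' pooled null draws is `(1 + #{null >= obs}) / (1 + N_null)`; Storey
#' q-values are then computed over the empirical p-values.
#'
#' @param nominal_stat per-peak observed statistics.
#' @param permuted_stat pooled null statistics (non-empty).
#' @param fdr significance cutoff on the q-value (default 0.1).
#' @return data.frame with `stat`, `p_emp`, `q`, `significant`.
#' @export
empiricalSignificance <- function(nominal_stat, permuted_stat, fdr = 0.1) {
  if (!length(permuted_stat)) stop("empty permutation null set")
  ord_null <- sort(permuted_stat)
  N <- length(ord_null)
  n_ge <- N - findInterval(nominal_stat, ord_null, left.open = TRUE)
  p_emp <- (1 + n_ge) / (1 + N)
  q <- suppressWarnings(storeyQvalue(p_emp)$q)
  data.frame(stat = nominal_stat, p_emp = p_emp, q = q,
             significant = q < fdr)
}

#' Effect-size concordance between two sets of paired estimates
#'
#' @param beta_a,beta_b paired effect estimates; pairs with a missing value
#'   are dropped, pairs where either estimate is exactly zero are excluded
#'   from the sign-agreement numerator and denominator (their count is
#'   reported).
#' @return list with `sign_agreement`, `correlation` (Pearson), `n_pairs`,
#'   `n_zero_excluded`.
#' @export
effectConcordance <- function(beta_a, beta_b) {
  keep <- complete.cases(beta_a, beta_b)
  a <- beta_a[keep]; b <- beta_b[keep]
  if (length(a) < 2) stop("need at least 2 complete pairs")
  nz <- a != 0 & b != 0
  if (!any(nz)) {
    warning("all pairs contain a zero estimate; sign agreement undefined")
    sign_agreement <- NA_real_
  } else {
    sign_agreement <- mean(a[nz] * b[nz] > 0)
  }
  list(sign_agreement = sign_agreement,
       correlation = if (sd(a) > 0 && sd(b) > 0) cor(a, b) else NA_real_,
       n_pairs = length(a), n_zero_excluded = sum(!nz))
}
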