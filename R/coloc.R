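#' Define GWAS loci by greedy lead-SNP clumping
#'
#' Iteratively picks the genome-wide smallest p-value below `p_thresh`,
#' defines a locus window centered on that lead, removes all SNPs within
#' `removal_bp` of the lead (on its chromosome), and repeats until no SNP
#' below threshold remains.
#'
#' @param ss summary-statistics data.frame with `snp`, `chrom`, `pos`, `p`.
#' @param p_thresh locus-defining p-value threshold (default 1e-7).
#' @param window_bp total width of the reported locus window, centered on
#'   the lead (default 1 Mb).
#' @param removal_bp removal radius around the lead; SNPs within this
#'   distance are assigned to (and removed with) the locus.  Defaults to
#'   `window_bp` (i.e. +/- 1 Mb), exposed separately because "within 1 Mb"
#'   admits either reading.
#' @return list of loci; each has `lead_snp`, `chrom`, `lead_pos`,
#'   `lead_p`, `window` (c(start, end)) and `members` (SNP ids removed with
#'   the locus).
#' @examples
#' ss <- data.frame(snp = c("a", "b"), chrom = "chr1",
#'                  pos = c(1e6, 5e6), p = c(1e-9, 1e-8))
#' length(defineGwasLoci(ss))
#' @export
defineGwasLoci <- function(ss, p_thresh = 1e-7, window_bp = 1e6,
                           removal_bp = window_bp) {
  stopifnot(all(c("snp", "chrom", "pos", "p") %in% colnames(ss)))
  avail <- ss
  loci <- list()
  while (nrow(avail) && min(avail$p) < p_thresh) {
    i <- which.min(avail$p)
    lead <- avail[i, ]
    in_locus <- avail$chrom == lead$chrom &
      abs(avail$pos - lead$pos) <= removal_bp
    loci[[length(loci) + 1L]] <- list(
      lead_snp = lead$snp, chrom = lead$chrom, lead_pos = lead$pos,
      lead_p = lead$p,
      window = c(lead$pos - window_bp / 2, lead$pos + window_bp / 2),
      members = avail$snp[in_locus])
    avail <- avail[!in_locus, , drop = FALSE]
  }
  loci
}

#' Colocalization eligibility check
#'
#' Two traits are eligible for colocalization over a region when they share
#' strictly more than `min_overlap` SNPs and both traits' lead SNPs
#' (smallest p) are among the shared SNPs.
#'
#' @param ss1,ss2 summary-statistics data.frames (`snp`, `p`).
#' @param min_overlap minimum shared SNP count; must be exceeded strictly
#'   (default 150).
#' @return list with `eligible`, `overlap` (shared SNP ids), `lead1`,
#'   `lead2`.
#' @export
colocEligible <- function(ss1, ss2, min_overlap = 150L) {
  overlap <- intersect(ss1$snp, ss2$snp)
  lead1 <- ss1$snp[which.min(ss1$p)]
  lead2 <- ss2$snp[which.min(ss2$p)]
  list(eligible = length(overlap) > min_overlap &&
         lead1 %in% overlap && lead2 %in% overlap,
       overlap = overlap, lead1 = lead1, lead2 = lead2)
}

#' Wakefield log approximate Bayes factor
#'
#' For a SNP with estimate `beta` and standard error `se`, under a N(0, W)
#' effect prior, the log approximate Bayes factor against the null is
#' \eqn{\tfrac12[\log(1 - r) + r z^2]} with \eqn{z = \beta/se},
#' \eqn{V = se^2} and shrinkage \eqn{r = W / (W + V)}.
#'
#' @param beta,se effect estimate and standard error (se > 0); vectorized.
#' @param W prior effect variance (default 0.15^2, the conventional
#'   quantitative-trait prior; use 0.2^2 for case-control log-odds).
#' @return numeric vector of log ABFs.
#' @examples
#' wakefieldLABF(0.1, 0.02)
#' @export
wakefieldLABF <- function(beta, se, W = 0.15^2) {
  stopifnot(all(se > 0), W > 0)
  z <- beta / se
  r <- W / (W + se^2)
  0.5 * (log(1 - r) + r * z^2)
}

.logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Exact log of sum_{i != j} exp(a_i + b_j) via leave-one-out logsumexp of b
## (prefix/suffix accumulation), avoiding the catastrophic cancellation of
## the log(S1*S2 - S12) form when one SNP dominates both traits.
.logsumexpCross <- function(a, b) {
  m <- length(b)
  if (m < 2) return(-Inf)
  pref <- suf <- numeric(m)
  pref[1] <- b[1]
  for (i in 2:m) pref[i] <- .logsumexp(c(pref[i - 1], b[i]))
  suf[m] <- b[m]
  for (i in (m - 1):1) suf[i] <- .logsumexp(c(suf[i + 1], b[i]))
  loo <- vapply(seq_len(m), function(i) {
    parts <- c(if (i > 1) pref[i - 1], if (i < m) suf[i + 1])
    .logsumexp(parts)
  }, numeric(1))
  .logsumexp(a + loo)
}

#' Approximate-Bayes-factor colocalization
#'
#' Single-causal-variant colocalization of two traits over a shared SNP set.
#' Per-SNP Wakefield log ABFs are combined in log space into the five
#' hypothesis sums (H0 no association; H1/H2 association with one trait;
#' H3 two distinct causal variants; H4 one shared causal variant), weighted
#' by the per-SNP priors `p1`, `p2` and `p12`, and normalized into posterior
#' probabilities PP0-PP4.
#'
#' @param ss1,ss2 summary-statistics data.frames with `snp`, `beta`, `se`;
#'   only shared SNPs are used.
#' @param p1,p2 prior probability a SNP is causal for trait 1 / trait 2
#'   only (defaults 1e-4).
#' @param p12 prior probability a SNP is causal for both (default 1e-5).
#' @param W1,W2 effect-size prior variances passed to [wakefieldLABF()].
#' @param check_eligibility if TRUE (default), apply [colocEligible()] and
#'   mark the result ineligible (posteriors still computed) when it fails.
#' @param min_overlap passed to [colocEligible()].
#' @return list of class `ColocResult`: `n_overlap_snps`, `pp` (named
#'   PP0-PP4 vector summing to 1), `priors`, `eligible`.
#' @examples
#' sim <- simulateGenotypes(100, 20, c(0.2, 0.5), 0.3, seed = 3)
#' stats <- simulateSummaryStats(sim, "shared", seed = 3)
#' colocABF(stats$ss1, stats$ss2, check_eligibility = FALSE)$pp
#' @export
colocABF <- function(ss1, ss2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                     W1 = 0.15^2, W2 = 0.15^2,
                     check_eligibility = TRUE, min_overlap = 150L) {
  elig <- colocEligible(ss1, ss2, min_overlap)
  shared <- intersect(ss1$snp, ss2$snp)
  if (!length(shared)) stop("no shared SNPs between the two traits")
  a <- ss1[match(shared, ss1$snp), ]
  b <- ss2[match(shared, ss2$snp), ]
  l1 <- wakefieldLABF(a$beta, a$se, W1)
  l2 <- wakefieldLABF(b$beta, b$se, W2)
  s1 <- .logsumexp(l1)
  s2 <- .logsumexp(l2)
  s12 <- .logsumexp(l1 + l2)
  ## H3 sum: sum_{i != j} BF1_i BF2_j, computed exactly in log space
  s3 <- .logsumexpCross(l1, l2)
  lh <- c(h0 = 0,
          h1 = log(p1) + s1,
          h2 = log(p2) + s2,
          h3 = log(p1) + log(p2) + s3,
          h4 = log(p12) + s12)
  pp <- exp(lh - .logsumexp(lh))
  names(pp) <- paste0("PP", 0:4)
  structure(list(n_overlap_snps = length(shared), pp = pp,
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 eligible = if (check_eligibility) elig$eligible else TRUE),
            class = "ColocResult")
}

#' @export
print.ColocResult <- function(x, ...) {
  cat("ColocResult over", x$n_overlap_snps, "SNPs",
      if (!x$eligible) "(INELIGIBLE)" else "", "\n")
  print(round(x$pp, 4))
  invisible(x)
}

#' Categorize GWAS loci by their colocalization support
#'
#' Given colocalization results of GWAS loci against caQTLs and eQTLs in
#' multiple cellular contexts, assigns each locus to one of `caQTL-only`,
#' `eQTL-only`, `both-same-context`, `both-different-context` (or
#' `none`).  "Same context" is decided through a user-supplied mapping
#' between the cell-type panels of the two modalities.
#'
#' @param results data.frame with columns `locus`, `modality` (`"caQTL"` or
#'   `"eQTL"`), `context`, `pp4`.
#' @param pp4_threshold PP4 at or above which a locus counts as colocalized
#'   in a context (default 0.75).
#' @param context_map optional data.frame (`caqtl_context`, `eqtl_context`)
#'   mapping cell types between the two panels; identity mapping if omitted.
#' @return data.frame per locus: `category`, `n_caqtl_contexts`,
#'   `n_eqtl_contexts`.
#' @export
categorizeColocContexts <- function(results, pp4_threshold = 0.75,
                                    context_map = NULL) {
  stopifnot(all(c("locus", "modality", "context", "pp4") %in%
                colnames(results)))
  hit <- results[results$pp4 >= pp4_threshold, , drop = FALSE]
  map_ctx <- function(ctx) {
    if (is.null(context_map)) return(ctx)
    m <- match(ctx, context_map$eqtl_context)
    ifelse(is.na(m), ctx, context_map$caqtl_context[m])
  }
  out <- lapply(unique(results$locus), function(lc) {
    h <- hit[hit$locus == lc, , drop = FALSE]
    ca <- unique(h$context[h$modality == "caQTL"])
    eq <- unique(h$context[h$modality == "eQTL"])
    category <- if (length(ca) && !length(eq)) "caQTL-only"
      else if (!length(ca) && length(eq)) "eQTL-only"
      else if (!length(ca) && !length(eq)) "none"
      else if (length(intersect(ca, map_ctx(eq)))) "both-same-context"
      else "both-different-context"
    data.frame(locus = lc, category = category,
               n_caqtl_contexts = length(ca),
               n_eqtl_contexts = length(eq), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
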