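#' Dynamic (genotype-by-cell-state) caQTL likelihood ratio test
#'
#' Tests whether a lead caQTL SNP's effect on a peak changes along a topic
#' loading.  The full model adds a loading main effect and a
#' genotype-by-loading interaction to the sc-PME model,
#' \eqn{\ldots + \theta t_i + \delta g_i t_i}; the reduced model keeps
#' \eqn{\theta t_i} but drops the interaction.  Both are fitted with
#' `lme4::glmer` and compared by a 1-df likelihood ratio test.  A constant
#' loading makes the interaction unidentifiable and is reported as LRT
#' statistic 0 with p = 1 (flagged), not an error.
#'
#' @param y per-cell counts for the peak.
#' @param design a [makeCellDesign()] object.
#' @param g per-cell genotype dosage.
#' @param t per-cell topic loading.
#' @param nAGQ passed to `glmer` (default 0, the fast scan setting).
#' @param topic,cell_type,peak_id,snp_id labels copied into the record.
#' @return one-row data.frame (`peak_id`, `snp_id`, `topic`, `cell_type`,
#'   `delta_hat`, `lrt_stat`, `p_lrt`, `converged`).
#' @export
dynamicLRT <- function(y, design, g, t, nAGQ = 0, topic = NA,
                       cell_type = NA, peak_id = NA, snp_id = NA) {
  rec <- function(delta, stat, p, conv)
    data.frame(peak_id = peak_id, snp_id = snp_id, topic = topic,
               cell_type = cell_type, delta_hat = delta, lrt_stat = stat,
               p_lrt = p, converged = conv, stringsAsFactors = FALSE)
  if (sd(t) < 1e-12)
    return(rec(NA_real_, 0, 1, FALSE))
  df <- data.frame(y = y, g = g, t = t, design$X, donor = design$donor,
                   lib = design$library, off = design$offset)
  covs <- paste(colnames(design$X), collapse = " + ")
  ctrl <- lme4::glmerControl(optimizer = "bobyqa", calc.derivs = FALSE)
  full <- try(suppressWarnings(suppressMessages(lme4::glmer(
    stats::as.formula(paste("y ~ g + t + g:t +", covs,
      "+ offset(off) + (1 | donor) + (1 | lib)")),
    data = df, family = poisson, nAGQ = nAGQ, control = ctrl))),
    silent = TRUE)
  red <- try(suppressWarnings(suppressMessages(lme4::glmer(
    stats::as.formula(paste("y ~ g + t +", covs,
      "+ offset(off) + (1 | donor) + (1 | lib)")),
    data = df, family = poisson, nAGQ = nAGQ, control = ctrl))),
    silent = TRUE)
  if (inherits(full, "try-error") || inherits(red, "try-error"))
    return(rec(NA_real_, NA_real_, NA_real_, FALSE))
  stat <- max(2 * (as.numeric(logLik(full)) - as.numeric(logLik(red))), 0)
  conv <- length(full@optinfo$conv$lme4) == 0 &&
    length(red@optinfo$conv$lme4) == 0
  rec(lme4::fixef(full)[["g:t"]], stat,
      pchisq(stat, df = 1, lower.tail = FALSE), conv)
}

#' Per-cell-type topics eligible for dynamic caQTL testing
#'
#' The mapping of common immune cell types to the topics present in them,
#' used to restrict genotype-by-loading tests to cell-state axes that exist
#' within each cell type (avoiding confounding dynamic with cell-type-
#' specific effects).
#'
#' @return named list of topic label vectors.
#' @export
dynamicTopicMap <- function() {
  list(B = c("k1", "k11"),
       `CD4 T` = c("k6", "k7", "k17"),
       `CD8 T` = c("k3", "k6", "k7", "k14", "k17", "k18", "k19"),
       NK = c("k3", "k17"),
       monocyte = c("k10", "k12", "k15"),
       DC = c("k4", "k10", "k12", "k15"),
       `other T` = c("k3", "k6", "k8", "k14", "k17", "k18", "k19"))
}

#' Multiple-testing adjustment for dynamic caQTL records
#'
#' q-values are computed from the LRT p-values within each (cell type,
#' topic) stratum separately, then multiplied by the number of topics in
#' which each SNP was tested (a Bonferroni adjustment over topics), capped
#' at 1.  Records with adjusted q below `alpha` (default 0.01) are flagged
#' significant.
#'
#' @param records data.frame from [dynamicLRT()] rows with `snp_id`,
#'   `cell_type`, `topic`, `p_lrt`.
#' @param topics_per_snp optional named integer vector (SNP id -> number of
#'   topics tested); computed from `records` when omitted.
#' @param alpha significance cutoff on the adjusted q-value (default 0.01).
#' @param min_tests per-stratum guard passed through to [storeyQvalue()]
#'   behaviour; strata smaller than 20 fall back to BH inside the q-value
#'   computation.
#' @return the records (rows with missing p dropped) with `q_topic`,
#'   `n_topics_tested`, `q_adj`, `significant`.
#' @export
adjustDynamic <- function(records, topics_per_snp = NULL, alpha = 0.01,
                          min_tests = 20L) {
  records <- records[!is.na(records$p_lrt), , drop = FALSE]
  if (!nrow(records)) return(records)
  key <- paste(records$cell_type, records$topic)
  records$q_topic <- NA_real_
  for (k in unique(key)) {
    idx <- which(key == k)
    records$q_topic[idx] <-
      suppressWarnings(storeyQvalue(records$p_lrt[idx])$q)
  }
  if (is.null(topics_per_snp)) {
    tab <- table(paste(records$cell_type, records$snp_id))
    records$n_topics_tested <-
      as.integer(tab[paste(records$cell_type, records$snp_id)])
  } else {
    records$n_topics_tested <-
      as.integer(topics_per_snp[as.character(records$snp_id)])
  }
  if (anyNA(records$n_topics_tested) || any(records$n_topics_tested < 1))
    stop("SNPs with zero tested topics must be excluded")
  records$q_adj <- pmin(1, records$q_topic * records$n_topics_tested)
  records$significant <- records$q_adj < alpha
  records
}
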