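#' Build a cell trajectory from a topic loading
#'
#' A trajectory is the rank-percentile of a (optionally reversed) topic
#' loading scaled to \[0, 100\], defined only on cells inside `cell_mask`
#' whose loading reaches `min_loading` (loadings below the threshold are
#' treated as estimation noise); all other cells are `NA`.  Rank scaling
#' makes the trajectory invariant to any strictly monotone transform of the
#' loadings; ties share the mean rank.
#'
#' @param Q cells x K loading matrix (or a [TopicModel-class]).
#' @param topic topic column index or name.
#' @param cell_mask logical mask of cells eligible for the trajectory
#'   (e.g. one annotated lineage); default all cells.
#' @param reverse reverse the ordering (so the trajectory increases as the
#'   source topic's loading decreases).
#' @param min_loading minimum loading for a cell to be included (default
#'   0).
#' @return numeric per-cell trajectory in \[0, 100\] with `NA` for
#'   undefined cells; attributes `source_topic`, `reversed`, `min_loading`.
#' @examples
#' Q <- cbind(k1 = c(0.1, 0.5, 0.9), k2 = c(0.9, 0.5, 0.1))
#' trajectoryFromLoading(Q, "k1")
#' @export
trajectoryFromLoading <- function(Q, topic, cell_mask = NULL,
                                  reverse = FALSE, min_loading = 0) {
  if (is(Q, "TopicModel")) Q <- topicLoadings(Q)
  loading <- Q[, topic]
  if (is.null(cell_mask)) cell_mask <- rep(TRUE, length(loading))
  defined <- cell_mask & loading >= min_loading
  n <- sum(defined)
  if (n < 2) stop("fewer than 2 defined cells on the trajectory")
  v <- loading[defined]
  if (reverse) v <- -v
  traj <- rep(NA_real_, length(loading))
  traj[defined] <- 100 * (rank(v, ties.method = "average") - 1) / (n - 1)
  structure(traj, source_topic = topic, reversed = reverse,
            min_loading = min_loading)
}

## Internal: assign defined trajectory values to 1..n_bins equal-width bins
## over [0, 100].
.trajBins <- function(traj, n_bins) {
  pmin(floor(traj / 100 * n_bins) + 1L, n_bins)
}

## Internal: centered moving average, NA-tolerant at the edges.
.smoothSeries <- function(x, window) {
  if (is.null(window) || window <= 1) return(x)
  half <- floor(window / 2)
  vapply(seq_along(x), function(i) {
    w <- x[max(1, i - half):min(length(x), i + half)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Label composition along a trajectory
#'
#' Fraction of cells carrying the target label within each trajectory
#' percentile bin, optionally smoothed by a centered moving average.  Empty
#' bins propagate as `NA` (never imputed).
#'
#' @param traj per-cell trajectory (see [trajectoryFromLoading()]).
#' @param labels per-cell category labels.
#' @param target the category whose proportion is tracked.
#' @param n_bins number of bins (default 100 percentiles).
#' @param smooth_window moving-average window (default none).
#' @return numeric vector of per-bin proportions (length `n_bins`).
#' @export
compositionAlong <- function(traj, labels, target, n_bins = 100L,
                             smooth_window = NULL) {
  defined <- !is.na(traj)
  if (sum(defined) < n_bins)
    stop("need at least n_bins defined cells")
  bins <- .trajBins(traj[defined], n_bins)
  hit <- labels[defined] == target
  prop <- rep(NA_real_, n_bins)
  agg <- tapply(hit, bins, mean)
  prop[as.integer(names(agg))] <- agg
  .smoothSeries(prop, smooth_window)
}

#' Binned feature matrix along a trajectory
#'
#' Per-bin mean of each feature along the trajectory, smoothed, filtered to
#' the most variable features (those whose across-bin variance lies at or
#' above the `var_cutoff` quantile, i.e. the top `1 - var_cutoff` fraction),
#' and min-max scaled per feature to \[0, 1\].
#'
#' @param traj per-cell trajectory.
#' @param features cells x feature matrix aligned to the trajectory cells.
#' @param n_bins number of trajectory bins (default 100).
#' @param var_cutoff variance quantile below which features are dropped
#'   (default 0.8, keeping the top 20 percent most variable).
#' @param smooth_window moving-average window over bins (default 3).
#' @return features x bins matrix (rows scaled to \[0, 1\]) for the
#'   retained features.
#' @export
featureTrajectoryMatrix <- function(traj, features, n_bins = 100L,
                                    var_cutoff = 0.8, smooth_window = 3L) {
  defined <- !is.na(traj)
  features <- as.matrix(features)
  bins <- .trajBins(traj[defined], n_bins)
  fsub <- features[defined, , drop = FALSE]
  binned <- matrix(NA_real_, ncol(features), n_bins,
                   dimnames = list(colnames(features), NULL))
  for (b in unique(bins))
    binned[, b] <- colMeans(fsub[bins == b, , drop = FALSE])
  binned <- t(apply(binned, 1, .smoothSeries, window = smooth_window))
  v <- apply(binned, 1, var, na.rm = TRUE)
  keep <- v >= quantile(v, var_cutoff, na.rm = TRUE) & v > 0
  binned <- binned[keep, , drop = FALSE]
  rng <- t(apply(binned, 1, range, na.rm = TRUE))
  (binned - rng[, 1]) / (rng[, 2] - rng[, 1])
}

#' Spearman correlation of features with a trajectory
#'
#' @param features cells x feature matrix.
#' @param traj per-cell trajectory; only defined cells are used.
#' @return named per-feature Spearman correlations; constant features give
#'   `NA`.
#' @export
spearmanWithTrajectory <- function(features, traj) {
  defined <- !is.na(traj)
  features <- as.matrix(features)[defined, , drop = FALSE]
  tv <- traj[defined]
  out <- suppressWarnings(
    apply(features, 2, function(f)
      if (sd(f) == 0) NA_real_ else cor(f, tv, method = "spearman")))
  out
}

#' Differential feature activity between trajectory quintiles
#'
#' Groups the defined trajectory cells into `q` equal-size bins (default
#' quintiles, computed by stable rank so bin sizes differ by at most one
#' for distinct values) and tests each feature between group A — all cells
#' in the first quintile (cases and controls alike, the idea being that
#' case cells at the trajectory start are epigenetically similar to
#' controls) — and group B — case cells in the higher quintiles — by
#' Wilcoxon rank-sum with BH correction.
#'
#' @param traj per-cell trajectory.
#' @param features cells x feature matrix.
#' @param condition per-cell `"case"` / `"control"` labels.
#' @param q number of quantile groups (default 5).
#' @param min_cells minimum cells per comparison group (default 3).
#' @return data.frame per feature: `log2fc` (group B over group A means),
#'   `p`, `fdr`.
#' @export
quintileDifferentialActivity <- function(traj, features, condition,
                                         q = 5L, min_cells = 3L) {
  defined <- which(!is.na(traj))
  r <- rank(traj[defined], ties.method = "first")
  quint <- ceiling(r * q / length(defined))
  groupA <- defined[quint == 1L]
  groupB <- defined[quint > 1L & condition[defined] == "case"]
  if (length(groupA) < min_cells || length(groupB) < min_cells)
    stop("a comparison group has fewer than ", min_cells, " cells")
  features <- as.matrix(features)
  eps <- 1e-9
  res <- apply(features, 2, function(f) {
    a <- f[groupA]; b <- f[groupB]
    p <- suppressWarnings(wilcox.test(b, a)$p.value)
    c(log2fc = log2((mean(b) + eps) / (mean(a) + eps)), p = p)
  })
  out <- as.data.frame(t(res))
  out$fdr <- p.adjust(out$p, method = "BH")
  out
}

#' Mixed-effects logistic association between a topic loading and a
#' donor-level phenotype
#'
#' Fits, on cells passing the loading filter, the full model
#' `status ~ loading + MTratio + nFrags + (1 | donor)` and the null model
#' without the loading term (both by Laplace-approximate `glmer`), and
#' reports the 1-df likelihood ratio test of whether the topic loading
#' predicts donor phenotype beyond the QC covariates.  Non-convergence is
#' reported as a flagged record with missing p, never a silent value.
#'
#' @param loading per-cell topic loading.
#' @param MTratio,nFrags per-cell QC covariates (nFrags on the log10,
#'   z-scaled convention used in the sc-PME design).
#' @param donor per-cell donor id.
#' @param status per-cell phenotype in \{0, 1\} (constant within donor).
#' @param min_loading cells below this loading are dropped as estimation
#'   noise (default 0.01).
#' @return list with `lrt_stat`, `p`, `beta_loading`, `n_cells`,
#'   `converged`.
#' @export
mixedLogitTopicAssociation <- function(loading, MTratio, nFrags, donor,
                                       status, min_loading = 0.01) {
  keep <- loading > min_loading
  df <- data.frame(status = status[keep], loading = loading[keep],
                   MTratio = MTratio[keep], nFrags = nFrags[keep],
                   donor = factor(donor[keep]))
  per_donor <- tapply(df$status, df$donor, unique)
  if (length(unique(unlist(per_donor))) < 2 ||
      min(table(vapply(per_donor, `[`, 0, 1))) < 2)
    stop("need at least 2 donors per phenotype group")
  ctrl <- lme4::glmerControl(optimizer = "bobyqa", calc.derivs = FALSE)
  full <- try(suppressWarnings(suppressMessages(lme4::glmer(
    status ~ loading + MTratio + nFrags + (1 | donor), data = df,
    family = binomial, control = ctrl))), silent = TRUE)
  null <- try(suppressWarnings(suppressMessages(lme4::glmer(
    status ~ MTratio + nFrags + (1 | donor), data = df,
    family = binomial, control = ctrl))), silent = TRUE)
  if (inherits(full, "try-error") || inherits(null, "try-error"))
    return(list(lrt_stat = NA_real_, p = NA_real_,
                beta_loading = NA_real_, n_cells = nrow(df),
                converged = FALSE))
  stat <- max(2 * (as.numeric(logLik(full)) - as.numeric(logLik(null))), 0)
  conv <- length(full@optinfo$conv$lme4) == 0 &&
    length(null@optinfo$conv$lme4) == 0
  list(lrt_stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
       beta_loading = lme4::fixef(full)[["loading"]],
       n_cells = nrow(df), converged = conv)
}
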