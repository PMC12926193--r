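#' Find peaks co-accessible with a reference peak
#'
#' Cells are partitioned into `n_aggregates` random groups; per-group mean
#' accessibility (per-cell counts divided by per-cell totals, so that depth
#' does not induce spurious correlation) is computed for every peak, and
#' candidates within `window_bp` of the reference peak center are called
#' co-accessible when their Pearson correlation with the reference exceeds
#' `r_min`.  A distance-matched control set is drawn from candidates in the
#' low-correlation `control_band`.
#'
#' @param counts peaks x cells matrix or `SingleCellExperiment`.
#' @param peaks `GRanges` of all peaks (default `rowRanges`).
#' @param reference_peak index of the reference peak.
#' @param window_bp candidate window around the reference center (default
#'   125000).
#' @param r_min co-accessibility correlation threshold (default 0.5).
#' @param control_band correlation band for control peaks (default
#'   c(0.05, 0.1)).
#' @param n_aggregates number of random cell groups (default 100).
#' @param seed seed for the random partition.
#' @param size_factors per-cell normalization factors; defaults to per-cell
#'   total counts.  When an external library size (e.g. total fragments) is
#'   available, pass it instead: totals over a small peak panel are
#'   compositional and can mask genuine co-accessibility.
#' @return list with `coacc` (peak indices, correlation > r_min), `controls`
#'   (indices in the control band, distance-matched to the coacc peaks up
#'   to availability), `correlations` (named vector over candidates).
#' @export
coaccessiblePeaks <- function(counts, reference_peak, peaks = NULL,
                              window_bp = 125000, r_min = 0.5,
                              control_band = c(0.05, 0.1),
                              n_aggregates = 100L, seed = 1L,
                              size_factors = NULL) {
  if (is(counts, "SummarizedExperiment")) {
    if (is.null(peaks)) peaks <- SummarizedExperiment::rowRanges(counts)
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  n_cells <- ncol(counts)
  if (n_cells < 2 * n_aggregates)
    stop("not enough cells for ", n_aggregates, " aggregates")
  centers <- floor((GenomicRanges::start(peaks) - 1 +
                    GenomicRanges::end(peaks)) / 2)
  ref_center <- centers[reference_peak]
  cand <- which(abs(centers - ref_center) <= window_bp &
                seq_along(centers) != reference_peak &
                as.character(GenomicRanges::seqnames(peaks)) ==
                  as.character(GenomicRanges::seqnames(peaks))[reference_peak])
  if (!length(cand))
    return(list(coacc = integer(0), controls = integer(0),
                correlations = numeric(0)))
  set.seed(seed)
  grp <- sample(rep(seq_len(n_aggregates), length.out = n_cells))
  depth <- if (is.null(size_factors)) Matrix::colSums(counts) else
    size_factors
  depth[depth == 0] <- 1
  norm <- Matrix::t(Matrix::t(counts[c(reference_peak, cand),
                                     , drop = FALSE]) / depth)
  ind <- Matrix::sparseMatrix(i = seq_len(n_cells), j = grp, x = 1,
                              dims = c(n_cells, n_aggregates))
  agg <- as.matrix(norm %*% ind) / rep(Matrix::colSums(ind),
                                       each = length(cand) + 1)
  r <- as.vector(cor(agg[1, ], t(agg[-1, , drop = FALSE])))
  names(r) <- as.character(cand)
  coacc <- cand[!is.na(r) & r > r_min]
  ctrl_pool <- cand[!is.na(r) & r > control_band[1] & r < control_band[2]]
  controls <- integer(0)
  if (length(coacc) && length(ctrl_pool)) {
    d_coacc <- abs(centers[coacc] - ref_center)
    avail <- rep(TRUE, length(ctrl_pool))
    for (d in d_coacc) {
      gap <- abs(abs(centers[ctrl_pool] - ref_center) - d)
      gap[!avail] <- Inf
      if (all(!is.finite(gap))) break
      j <- which.min(gap)
      controls <- c(controls, ctrl_pool[j])
      avail[j] <- FALSE
    }
  } else controls <- ctrl_pool
  list(coacc = coacc, controls = controls, correlations = r)
}

#' Test distal effects of a lead SNP on co-accessible peaks
#'
#' Fits the sc-PME model of each co-accessible (or control) peak's counts
#' on the reference peak's lead-SNP genotype, and applies Storey q-values
#' across all tested pairs (`q < fdr` significant).
#'
#' @param counts peaks x cells matrix or `SingleCellExperiment`.
#' @param design a [makeCellDesign()] object.
#' @param g per-cell dosage of the reference peak's lead SNP.
#' @param peak_idx indices of the peaks to test.
#' @param method passed to [fitSCPME()].
#' @param fdr q-value cutoff (default 0.1).
#' @return data.frame per pair: `peak_idx`, `beta`, `se`, `z`, `p`, `q`,
#'   `significant`.
#' @export
distalCoaccTest <- function(counts, design, g, peak_idx, method = "pql",
                            fdr = 0.1) {
  if (is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  fits <- lapply(peak_idx, function(i)
    fitSCPME(as.numeric(counts[i, ]), design, g, method = method))
  out <- data.frame(peak_idx = peak_idx,
                    beta = vapply(fits, `[[`, 0, "beta"),
                    se = vapply(fits, `[[`, 0, "se"),
                    z = vapply(fits, `[[`, 0, "z"),
                    p = vapply(fits, `[[`, 0, "p_wald"))
  out$q <- suppressWarnings(storeyQvalue(out$p)$q)
  out$significant <- out$q < fdr
  out
}
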