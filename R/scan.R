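#' SNPs within the mapping window of a peak
#'
#' Returns the indices of SNPs whose position lies in
#' `[center - half_width, center + half_width]` (inclusive), where the peak
#' center is `floor((start0 + end0) / 2)` of the 0-based half-open peak
#' interval.
#'
#' @param peak either a length-1 `GRanges` or a numeric `c(start, end)`
#'   0-based half-open interval.
#' @param snp_pos sorted integer SNP positions.
#' @param half_width window half-width in bp (default 125000, i.e. a 250 kb
#'   window).
#' @return integer indices into `snp_pos`.
#' @export
snpWindow <- function(peak, snp_pos, half_width = 125000) {
  if (is(peak, "GRanges")) {
    start0 <- GenomicRanges::start(peak)[1] - 1L
    end0 <- GenomicRanges::end(peak)[1]
  } else {
    start0 <- peak[1]; end0 <- peak[2]
  }
  center <- floor((start0 + end0) / 2)
  which(snp_pos >= center - half_width & snp_pos <= center + half_width)
}

#' Filter SNPs by minor-allele count
#'
#' Keeps SNPs with at least `min_mac` minor-allele dosage counts across the
#' tested donors; monomorphic SNPs are excluded automatically (their minor
#' allele count is zero).
#'
#' @param dosages donor x SNP dosage matrix with entries in \[0, 2\].
#' @param min_mac minimum minor-allele count (default 4).
#' @return integer indices of SNPs passing the filter.
#' @export
filterSnps <- function(dosages, min_mac = 4) {
  if (any(dosages < 0 | dosages > 2)) stop("dosages must lie in [0, 2]")
  s <- colSums(dosages)
  mac <- pmin(s, 2 * nrow(dosages) - s)
  which(mac >= min_mac)
}

## Lead selection: smallest p, ties by smaller distance to peak center,
## then lexicographic SNP id.
.leadIndex <- function(p, distance, snp_id) {
  order(p, distance, snp_id)[1]
}

#' Scan one peak over its eligible SNPs
#'
#' Fits the sc-PME model for every eligible SNP of a peak and assembles the
#' per-association records, the per-peak Bonferroni-adjusted p-values, and
#' the lead SNP (smallest Wald p; ties broken by distance to the peak
#' center, then lexicographic SNP id).
#'
#' @param y per-cell counts for the peak.
#' @param peak length-1 `GRanges` (or `c(start0, end0)`).
#' @param design a [makeCellDesign()] object.
#' @param genotypes list with `dosages` and `snps` (see
#'   [simulateGenotypes()]).
#' @param snp_idx indices of SNPs to test; default
#'   `intersect(snpWindow(), filterSnps())`.
#' @param peak_id label for the output records.
#' @param method,nAGQ,null_fit passed to [fitSCPME()].
#' @param half_width,min_mac window and allele-count settings used when
#'   `snp_idx` is not supplied.
#' @return data.frame of QTL records (`peak_id`, `snp_id`, `chrom`, `pos`,
#'   `distance`, `beta`, `se`, `z`, `p`, `p_bonf`, `is_lead`, `converged`),
#'   or `NULL` when no SNP is eligible (the peak is reported untested via
#'   attribute `untested_reason`).
#' @export
scanPeak <- function(y, peak, design, genotypes, snp_idx = NULL,
                     peak_id = "peak", method = "pql", nAGQ = 0,
                     null_fit = NULL, half_width = 125000, min_mac = 4) {
  if (is.null(snp_idx)) {
    snp_idx <- intersect(snpWindow(peak, genotypes$snps$pos, half_width),
                         filterSnps(genotypes$dosages, min_mac))
  }
  if (!length(snp_idx)) {
    out <- NULL
    attr(out, "untested_reason") <- "no eligible SNPs in window"
    return(out)
  }
  if (method == "pql" && is.null(null_fit))
    null_fit <- scpmeNull(y, design)
  if (is(peak, "GRanges")) {
    center <- floor((GenomicRanges::start(peak)[1] - 1 +
                     GenomicRanges::end(peak)[1]) / 2)
  } else center <- floor((peak[1] + peak[2]) / 2)
  fits <- lapply(snp_idx, function(j) {
    g <- expandGenotype(genotypes$dosages, design$donor, j)
    fitSCPME(y, design, g, method = method, nAGQ = nAGQ,
             null_fit = null_fit)
  })
  m <- length(snp_idx)
  rec <- data.frame(
    peak_id = peak_id,
    snp_id = genotypes$snps$snp[snp_idx],
    chrom = genotypes$snps$chrom[snp_idx],
    pos = genotypes$snps$pos[snp_idx],
    distance = abs(genotypes$snps$pos[snp_idx] - center),
    beta = vapply(fits, `[[`, 0, "beta"),
    se = vapply(fits, `[[`, 0, "se"),
    z = vapply(fits, `[[`, 0, "z"),
    p = vapply(fits, `[[`, 0, "p_wald"),
    converged = vapply(fits, `[[`, TRUE, "converged"),
    stringsAsFactors = FALSE)
  rec$p_bonf <- pmin(1, rec$p * m)
  rec$is_lead <- FALSE
  rec$is_lead[.leadIndex(rec$p, rec$distance, rec$snp_id)] <- TRUE
  rec
}

#' Scan many peaks
#'
#' Drives [scanPeak()] over a peak set, reusing one null-model fit per peak
#' in PQL mode.  Peaks with no eligible SNP are reported untested.
#'
#' @param counts peaks x cells count matrix or a `SingleCellExperiment`.
#' @param peaks `GRanges` of the peaks to scan (default `rowRanges`).
#' @param design a [makeCellDesign()] object.
#' @param genotypes list with `dosages` and `snps`.
#' @param snp_sets optional list of per-peak SNP index vectors (default:
#'   window + MAC filter per peak).
#' @param null_fits optional list of per-peak [scpmeNull()] results to
#'   reuse (e.g. across permutations; they do not involve genotype).
#' @param method,nAGQ,half_width,min_mac see [scanPeak()].
#' @param verbose print progress every 50 peaks.
#' @return list with `records` (all associations), `leads` (one row per
#'   tested peak), `untested` (character vector of peak ids).
#' @export
scanPeaks <- function(counts, design, genotypes, peaks = NULL,
                      snp_sets = NULL, null_fits = NULL, method = "pql",
                      nAGQ = 0, half_width = 125000, min_mac = 4,
                      verbose = FALSE) {
  if (is(counts, "SummarizedExperiment")) {
    if (is.null(peaks)) peaks <- SummarizedExperiment::rowRanges(counts)
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  peak_ids <- if (!is.null(names(peaks))) names(peaks) else
    rownames(counts)
  keep_snps <- filterSnps(genotypes$dosages, min_mac)
  res <- vector("list", length(peaks))
  untested <- character(0)
  for (i in seq_along(peaks)) {
    idx <- if (!is.null(snp_sets)) snp_sets[[i]] else
      intersect(snpWindow(peaks[i], genotypes$snps$pos, half_width),
                keep_snps)
    if (!is.null(snp_sets)) idx <- intersect(idx, keep_snps)
    y <- as.numeric(counts[i, ])
    nf <- if (!is.null(null_fits)) null_fits[[i]] else NULL
    r <- scanPeak(y, peaks[i], design, genotypes, snp_idx = idx,
                  peak_id = peak_ids[i], method = method, nAGQ = nAGQ,
                  null_fit = nf)
    if (is.null(r)) untested <- c(untested, peak_ids[i]) else res[[i]] <- r
    if (verbose && i %% 50 == 0)
      message("scanned ", i, "/", length(peaks), " peaks")
  }
  records <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  leads <- records[records$is_lead, , drop = FALSE]
  list(records = records, leads = leads, untested = untested)
}

#' Call significant caQTLs from per-peak lead records
#'
#' Applies Storey q-values to the lead SNPs' per-peak Bonferroni-adjusted
#' p-values and flags peaks with `q < fdr` as significant caQTLs (cPeaks).
#'
#' @param leads data.frame of per-peak lead records with `p_bonf` (see
#'   [scanPeaks()]).
#' @param fdr q-value cutoff (default 0.10).
#' @param min_peaks guard on the number of peaks for a stable q-value
#'   estimate (default 50); lower it explicitly for toy data.
#' @return the input with `q` and `significant` columns and attribute
#'   `pi0`.
#' @export
callCaqtls <- function(leads, fdr = 0.10, min_peaks = 50L) {
  if (nrow(leads) < min_peaks)
    stop("only ", nrow(leads), " peaks; q-value estimation is unstable ",
         "below ", min_peaks, " - lower `min_peaks` explicitly if intended")
  sq <- storeyQvalue(leads$p_bonf)
  leads$q <- sq$q
  leads$significant <- leads$q < fdr
  attr(leads, "pi0") <- sq$pi0
  leads
}

#' Aggregate single-cell counts into pseudobulk
#'
#' Sums per-cell counts within cell groups (exact integer sums).  With
#' `dedup_by_visit = TRUE`, donors sampled at two visits contribute only
#' the visit with more cells (ties broken toward the earlier visit), the
#' repeated-measure rule used before pseudobulk QTL mapping.
#'
#' @param counts peaks x cells matrix or `SingleCellExperiment`.
#' @param cell_groups per-cell grouping factor (e.g. donor or
#'   donor-by-cell-type).
#' @param dedup_by_visit apply the repeated-visit rule.
#' @param donor,visit per-cell donor and visit vectors (required for
#'   dedup; taken from `colData` when `counts` is an SCE).
#' @return list with `pseudobulk` (group x peak integer matrix) and
#'   `cells_per_group`.
#' @export
aggregatePseudobulk <- function(counts, cell_groups, dedup_by_visit = FALSE,
                                donor = NULL, visit = NULL) {
  if (is(counts, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(counts)
    if (is.null(donor) && "donor" %in% colnames(cd)) donor <- cd$donor
    if (is.null(visit) && "visit" %in% colnames(cd)) visit <- cd$visit
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  keep <- rep(TRUE, ncol(counts))
  if (dedup_by_visit) {
    if (is.null(donor) || is.null(visit))
      stop("dedup_by_visit requires donor and visit")
    tab <- table(donor, visit)
    for (d in rownames(tab)) {
      vs <- colnames(tab)[tab[d, ] > 0]
      if (length(vs) > 1) {
        sizes <- tab[d, vs]
        best <- vs[which.max(sizes)]   # which.max takes the first = earlier
        keep[donor == d & visit != best] <- FALSE
      }
    }
  }
  grp <- factor(cell_groups[keep])
  sub <- counts[, keep, drop = FALSE]
  ind <- Matrix::sparseMatrix(i = seq_len(ncol(sub)),
                              j = as.integer(grp), x = 1,
                              dims = c(ncol(sub), nlevels(grp)))
  pb <- t(as.matrix(sub %*% ind))
  rownames(pb) <- levels(grp)
  colnames(pb) <- rownames(counts)
  storage.mode(pb) <- "integer"
  list(pseudobulk = pb, cells_per_group = as.integer(table(grp)))
}
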