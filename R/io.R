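#' Write a simulated dataset to plain-text files
#'
#' Emits the standard on-disk layout: `counts.mtx` (MatrixMarket, peaks x
#' cells), `peaks.bed` (0-based half-open), `cells.tsv` (cell metadata and
#' QC covariates), `dosages.tsv` (donor x SNP), `snps.tsv`, and
#' `truth.tsv` / `truth_loadings.tsv` / `truth_profiles.tsv` (planted
#' ground truth).
#'
#' @param sim result of [simulateCaqtlData()].
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
writeSimulatedData <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f <- function(x) file.path(dir, x)
  counts <- SummarizedExperiment::assay(sim$sce, "counts")
  Matrix::writeMM(counts, f("counts.mtx"))
  peaks <- SummarizedExperiment::rowRanges(sim$sce)
  write.table(data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                         start = GenomicRanges::start(peaks) - 1L,
                         end = GenomicRanges::end(peaks),
                         name = names(peaks)),
              f("peaks.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(as.data.frame(SummarizedExperiment::colData(sim$sce)),
              f("cells.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(donor = rownames(sim$genotypes$dosages),
                         sim$genotypes$dosages, check.names = FALSE),
              f("dosages.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$genotypes$snps, f("snps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tr <- sim$truth
  write.table(data.frame(peak = names(peaks),
                         causal_snp = tr$causal_snp_per_peak,
                         beta_true = tr$beta_true,
                         delta_true = tr$delta_true),
              f("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tr$topic_loadings_true, f("truth_loadings.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(tr$topic_profiles_true, f("truth_profiles.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list.files(dir, full.names = TRUE))
}

#' Read a dataset written by [writeSimulatedData()]
#'
#' @param dir directory holding `counts.mtx`, `peaks.bed`, `cells.tsv`,
#'   `dosages.tsv`, `snps.tsv`.
#' @return list with `sce` (a `SingleCellExperiment`) and `genotypes`.
#' @export
readCaqtlData <- function(dir) {
  f <- function(x) file.path(dir, x)
  counts <- methods::as(Matrix::readMM(f("counts.mtx")), "CsparseMatrix")
  bed <- read.delim(f("peaks.bed"), header = FALSE,
                    col.names = c("chrom", "start", "end", "name"))
  peaks <- GenomicRanges::GRanges(bed$chrom,
    IRanges::IRanges(start = bed$start + 1L, end = bed$end))
  names(peaks) <- bed$name
  cells <- read.delim(f("cells.tsv"))
  rownames(counts) <- bed$name
  colnames(counts) <- cells$cell_id
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), rowRanges = peaks,
    colData = S4Vectors::DataFrame(cells))
  dos <- read.delim(f("dosages.tsv"), check.names = FALSE)
  dosages <- as.matrix(dos[, -1, drop = FALSE])
  rownames(dosages) <- dos$donor
  snps <- read.delim(f("snps.tsv"))
  list(sce = sce,
       genotypes = list(dosages = dosages, snps = snps,
                        maf = snps$maf, ld_rho = NA_real_))
}

#' Read per-SNP summary statistics from a TSV file
#'
#' Expects the columns `snp`, `chrom`, `pos`, `ea`, `oa`, `beta`, `se`,
#' `p`, `maf`, `n`.  The reported p-values are checked against the
#' two-sided normal approximation of `beta/se` and a warning is issued when
#' they disagree by more than 10 percent relative (for p > 1e-300).
#'
#' @param path TSV file path.
#' @return data.frame of summary statistics.
#' @export
readSummaryStats <- function(path) {
  ss <- read.delim(path)
  need <- c("snp", "chrom", "pos", "beta", "se", "p")
  miss <- setdiff(need, colnames(ss))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(ss$se <= 0)) stop("se must be positive")
  p_wald <- 2 * pnorm(-abs(ss$beta / ss$se))
  chk <- p_wald > 1e-300 & ss$p > 1e-300
  bad <- abs(log(ss$p[chk]) - log(p_wald[chk])) / abs(log(p_wald[chk])) > 0.1
  if (any(bad))
    warning(sum(bad), " SNP(s) have p inconsistent with beta/se ",
            "(>10% relative on the log scale)")
  ss
}

#' Write QTL records with the standard column order
#'
#' @param records data.frame of QTL records (see [scanPeaks()]).
#' @param path output TSV path.
#' @export
writeQtlRecords <- function(records, path) {
  lead <- c("peak_id", "snp_id", "chrom", "pos", "distance", "beta",
            "se", "z", "p", "p_bonf", "q", "is_lead")
  cols <- c(intersect(lead, colnames(records)),
            setdiff(colnames(records), lead))
  write.table(records[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
}
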