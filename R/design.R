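#' Build the per-cell fixed/random design for sc-PME fitting
#'
#' Assembles the design shared by all peak-SNP fits: a z-scaled fixed
#' covariate matrix, a per-cell log-library-size offset, and donor and
#' library grouping factors.  In the full-scale analysis the covariates are
#' the top genotype PCs, top latent-embedding dimensions, TSS enrichment,
#' mitochondrial fraction and log10 unique fragments; for synthetic data the
#' three QC covariates suffice (the generator plants no PC/embedding
#' structure).
#'
#' @param sce a `SingleCellExperiment` (peaks x cells) with `colData`
#'   columns `donor`, `library` and the requested covariates, or `NULL` if
#'   all pieces are given explicitly.
#' @param covariates character vector of `colData` columns to z-scale into
#'   `X` (default the three QC covariates).
#' @param extra optional numeric matrix of additional per-cell covariates
#'   (e.g. genotype PCs, embedding dimensions); z-scaled as well.
#' @param offset per-cell log library size; defaults to the log `depth`
#'   column of `colData` (total fragments) when present, else log total
#'   in-peak counts (floored at 1).
#' @param donor,library grouping factors (defaults from `colData`).
#' @return list of class `CellDesign`: `X` (cells x m, each column mean 0
#'   sd 1), `offset`, `donor`, `library`, `n`, and sparse random-effect
#'   indicator matrices `Zd`, `Zl`.
#' @examples
#' sim <- simulateCaqtlData(simConfig(n_donors = 6, n_peaks = 10,
#'   cells_per_donor = c(10, 12), seed = 2))
#' d <- makeCellDesign(sim$sce)
#' colMeans(d$X)
#' @export
makeCellDesign <- function(sce = NULL,
                           covariates = c("TSSEnrichment", "MTratio",
                                          "log10nFrags"),
                           extra = NULL, offset = NULL,
                           donor = NULL, library = NULL) {
  if (!is.null(sce)) {
    cd <- SummarizedExperiment::colData(sce)
    if (is.null(donor)) donor <- cd$donor
    if (is.null(library)) library <- cd$library
    X <- as.matrix(as.data.frame(cd[, covariates, drop = FALSE]))
    if (is.null(offset)) {
      offset <- if ("depth" %in% colnames(cd)) log(cd$depth) else
        log(pmax(Matrix::colSums(SummarizedExperiment::assay(sce,
                                                             "counts")), 1))
    }
  } else {
    X <- NULL
  }
  if (!is.null(extra)) X <- cbind(X, as.matrix(extra))
  if (is.null(X) || !ncol(X)) stop("no covariates supplied")
  sds <- apply(X, 2, sd)
  if (any(sds < 1e-12))
    stop("constant covariate column(s): ",
         paste(colnames(X)[sds < 1e-12], collapse = ", "))
  X <- scale(X)
  attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  if (any(!is.finite(offset))) stop("offsets must be finite")
  donor <- factor(donor)
  library <- factor(library)
  n <- nrow(X)
  stopifnot(length(offset) == n, length(donor) == n, length(library) == n)
  Zd <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(donor),
                             x = 1, dims = c(n, nlevels(donor)))
  Zl <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(library),
                             x = 1, dims = c(n, nlevels(library)))
  structure(list(X = X, offset = as.numeric(offset), donor = donor,
                 library = library, n = n, Zd = Zd, Zl = Zl),
            class = "CellDesign")
}

#' Expand donor-level genotype dosages to cells
#'
#' @param dosages donor x SNP dosage matrix (rownames = donor ids).
#' @param donor per-cell donor factor/ids matching the rownames.
#' @param snp SNP column name or index.
#' @return numeric per-cell dosage vector.
#' @export
expandGenotype <- function(dosages, donor, snp) {
  idx <- match(as.character(donor), rownames(dosages))
  if (anyNA(idx)) stop("cell donors missing from dosage matrix")
  as.numeric(dosages[idx, snp])
}
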