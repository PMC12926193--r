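#' Aggregate peak-level scores into gene-level scores
#'
#' For each gene, scores of peaks overlapping the gene body are summed
#' directly, and scores of peaks whose center lies within `upstream_bp`
#' upstream of the TSS (strand-aware; body-overlapping peaks take
#' precedence) are added with a distance-decayed weight
#' \eqn{w(d) = e^{-d/decay}} (exponential kernel, the default) or
#' \eqn{w(d) = (1 + d/decay)^{-1}} (`kernel = "power"`), where `d` is the
#' distance from the peak center to the TSS.  Genes with no contributing
#' peak score 0.  When `peak_scores` is a matrix (peaks x topics), per-gene
#' Z-scores across topics (sample SD) are also returned.
#'
#' The aggregation is linear in the peak scores.
#'
#' @param peak_scores per-peak score vector, or peaks x topics matrix.
#' @param peaks `GRanges` of the peaks (or data.frame with `chrom`,
#'   `start`, `end`, 0-based half-open).
#' @param genes data.frame with `gene`, `chrom`, `start`, `end` (0-based
#'   half-open gene body), `strand` (`"+"`/`"-"`), `tss`.
#' @param upstream_bp upstream reach from the TSS (default 5000).
#' @param decay_bp decay length of the weight kernel (default 5000).
#' @param kernel `"exp"` (default) or `"power"`.
#' @return list with `scores` (gene x topic matrix, or single-column) and
#'   `z` (per-gene Z-scores across topics; NA rows for constant scores).
#' @examples
#' peaks <- data.frame(chrom = "chr1", start = c(1000, 6000),
#'                     end = c(1400, 6400))
#' genes <- data.frame(gene = "g1", chrom = "chr1", start = 6000,
#'                     end = 9000, strand = "+", tss = 6000)
#' geneScores(c(1, 2), peaks, genes)$scores
#' @export
geneScores <- function(peak_scores, peaks, genes, upstream_bp = 5000,
                       decay_bp = 5000, kernel = c("exp", "power")) {
  kernel <- match.arg(kernel)
  if (is(peaks, "GRanges")) {
    pk <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                     start = GenomicRanges::start(peaks) - 1L,
                     end = GenomicRanges::end(peaks))
  } else pk <- peaks
  S <- as.matrix(peak_scores)
  if (nrow(S) != nrow(pk)) stop("peak_scores and peaks disagree in length")
  center <- floor((pk$start + pk$end) / 2)
  w_fun <- switch(kernel,
                  exp = function(d) exp(-d / decay_bp),
                  power = function(d) (1 + d / decay_bp)^(-1))
  out <- matrix(0, nrow(genes), ncol(S),
                dimnames = list(genes$gene, colnames(S)))
  for (i in seq_len(nrow(genes))) {
    on_chr <- pk$chrom == genes$chrom[i]
    body <- on_chr & pk$start < genes$end[i] & pk$end > genes$start[i]
    d <- if (genes$strand[i] == "+") genes$tss[i] - center
         else center - genes$tss[i]
    upstream <- on_chr & !body & d > 0 & d <= upstream_bp
    acc <- colSums(S[body, , drop = FALSE])
    if (any(upstream))
      acc <- acc + colSums(S[upstream, , drop = FALSE] * w_fun(d[upstream]))
    out[i, ] <- acc
  }
  z <- if (ncol(out) > 1) {
    t(apply(out, 1, function(r)
      if (sd(r) > 0) (r - mean(r)) / sd(r) else rep(NA_real_, length(r))))
  } else NULL
  list(scores = out, z = z)
}
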