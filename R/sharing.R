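#' Cross-cell-type caQTL sharing from a peak x cell-type q-value matrix
#'
#' A peak's caQTL is significant in a focal cell type at `primary`
#' (q < 0.1 by default) and counted as shared with another cell type only
#' when that type's q-value clears the stricter `secondary` threshold.  The
#' default secondary threshold applies a Bonferroni correction of the
#' primary level over the other cell types: `primary / (ncol(q) - 1)`, i.e.
#' 0.1 / 4 = 0.025 for five cell types.  A peak's context count is 1 plus
#' the number of other types below `secondary`; a peak is "specific" when
#' its context count is 1.
#'
#' @param q_matrix numeric peak x cell-type matrix of q-values in \[0, 1\].
#' @param primary per-cell-type significance threshold (default 0.10).
#' @param secondary sharing threshold; default `primary / (ncol - 1)`.
#' @return list with `secondary` (the threshold used), `significant`
#'   (logical peak x type matrix at `primary`), `context_count` (per peak x
#'   focal type: NA where not significant), `specific` (logical, same
#'   shape), `overlap` (pairwise fraction of type-A-significant peaks also
#'   below `secondary` in type B).
#' @examples
#' q <- rbind(c(0.05, 0.024, 0.5, 0.5, 0.5))
#' colnames(q) <- c("B", "CD4", "CD8", "NK", "Mono")
#' sharingContexts(q)$context_count
#' @export
sharingContexts <- function(q_matrix, primary = 0.10, secondary = NULL) {
  q_matrix <- as.matrix(q_matrix)
  if (any(q_matrix < 0 | q_matrix > 1, na.rm = TRUE))
    stop("q-values must lie in [0, 1]")
  n_type <- ncol(q_matrix)
  if (is.null(secondary)) secondary <- primary / (n_type - 1)
  sig <- q_matrix < primary
  shared <- q_matrix < secondary
  context_count <- matrix(NA_integer_, nrow(q_matrix), n_type,
                          dimnames = dimnames(q_matrix))
  for (ty in seq_len(n_type)) {
    idx <- which(sig[, ty])
    if (length(idx))
      context_count[idx, ty] <-
        1L + rowSums(shared[idx, -ty, drop = FALSE], na.rm = TRUE)
  }
  overlap <- matrix(NA_real_, n_type, n_type,
                    dimnames = list(colnames(q_matrix), colnames(q_matrix)))
  for (a in seq_len(n_type)) for (b in seq_len(n_type)) {
    if (a == b) { overlap[a, b] <- 1; next }
    ia <- which(sig[, a])
    if (length(ia)) overlap[a, b] <- mean(shared[ia, b], na.rm = TRUE)
  }
  list(secondary = secondary, significant = sig,
       context_count = context_count, specific = context_count == 1L,
       overlap = overlap)
}

#' Pairwise pi1 replication statistic
#'
#' Storey's pi1 applied to the p-values, in cell type B, of the peaks whose
#' caQTLs are significant in cell type A: the estimated fraction of type-A
#' caQTLs replicating in type B.
#'
#' @param p_in_b p-values in cell type B for the type-A-significant peaks
#'   (>= 20 values).
#' @return scalar pi1 in \[0, 1\].
#' @export
pairwisePi1 <- function(p_in_b) {
  if (length(p_in_b) < 20L)
    stop("need >= 20 p-values for a stable pi1 estimate")
  max(min(storeyPi1(p_in_b), 1), 0)
}

#' Fisher exact enrichment of hits in a set against a background
#'
#' Wraps the two-sided Fisher exact test on the 2x2 table
#' \[hits_in, set_size - hits_in; hits_out, bg_size - hits_out\], returning
#' the conditional-MLE odds ratio, p-value and 95 percent CI.
#'
#' @param hits_in hits inside the set; `set_size` its total size.
#' @param hits_out hits in the background; `bg_size` its total size.
#' @return list with `OR`, `p`, `CI` (length 2), `table`.
#' @examples
#' fisherEnrichment(20, 100, 5, 100)
#' @export
fisherEnrichment <- function(hits_in, set_size, hits_out, bg_size) {
  tab <- matrix(c(hits_in, set_size - hits_in,
                  hits_out, bg_size - hits_out), 2, 2)
  if (any(tab < 0)) stop("negative cell in 2x2 table")
  ft <- fisher.test(tab)
  list(OR = unname(ft$estimate), p = ft$p.value,
       CI = as.numeric(ft$conf.int), table = tab)
}
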