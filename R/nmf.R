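## Internal: coerce the various count containers to a dense cells x peaks
## matrix.  A SummarizedExperiment stores peaks in rows, so it is transposed.
.cellsByPeaks <- function(counts) {
  if (is(counts, "SummarizedExperiment"))
    counts <- Matrix::t(SummarizedExperiment::assay(counts, "counts"))
  Y <- as.matrix(counts)
  if (any(Y < 0) || any(Y != round(Y)))
    stop("counts must be non-negative integers")
  Y
}

## Poisson NMF objective: log-likelihood up to the sum(lfactorial(y)) term.
.nmfObjective <- function(Y, M) {
  M <- pmax(M, 1e-300)
  sum(Y * log(M) - M)
}

#' Down-sample cells for topic-model fitting, rescuing all-zero peaks
#'
#' Randomly samples `n_cells` cells; any peak left with zero counts in the
#' sample is "rescued" by appending one cell in which it is non-zero, so
#' every peak keeps at least one non-zero count and the fitted factors can
#' later be projected to all cells.  A peak with zero counts in every cell
#' cannot be rescued and raises an error naming it.
#'
#' @param counts a `SingleCellExperiment` or peaks x cells matrix.
#' @param n_cells target number of sampled cells.
#' @param seed integer seed.
#' @return list with `counts` (the peaks x cells subset, same container
#'   orientation), `cell_index` (columns of the input retained; length >=
#'   `n_cells` when rescue cells were appended).
#' @export
downsampleForFit <- function(counts, n_cells, seed = 1L) {
  mat <- if (is(counts, "SummarizedExperiment"))
    SummarizedExperiment::assay(counts, "counts") else counts
  if (n_cells > ncol(mat)) stop("n_cells exceeds the number of cells")
  peak_tot <- Matrix::rowSums(mat)
  if (any(peak_tot == 0)) {
    bad <- rownames(mat)[which(peak_tot == 0)[1]]
    if (is.null(bad)) bad <- paste0("row ", which(peak_tot == 0)[1])
    stop("peak with zero counts in all cells: ", bad)
  }
  set.seed(seed)
  idx <- sort(sample.int(ncol(mat), n_cells))
  covered <- Matrix::rowSums(mat[, idx, drop = FALSE]) > 0
  rescue <- integer(0)
  for (j in which(!covered)) {
    cand <- setdiff(which(mat[j, ] > 0), c(idx, rescue))
    if (!length(cand)) next  # already rescued by an earlier peak's cell
    rescue <- c(rescue, cand[sample.int(length(cand), 1)])
    if (all(Matrix::rowSums(mat[, c(idx, rescue), drop = FALSE]) > 0))
      break
  }
  idx <- c(idx, sort(rescue))
  list(counts = counts[, idx], cell_index = idx)
}

## One EM (multiplicative) sweep; returns updated L, F.
.emSweep <- function(Y, L, F) {
  M <- pmax(L %*% t(F), 1e-300)
  L <- L * ((Y / M) %*% F) / rep(pmax(colSums(F), 1e-300), each = nrow(L))
  L <- pmax(L, 1e-15)     # keep multiplicative updates away from absorbing 0
  M <- pmax(L %*% t(F), 1e-300)
  F <- F * (t(Y / M) %*% L) / rep(pmax(colSums(L), 1e-300), each = nrow(F))
  F <- pmax(F, 1e-15)
  list(L = L, F = F)
}

## One cyclic-coordinate-descent sweep: per topic column, a projected Newton
## update of L[,k] then F[,k], with step halving so the objective never
## decreases.
.ccdSweep <- function(Y, L, F) {
  K <- ncol(L)
  M <- pmax(L %*% t(F), 1e-300)
  obj <- .nmfObjective(Y, M)
  update_col <- function(v, other, Yd, M, obj) {
    ## v: column being updated (length n); other: fixed factor (length m);
    ## M is n x m with M = rest + v o^T
    grad <- sum(other) - as.vector((Yd / M) %*% other)
    hess <- as.vector((Yd / M^2) %*% other^2)
    step <- grad / hess
    step[!is.finite(step) | hess <= 0] <- 0
    repeat {
      vn <- pmax(v - step, 0)
      Mn <- pmax(M + outer(vn - v, other), 1e-300)
      objn <- .nmfObjective(Yd, Mn)
      if (objn >= obj - 1e-12 || max(abs(step)) < 1e-14)
        return(list(v = vn, M = Mn, obj = objn))
      step <- step / 2
    }
  }
  for (k in seq_len(K)) {
    up <- update_col(L[, k], F[, k], Y, M, obj)
    L[, k] <- up$v; M <- up$M; obj <- up$obj
    upf <- update_col(F[, k], L[, k], t(Y), t(M), obj)
    F[, k] <- upf$v; M <- t(upf$M); obj <- upf$obj
  }
  list(L = L, F = F, obj = obj)
}

#' Fit a Poisson non-negative matrix factorization (topic model)
#'
#' Factorizes a cell-by-peak fragment count matrix as \eqn{Y \approx L F^T}
#' under the Poisson likelihood, with `n_main` multiplicative EM updates
#' followed by `n_refine` cyclic coordinate-descent sweeps (projected
#' single-variable Newton steps with step halving, so the objective is
#' monotone through both phases).  Updates stop early when the relative
#' objective change drops below `tol`.
#'
#' @param counts cells x peaks matrix, or a `SingleCellExperiment` /
#'   peaks x cells `SummarizedExperiment` (transposed internally).
#' @param K number of topics (>= 1).
#' @param n_main EM iterations (default 100).
#' @param n_refine coordinate-descent iterations (default 200).
#' @param seed seed for the random non-negative initialization.
#' @param init optional list with starting `L`, `F` (used by
#'   [expandAndRefit()]).
#' @param tol relative-objective early-stopping tolerance (default 1e-10).
#' @return a [PoissonNMFFit-class].
#' @examples
#' Y <- matrix(rpois(600, 2), 30, 20)
#' fit <- fitPoissonNMF(Y, K = 2, n_main = 20, n_refine = 10)
#' @export
fitPoissonNMF <- function(counts, K, n_main = 100L, n_refine = 200L,
                          seed = 1L, init = NULL, tol = 1e-10) {
  Y <- .cellsByPeaks(counts)
  n <- nrow(Y); m <- ncol(Y)
  if (is.null(init)) {
    if (K < 1) stop("K must be >= 1")
    set.seed(seed)
    scale0 <- sqrt(mean(Y) / K)
    L <- matrix(runif(n * K, 0.5, 1.5) * scale0, n, K)
    F <- matrix(runif(m * K, 0.5, 1.5) * scale0, m, K)
  } else {
    L <- init$L; F <- init$F; K <- ncol(L)
  }
  objective <- .nmfObjective(Y, L %*% t(F))
  for (it in seq_len(n_main)) {
    s <- .emSweep(Y, L, F)
    L <- s$L; F <- s$F
    objective <- c(objective, .nmfObjective(Y, L %*% t(F)))
    nobj <- length(objective)
    if (abs(objective[nobj] - objective[nobj - 1]) <
        tol * abs(objective[nobj])) break
  }
  for (it in seq_len(n_refine)) {
    s <- .ccdSweep(Y, L, F)
    L <- s$L; F <- s$F
    objective <- c(objective, s$obj)
    nobj <- length(objective)
    if (abs(objective[nobj] - objective[nobj - 1]) <
        tol * abs(objective[nobj])) break
  }
  dimnames(L) <- list(rownames(Y), sprintf("k%d", seq_len(K)))
  dimnames(F) <- list(colnames(Y), sprintf("k%d", seq_len(K)))
  new("PoissonNMFFit", L = L, F = F, objective = objective,
      K = as.integer(K))
}

#' Expand a Poisson NMF fit to more topics and refit
#'
#' Implements the incremental-K ladder: the existing loading and factor
#' matrices are propagated and padded with new uniform columns (1/K_new for
#' loadings, 1/n_peaks for factors), then refit with `n_main` EM updates
#' followed by two consecutive runs of `n_refine` coordinate-descent
#' updates.  Previous topic columns keep their original positions, so topic
#' i of the old fit is comparable to topic i of the new fit.
#'
#' @param fit a [PoissonNMFFit-class].
#' @param K_new new topic count (> `fit@K`).
#' @param counts the count matrix used for refitting (see
#'   [fitPoissonNMF()]).
#' @param n_main,n_refine iteration schedule (defaults 100 and 200).
#' @return a [PoissonNMFFit-class] with `K_new` topics.
#' @export
expandAndRefit <- function(fit, K_new, counts, n_main = 100L,
                           n_refine = 200L) {
  if (K_new <= fit@K) stop("K_new must exceed the current K")
  Y <- .cellsByPeaks(counts)
  n_add <- K_new - fit@K
  L <- cbind(fit@L, matrix(1 / K_new, nrow(fit@L), n_add))
  F <- cbind(fit@F, matrix(1 / nrow(fit@F), nrow(fit@F), n_add))
  f1 <- fitPoissonNMF(Y, K_new, n_main = n_main, n_refine = n_refine,
                      init = list(L = L, F = F))
  f2 <- fitPoissonNMF(Y, K_new, n_main = 0L, n_refine = n_refine,
                      init = list(L = f1@L, F = f1@F))
  new("PoissonNMFFit", L = f2@L, F = f2@F,
      objective = c(f1@objective, f2@objective[-1]),
      K = as.integer(K_new))
}

#' Project topic loadings onto new cells with fixed factors
#'
#' With the peak factor matrix held fixed, each cell's loading vector
#' maximizes its own Poisson likelihood — an independent convex problem per
#' cell — solved here by multiplicative EM updates to convergence.  An
#' all-zero cell has a flat likelihood and receives the uniform loading
#' 1/K with a warning.
#'
#' @param F peaks x K non-negative factor matrix (`peakScores()` of a fit).
#' @param counts_new counts for the new cells (cells x peaks matrix or
#'   `SummarizedExperiment`).
#' @param maxit,tol convergence controls.
#' @return cells x K loading matrix (unnormalized Poisson intensities; for
#'   topic proportions convert the combined fit with [toMultinomial()], or
#'   normalize rows).
#' @export
projectLoadings <- function(F, counts_new, maxit = 500L, tol = 1e-10) {
  Y <- .cellsByPeaks(counts_new)
  if (any(F < 0)) stop("F must be non-negative")
  K <- ncol(F)
  n <- nrow(Y)
  L <- matrix(rowSums(Y) / sum(F) + 1e-8, n, K)
  sF <- colSums(F)
  for (it in seq_len(maxit)) {
    M <- pmax(L %*% t(F), 1e-300)
    Lnew <- L * ((Y / M) %*% F) / rep(sF, each = n)
    if (max(abs(Lnew - L)) < tol * (1 + max(L))) { L <- Lnew; break }
    L <- Lnew
  }
  zero <- rowSums(Y) == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero cell(s) assigned uniform loading 1/K")
    L[zero, ] <- 1 / K
  }
  dimnames(L) <- list(rownames(Y), colnames(F))
  L
}

#' Convert a Poisson NMF fit to the multinomial topic model
#'
#' Rescales the factors into per-topic peak probabilities and the loadings
#' into per-cell topic proportions: with \eqn{u_k = \sum_j F_{jk}},
#' \eqn{\Phi_{jk} = F_{jk}/u_k} and
#' \eqn{Q_{ik} = L_{ik} u_k / \sum_{k'} L_{ik'} u_{k'}}.
#'
#' @param fit a [PoissonNMFFit-class].
#' @return a [TopicModel-class].
#' @export
toMultinomial <- function(fit) {
  u <- colSums(fit@F)
  if (any(u == 0)) stop("topic with all-zero factor column (u_k = 0)")
  Phi <- sweep(fit@F, 2, u, "/")
  Qraw <- sweep(fit@L, 2, u, "*")
  rs <- rowSums(Qraw)
  if (any(rs == 0)) {
    Qraw[rs == 0, ] <- 1 / fit@K
    rs[rs == 0] <- 1
  }
  Q <- Qraw / rs
  new("TopicModel", Q = Q, Phi = Phi, K = fit@K)
}

#' Select the top-scoring peaks of a topic
#'
#' Returns the `ceiling(frac * n_peaks)` peaks with the largest score in
#' the given topic; ties at the selection boundary are broken by peak
#' (genomic row) order, so the set size is invariant.
#'
#' @param Phi peaks x K score matrix (`peakScores()` of a [TopicModel-class]).
#' @param topic topic index or name.
#' @param frac fraction of peaks to keep, in (0, 1\] (default 0.10).
#' @return integer vector of peak row indices, in decreasing score order.
#' @export
selectTopPeaks <- function(Phi, topic, frac = 0.10) {
  if (frac <= 0 || frac > 1) stop("frac must lie in (0, 1]")
  score <- Phi[, topic]
  n_top <- ceiling(frac * nrow(Phi))
  order(-score, seq_along(score))[seq_len(n_top)]
}

#' Flag topics tracking technical/QC variation
#'
#' Computes the Spearman correlation of each topic's loadings with each QC
#' covariate and flags topics whose strongest absolute correlation exceeds
#' `threshold`.  Such topics typically capture batch or data-quality
#' variation rather than cell biology and can be excluded downstream.
#'
#' @param Q cells x K loading matrix.
#' @param qc cells x c data.frame/matrix of QC covariates.
#' @param threshold absolute-correlation cutoff (default 0.3).
#' @return data.frame per topic: `max_abs_rho`, `which_covariate`,
#'   `technical`.
#' @export
flagTechnicalTopics <- function(Q, qc, threshold = 0.3) {
  qc <- as.matrix(qc)
  rho <- suppressWarnings(cor(Q, qc, method = "spearman"))
  i <- apply(abs(rho), 1, which.max)
  data.frame(topic = colnames(Q),
             max_abs_rho = abs(rho)[cbind(seq_len(nrow(rho)), i)],
             which_covariate = colnames(qc)[i],
             technical = abs(rho)[cbind(seq_len(nrow(rho)), i)] > threshold,
             row.names = NULL)
}
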