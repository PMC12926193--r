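#' @import methods
#' @importFrom stats pnorm pchisq qnorm rnorm rpois rbinom runif rlnorm
#'   rgamma rexp quantile sd cor var median complete.cases p.adjust
#'   wilcox.test fisher.test glm poisson coef vcov smooth.spline predict
#'   logLik anova offset setNames optimize cor.test aggregate binomial
#'   ks.test plogis
#' @importFrom utils head tail read.delim write.table
NULL

#' Poisson NMF model fit
#'
#' Holds the result of fitting a rank-K Poisson non-negative matrix
#' factorization to a cell-by-peak fragment count matrix \eqn{Y \approx L F^T},
#' where `L` (cells x K) and `F` (peaks x K) are non-negative.  The Poisson
#' log-likelihood (up to a constant not depending on the factors) is recorded
#' per update sweep in `objective`.
#'
#' @slot L numeric matrix, cells x K, non-negative loadings.
#' @slot F numeric matrix, peaks x K, non-negative factors.
#' @slot objective numeric vector of per-iteration Poisson log-likelihood
#'   values (up to constant), non-decreasing during the EM phase.
#' @slot K integer, number of topics.
#'
#' @seealso [fitPoissonNMF()], [toMultinomial()]
#' @export
setClass("PoissonNMFFit",
  representation(L = "matrix", F = "matrix", objective = "numeric",
                 K = "integer"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@L) != object@K || ncol(object@F) != object@K)
      msg <- c(msg, "L and F must have K columns")
    if (any(object@L < 0) || any(object@F < 0))
      msg <- c(msg, "factors must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' Multinomial topic model
#'
#' The multinomial ("grade of membership") parameterization of a Poisson NMF
#' fit: `Q` holds per-cell topic proportions (loadings, rows sum to 1) and
#' `Phi` per-topic peak probabilities (scores, columns sum to 1).
#'
#' @slot Q numeric matrix, cells x K topic loadings; each row sums to 1.
#' @slot Phi numeric matrix, peaks x K peak scores; each column sums to 1.
#' @slot K integer, number of topics.
#'
#' @seealso [toMultinomial()], [projectLoadings()], [selectTopPeaks()]
#' @export
setClass("TopicModel",
  representation(Q = "matrix", Phi = "matrix", K = "integer"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@Q) != object@K || ncol(object@Phi) != object@K)
      msg <- c(msg, "Q and Phi must have K columns")
    if (any(object@Q < 0) || any(object@Phi < 0))
      msg <- c(msg, "Q and Phi must be non-negative")
    if (nrow(object@Q) > 0 &&
        max(abs(rowSums(object@Q) - 1)) > 1e-6)
      msg <- c(msg, "rows of Q must sum to 1")
    if (nrow(object@Phi) > 0 &&
        max(abs(colSums(object@Phi) - 1)) > 1e-6)
      msg <- c(msg, "columns of Phi must sum to 1")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "PoissonNMFFit", function(object) {
  cat("PoissonNMFFit: ", nrow(object@L), " cells x ", nrow(object@F),
      " peaks, K = ", object@K, "\n", sep = "")
  if (length(object@objective))
    cat("  final objective (Poisson loglik, up to const): ",
        format(tail(object@objective, 1)), " after ",
        length(object@objective), " recorded updates\n", sep = "")
})

setMethod("show", "TopicModel", function(object) {
  cat("TopicModel: ", nrow(object@Q), " cells x ", nrow(object@Phi),
      " peaks, K = ", object@K, " topics\n", sep = "")
})

#' @describeIn TopicModel-accessors number of topics
#' @export
setGeneric("nTopics", function(x) standardGeneric("nTopics"))

#' @describeIn TopicModel-accessors cell x K topic loading matrix
#' @export
setGeneric("topicLoadings", function(x) standardGeneric("topicLoadings"))

#' @describeIn TopicModel-accessors peak x K topic score matrix
#' @export
setGeneric("peakScores", function(x) standardGeneric("peakScores"))

#' Accessors for topic-model objects
#'
#' @param x a [TopicModel-class] or [PoissonNMFFit-class] object.
#' @return `nTopics` the number of topics; `topicLoadings` the cells x K
#'   loading matrix (`Q` for a `TopicModel`, `L` for a `PoissonNMFFit`);
#'   `peakScores` the peaks x K score/factor matrix.
#' @name TopicModel-accessors
NULL

#' @rdname TopicModel-accessors
#' @export
setMethod("nTopics", "TopicModel", function(x) x@K)
#' @rdname TopicModel-accessors
#' @export
setMethod("nTopics", "PoissonNMFFit", function(x) x@K)
#' @rdname TopicModel-accessors
#' @export
setMethod("topicLoadings", "TopicModel", function(x) x@Q)
#' @rdname TopicModel-accessors
#' @export
setMethod("topicLoadings", "PoissonNMFFit", function(x) x@L)
#' @rdname TopicModel-accessors
#' @export
setMethod("peakScores", "TopicModel", function(x) x@Phi)
#' @rdname TopicModel-accessors
#' @export
setMethod("peakScores", "PoissonNMFFit", function(x) x@F)

#' @rdname TopicModel-accessors
#' @export
objectiveTrace <- function(x) {
  stopifnot(is(x, "PoissonNMFFit"))
  x@objective
}
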