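## Distributional primitives for the Gibbs sampler: matrix-variate normal
## draws with possibly rank-deficient row covariance, inverse-Wishart draws,
## and Gaussian conditioning for missing-trait imputation.

.checkSPD <- function(S, what = "matrix") {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8 * max(abs(S), 1))
    stop(sprintf("%s must be symmetric", what))
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) stop(sprintf("%s is not positive definite", what))
  ch
}

#' Draw from a centered matrix-variate normal distribution
#'
#' Samples \eqn{G \sim MN(0, U, V)}, i.e. \eqn{vec(G) \sim N(0, V \otimes U)},
#' where U is an m x m row covariance (allowed to be positive semidefinite
#' and rank deficient -- repaired kernels are accepted) and V an SPD column
#' (trait) covariance. The row covariance is handled through its symmetric
#' eigendecomposition, never Cholesky, so PSD inputs work.
#'
#' @param n number of independent draws.
#' @param rowCov m x m PSD row covariance (or a \linkS4class{KernelMatrix}).
#' @param colCov nT x nT SPD column covariance.
#' @param seed optional integer seed for reproducibility.
#' @return an m x nT matrix when \code{n = 1}, else an m x nT x n array.
#' @examples
#' g <- rMatrixNormal(1, diag(3), diag(2), seed = 1)
#' @export
rMatrixNormal <- function(n = 1, rowCov, colCov, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is(rowCov, "KernelMatrix")) rowCov <- rowCov@values
  rowCov <- as.matrix(rowCov)
  colCov <- as.matrix(colCov)
  m <- nrow(rowCov)
  nT <- nrow(colCov)
  es <- eigen((rowCov + t(rowCov)) / 2, symmetric = TRUE)
  tolneg <- 1e-8 * max(abs(es$values), 1)
  if (min(es$values) < -tolneg)
    stop(sprintf("row covariance is not PSD (min eigenvalue %.3g)",
                 min(es$values)))
  keep <- es$values > tolneg
  r <- sum(keep)
  Lc <- .checkSPD(colCov, "column covariance")
  out <- array(0, dim = c(m, nT, n))
  if (r > 0) {
    A <- es$vectors[, keep, drop = FALSE] %*% diag(sqrt(es$values[keep]), r)
    for (i in seq_len(n)) {
      Z <- matrix(rnorm(r * nT), r, nT)
      out[, , i] <- A %*% Z %*% Lc
    }
  }
  if (n == 1) matrix(out[, , 1], m, nT) else out
}

#' Draw from an inverse-Wishart distribution
#'
#' Parameterised so that for \eqn{\Sigma \sim IW(\nu, S)} the mean is
#' \eqn{S / (\nu - p - 1)} (for \eqn{\nu > p + 1}); this is the convention in
#' which S is the prior scale matrix and \eqn{\nu} the degrees of freedom of
#' the quoted Gibbs conditionals. Sampled via the standard
#' Wishart-of-the-inverse route: \eqn{W \sim Wishart(\nu, S^{-1})},
#' \eqn{\Sigma = W^{-1}}.
#'
#' @param n number of draws.
#' @param df degrees of freedom \eqn{\nu > p - 1}.
#' @param scale p x p SPD scale matrix S.
#' @param seed optional integer seed.
#' @return a p x p matrix when \code{n = 1}, else a p x p x n array.
#' @examples
#' rInvWishart(1, df = 10, scale = diag(2), seed = 1)
#' @export
rInvWishart <- function(n = 1, df, scale, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scale <- as.matrix(scale)
  p <- nrow(scale)
  if (df <= p - 1) stop(sprintf("df must exceed p - 1 = %d", p - 1))
  .checkSPD(scale, "scale matrix")
  W <- stats::rWishart(n, df, chol2inv(chol(scale)))
  out <- array(0, dim = dim(W))
  for (i in seq_len(n)) {
    Si <- chol2inv(chol(W[, , i]))
    out[, , i] <- (Si + t(Si)) / 2
  }
  dimnames(out) <- list(rownames(scale), colnames(scale), NULL)
  if (n == 1) matrix(out[, , 1], p, p, dimnames = dimnames(scale)) else out
}

#' Gaussian conditional distribution of unobserved traits
#'
#' Partitions an nT-variate normal \eqn{N(\mu, \Sigma)} into observed and
#' missing coordinates and returns the conditional distribution of the
#' missing block given the observed values:
#' \deqn{\mu_m + \Sigma_{mo} \Sigma_{oo}^{-1} (y_o - \mu_o), \quad
#'       \Sigma_{mm} - \Sigma_{mo} \Sigma_{oo}^{-1} \Sigma_{om}.}
#' With no observed coordinates the marginal (mean, cov) is returned; with
#' all coordinates observed the missing block is empty.
#'
#' @param mean length-nT mean vector.
#' @param cov nT x nT SPD covariance.
#' @param observedIdx integer (or logical) indices of observed coordinates.
#' @param observedValues values at \code{observedIdx}.
#' @return list with \code{missingIdx}, \code{mean} (conditional mean of the
#'   missing block) and \code{cov} (its conditional covariance).
#' @examples
#' conditionalNormal(c(0, 0), matrix(c(1, .5, .5, 1), 2), 2, 2.0)
#' @export
conditionalNormal <- function(mean, cov, observedIdx, observedValues) {
  cov <- as.matrix(cov)
  nT <- length(mean)
  if (is.logical(observedIdx)) observedIdx <- which(observedIdx)
  observedIdx <- as.integer(observedIdx)
  if (length(observedIdx) != length(observedValues))
    stop("observedIdx and observedValues lengths differ")
  missIdx <- setdiff(seq_len(nT), observedIdx)
  if (length(observedIdx) == 0)
    return(list(missingIdx = missIdx, mean = mean, cov = cov))
  Soo <- cov[observedIdx, observedIdx, drop = FALSE]
  ch <- tryCatch(chol(Soo), error = function(e)
    stop("observed-block covariance is numerically singular: ",
         conditionMessage(e)))
  if (length(missIdx) == 0)
    return(list(missingIdx = integer(0),
                mean = numeric(0),
                cov = matrix(0, 0, 0)))
  Smo <- cov[missIdx, observedIdx, drop = FALSE]
  W <- Smo %*% chol2inv(ch)
  condMean <- mean[missIdx] + drop(W %*% (observedValues - mean[observedIdx]))
  condCov <- cov[missIdx, missIdx, drop = FALSE] - W %*% t(Smo)
  condCov <- (condCov + t(condCov)) / 2
  list(missingIdx = missIdx, mean = condMean, cov = condCov)
}
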