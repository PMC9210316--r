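## Marker scaling and the four kernels. All kernels consume the same scaled
## matrix: columns centered, polymorphic columns at unit (population) variance,
## whole matrix divided by sqrt(p). Under that convention gamma = 1 is a
## sensible default for the Gaussian kernel because squared row distances are
## O(1) whatever the marker count.

#' Scale a marker matrix for kernel construction
#'
#' Centers every marker column to mean zero, standardises each polymorphic
#' column to unit population variance (monomorphic columns become all-zero),
#' and divides the whole matrix by \code{sqrt(p)} so that row inner products
#' and distances are O(1) regardless of the number of markers. After scaling,
#' every column has mean 0 and every originally polymorphic column has
#' population variance \code{1/p}.
#'
#' @param raw a \linkS4class{MarkerMatrix} of raw codes (no missing values).
#' @return a scaled \linkS4class{MarkerMatrix}.
#' @examples
#' m <- MarkerMatrix(matrix(c(0, 2), 2, 1))
#' values(scaleMarkers(m))   # -1, 1
#' @export
scaleMarkers <- function(raw) {
  stopifnot(is(raw, "MarkerMatrix"))
  X <- raw@values
  if (nrow(X) < 2) stop("need at least 2 lines to scale markers")
  if (anyNA(X)) stop("marker matrix contains missing values")
  if (raw@scaled) return(raw)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, `-`)
  sdev <- sqrt(colMeans(Xc^2))         # population sd
  poly <- sdev > 0
  Xc[, poly] <- sweep(Xc[, poly, drop = FALSE], 2L, sdev[poly], `/`)
  Xc[, !poly] <- 0
  Xc <- Xc / sqrt(ncol(X))
  new("MarkerMatrix", values = Xc, scaled = TRUE)
}

.ensureScaled <- function(X) {
  if (!X@scaled) {
    warning("marker matrix is not scaled; scaling automatically")
    X <- scaleMarkers(X)
  }
  X
}

#' Linear (GBLUP) kernel
#'
#' \eqn{K_{ij} = x_i^T x_j} on the scaled marker rows: the VanRaden-style
#' genomic relationship matrix used by multitrait GBLUP.
#'
#' @param X a scaled \linkS4class{MarkerMatrix} (unscaled input triggers a
#'   warning and automatic scaling).
#' @return a \linkS4class{KernelMatrix}.
#' @export
linearKernel <- function(X) {
  X <- .ensureScaled(X)
  KernelMatrix(tcrossprod(X@values), rowIds = rownames(X@values))
}

#' Polynomial kernel
#'
#' \eqn{K_{ij} = (\gamma\, x_i^T x_j + a)^d} with defaults \eqn{\gamma = 1},
#' \eqn{a = 0}, \eqn{d = 3}. With \eqn{\gamma = 1, a = 0, d = 1} this is the
#' linear kernel exactly.
#'
#' @param X a scaled \linkS4class{MarkerMatrix}.
#' @param gamma positive scale on the inner product.
#' @param offset real offset \eqn{a}.
#' @param degree positive integer exponent \eqn{d}.
#' @return a \linkS4class{KernelMatrix}.
#' @export
polynomialKernel <- function(X, gamma = 1, offset = 0, degree = 3) {
  if (length(degree) != 1 || degree < 1 || degree != round(degree))
    stop("degree must be a positive integer")
  if (gamma <= 0) stop("gamma must be positive")
  X <- .ensureScaled(X)
  K <- (gamma * tcrossprod(X@values) + offset)^degree
  KernelMatrix(K, rowIds = rownames(X@values))
}

#' Sigmoid kernel
#'
#' \eqn{K_{ij} = \tanh(x_i^T x_j + a)}; entries lie strictly in (-1, 1). The
#' result is not guaranteed positive semidefinite, so it must pass through
#' \code{\link{spectralDecompose}} before use as a covariance.
#'
#' @param X a scaled \linkS4class{MarkerMatrix}.
#' @param offset real offset \eqn{a} (default 0, matching the polynomial
#'   kernel's default and tanh's natural zero).
#' @return a \linkS4class{KernelMatrix}, possibly indefinite.
#' @export
sigmoidKernel <- function(X, offset = 0) {
  X <- .ensureScaled(X)
  KernelMatrix(tanh(tcrossprod(X@values) + offset),
               rowIds = rownames(X@values))
}

#' Gaussian (radial basis function) kernel
#'
#' \eqn{K_{ij} = \exp(-\gamma \|x_i - x_j\|^2)} on the scaled marker rows,
#' with \eqn{\gamma = 1} by default (the scaling makes distances O(1)).
#' The diagonal is exactly 1.
#'
#' @param X a scaled \linkS4class{MarkerMatrix}.
#' @param gamma positive bandwidth parameter.
#' @return a positive semidefinite \linkS4class{KernelMatrix}.
#' @export
gaussianKernel <- function(X, gamma = 1) {
  if (length(gamma) != 1 || gamma <= 0) stop("gamma must be positive")
  X <- .ensureScaled(X)
  G <- tcrossprod(X@values)
  sq <- diag(G)
  D2 <- pmax(outer(sq, sq, `+`) - 2 * G, 0)
  K <- exp(-gamma * D2)
  diag(K) <- 1
  KernelMatrix(K, rowIds = rownames(X@values))
}

#' Build a marker kernel by name
#'
#' Dispatcher over the four kernels; \code{"brr"} and \code{"gblup"} are
#' aliases of the linear kernel (Bayesian ridge regression on markers is
#' posterior-predictive-equivalent to linear-kernel GBLUP).
#'
#' @param X a scaled \linkS4class{MarkerMatrix}.
#' @param kernel one of \code{"linear"}, \code{"gaussian"},
#'   \code{"polynomial"}, \code{"sigmoid"} (aliases \code{"brr"},
#'   \code{"gblup"}, \code{"gk"}, \code{"pk"}, \code{"sk"}).
#' @param gamma,offset,degree kernel hyperparameters (used where relevant).
#' @return a \linkS4class{KernelMatrix}.
#' @export
buildKernel <- function(X, kernel = c("linear", "gaussian", "polynomial",
                                      "sigmoid", "brr", "gblup", "gk", "pk",
                                      "sk"),
                        gamma = 1, offset = 0, degree = 3) {
  kernel <- match.arg(kernel)
  kernel <- switch(kernel, brr = "linear", gblup = "linear", gk = "gaussian",
                   pk = "polynomial", sk = "sigmoid", kernel)
  switch(kernel,
         linear = linearKernel(X),
         gaussian = gaussianKernel(X, gamma = gamma),
         polynomial = polynomialKernel(X, gamma = gamma, offset = offset,
                                       degree = degree),
         sigmoid = sigmoidKernel(X, offset = offset))
}

#' Expand a line-level kernel to line-by-environment cells
#'
#' Returns \eqn{K_L = Z_L K_l Z_L^T}: the n x n cell-level kernel whose
#' (c, c') entry is the line kernel entry for the lines of cells c and c'.
#' Computed by direct indexing rather than forming the indicator matrix.
#'
#' @param kLine a \linkS4class{KernelMatrix} over lines.
#' @param lineOfCell character or integer vector mapping each cell to a line
#'   of \code{kLine} (character values are matched against its row IDs).
#' @return a \linkS4class{KernelMatrix} over cells.
#' @export
expandLineKernel <- function(kLine, lineOfCell) {
  stopifnot(is(kLine, "KernelMatrix"))
  if (is.character(lineOfCell) || is.factor(lineOfCell)) {
    idx <- match(as.character(lineOfCell), rownames(kLine@values))
    if (anyNA(idx))
      stop(sprintf("cells map to unknown lines: %s",
                   paste(unique(lineOfCell[is.na(idx)]), collapse = ", ")))
  } else {
    idx <- as.integer(lineOfCell)
    if (any(idx < 1 | idx > nrow(kLine@values)))
      stop("cells map to line indices outside the kernel")
  }
  KL <- kLine@values[idx, idx, drop = FALSE]
  ids <- paste0("c", seq_along(idx))
  dimnames(KL) <- list(ids, ids)
  KernelMatrix(KL)
}

#' Environment block kernel
#'
#' \eqn{K_E = X_E X_E^T} with \eqn{X_E} the environment indicator matrix:
#' 1 where two cells share an environment, 0 otherwise.
#'
#' @param envOfCell vector mapping each cell to its environment.
#' @return a \linkS4class{KernelMatrix} over cells (blocks of ones).
#' @export
envBlockKernel <- function(envOfCell) {
  if (length(envOfCell) < 1) stop("need at least one cell")
  e <- as.character(envOfCell)
  KE <- (outer(e, e, `==`)) * 1
  ids <- paste0("c", seq_along(e))
  dimnames(KE) <- list(ids, ids)
  KernelMatrix(KE)
}

#' Hadamard genotype-by-environment interaction kernel
#'
#' \eqn{K_{LE} = K_L \circ K_E} (element-wise product). With complete cells in
#' environment-major order this equals a block-diagonal matrix with one copy
#' of the line kernel per environment, i.e. the Kronecker form with identity
#' environment covariance. PSD whenever both inputs are (Schur product
#' theorem).
#'
#' @param KL,KE cell-level \linkS4class{KernelMatrix} objects of the same
#'   dimension and ordering.
#' @return a \linkS4class{KernelMatrix}.
#' @export
interactionKernel <- function(KL, KE) {
  stopifnot(is(KL, "KernelMatrix"), is(KE, "KernelMatrix"))
  if (!identical(dim(KL@values), dim(KE@values)))
    stop("kernel dimensions differ")
  K <- KL@values * KE@values
  dimnames(K) <- dimnames(KL@values)
  KernelMatrix(K)
}

#' Truncated spectral decomposition / PSD repair of a kernel
#'
#' Symmetric eigendecomposition retaining eigenpairs with
#' \eqn{\lambda > tol \cdot \lambda_{max}}; negative and near-zero eigenvalues
#' are dropped (this repairs indefinite kernels such as the sigmoid kernel by
#' projection onto the PSD cone rather than diagonal loading, keeping the
#' eigenspace sampler exact on the repaired operator). The repaired matrix
#' \eqn{\sum_m \lambda_m v_m v_m^T} replaces the values slot.
#'
#' @param K a symmetric \linkS4class{KernelMatrix}.
#' @param tol relative eigenvalue threshold (default 1e-8).
#' @return the \linkS4class{KernelMatrix} with spectrum stored and values
#'   replaced by the PSD repair.
#' @export
spectralDecompose <- function(K, tol = 1e-8) {
  stopifnot(is(K, "KernelMatrix"))
  es <- eigen(K@values, symmetric = TRUE)
  lmax <- es$values[1]
  if (!(lmax > 0))
    stop("degenerate kernel: no positive eigenvalue")
  keep <- es$values > tol * lmax
  lambda <- es$values[keep]
  V <- es$vectors[, keep, drop = FALSE]
  rownames(V) <- rownames(K@values)
  repaired <- V %*% (lambda * t(V))
  repaired <- (repaired + t(repaired)) / 2
  dimnames(repaired) <- dimnames(K@values)
  new("KernelMatrix", values = repaired, evalues = lambda, evectors = V)
}

#' Write / read a kernel matrix as labelled square CSV
#'
#' Interchange format for GBLUP-style software: a header of column IDs and a
#' first column of row IDs.
#'
#' @param K a \linkS4class{KernelMatrix}.
#' @param path file path.
#' @return \code{readKernelCSV} returns a \linkS4class{KernelMatrix};
#'   \code{writeKernelCSV} returns \code{path} invisibly.
#' @export
writeKernelCSV <- function(K, path) {
  stopifnot(is(K, "KernelMatrix"))
  df <- data.frame(id = rownames(K@values), K@values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeKernelCSV
#' @export
readKernelCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  KernelMatrix(m, rowIds = df[[1]])
}
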