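#' @import methods
#' @importFrom stats rnorm rbinom runif rWishart var predict setNames
#'   aggregate cov2cor
#' @importFrom utils read.csv write.csv
NULL

## Central S4 containers. All matrices are base matrices with dimnames used
## as the authoritative identifiers (line IDs, environment IDs, trait names).

#' MarkerMatrix: genotype codes for J lines at p markers
#'
#' Holds a J x p numeric matrix of marker codes (e.g. 0/1/2 biallelic dosage)
#' with line identifiers as rownames, plus a flag recording whether the
#' scaling transform (per-column centering, unit population variance for
#' polymorphic markers, division of the whole matrix by sqrt(p)) has been
#' applied. All kernels consume the scaled matrix, so with gamma = 1 the
#' Gaussian kernel sees O(1) squared distances regardless of marker count.
#'
#' @slot values J x p numeric matrix; rownames are unique line IDs.
#' @slot scaled logical flag; \code{TRUE} after \code{\link{scaleMarkers}}.
#' @export
setClass("MarkerMatrix",
         representation(values = "matrix", scaled = "logical"),
         prototype(values = matrix(numeric(0), 0, 0), scaled = FALSE))

setValidity("MarkerMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("marker values must be numeric")
  if (anyNA(v)) return("marker matrix contains missing values")
  ids <- rownames(v)
  if (is.null(ids)) return("marker matrix must carry line IDs as rownames")
  if (anyDuplicated(ids)) {
    return(sprintf("duplicated line IDs: %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (length(object@scaled) != 1L) return("scaled must be a single flag")
  TRUE
})

#' Construct a MarkerMatrix
#'
#' @param values numeric J x p matrix of marker codes, or a data.frame.
#' @param lineIds optional character vector of J line IDs; defaults to
#'   existing rownames, or \code{L1..LJ} when absent.
#' @param scaled logical; set by \code{\link{scaleMarkers}}, rarely by hand.
#' @return A \linkS4class{MarkerMatrix}.
#' @examples
#' m <- MarkerMatrix(matrix(c(0, 2, 1, 1), 2, 2), lineIds = c("a", "b"))
#' @export
MarkerMatrix <- function(values, lineIds = NULL, scaled = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(lineIds)) rownames(values) <- as.character(lineIds)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("L", seq_len(nrow(values)))
  if (is.null(colnames(values)) && ncol(values) > 0)
    colnames(values) <- paste0("M", seq_len(ncol(values)))
  new("MarkerMatrix", values = values, scaled = scaled)
}

#' KernelMatrix: labelled symmetric similarity matrix
#'
#' A symmetric m x m kernel (relationship) matrix with row identifiers and an
#' optional truncated spectral decomposition produced by
#' \code{\link{spectralDecompose}}. The sampler works in the eigenbasis, so
#' indefinite kernels (the sigmoid kernel can be indefinite) are repaired by
#' dropping non-positive eigenvalues before use as a covariance.
#'
#' @slot values m x m numeric symmetric matrix with matching dimnames.
#' @slot evalues retained positive eigenvalues (possibly length 0 when the
#'   decomposition has not been computed).
#' @slot evectors m x r matrix of the corresponding eigenvectors.
#' @export
setClass("KernelMatrix",
         representation(values = "matrix", evalues = "numeric",
                        evectors = "matrix"),
         prototype(values = matrix(numeric(0), 0, 0), evalues = numeric(0),
                   evectors = matrix(numeric(0), 0, 0)))

setValidity("KernelMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("kernel matrix must be square")
  if (nrow(v) > 0) {
    asym <- max(abs(v - t(v)))
    if (asym > 1e-10 * max(abs(v), 1)) {
      return(sprintf("kernel matrix not symmetric (max asymmetry %.3g)", asym))
    }
  }
  r <- length(object@evalues)
  if (r > 0) {
    if (any(object@evalues <= 0)) return("retained eigenvalues must be > 0")
    if (ncol(object@evectors) != r || nrow(object@evectors) != nrow(v))
      return("eigenvector matrix inconsistent with eigenvalues")
  }
  TRUE
})

#' Construct a KernelMatrix
#'
#' Symmetrises tiny numerical asymmetry ((K + t(K))/2) before validation.
#'
#' @param values square numeric matrix.
#' @param rowIds optional identifiers for rows/columns.
#' @return A \linkS4class{KernelMatrix}.
#' @export
KernelMatrix <- function(values, rowIds = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("kernel matrix must be square")
  asym <- if (nrow(values)) max(abs(values - t(values))) else 0
  if (asym > 1e-10 * max(abs(values), 1))
    stop(sprintf("matrix is not symmetric (max asymmetry %.3g)", asym))
  values <- (values + t(values)) / 2
  if (!is.null(rowIds)) {
    rowIds <- as.character(rowIds)
    dimnames(values) <- list(rowIds, rowIds)
  } else if (is.null(rownames(values))) {
    ids <- paste0("R", seq_len(nrow(values)))
    dimnames(values) <- list(ids, ids)
  } else {
    colnames(values) <- rownames(values)
  }
  new("KernelMatrix", values = values)
}

#' PhenotypeTable: line-by-environment trait records
#'
#' One row per observed line x environment cell, one column per trait, with a
#' logical mask marking which entries are observed. Rows are canonicalised to
#' environment-major order (sorted by environment, then by line) at
#' construction, so any input row order yields the same object; masked
#' entries' stored values carry no information (they are set to NA).
#'
#' @slot values n x nT numeric matrix of trait values (trait units).
#' @slot mask n x nT logical matrix; TRUE marks an observed entry.
#' @slot line character vector of line IDs, one per cell.
#' @slot env character vector of environment IDs, one per cell.
#' @export
setClass("PhenotypeTable",
         representation(values = "matrix", mask = "matrix",
                        line = "character", env = "character"))

setValidity("PhenotypeTable", function(object) {
  n <- nrow(object@values)
  nT <- ncol(object@values)
  if (nT < 1) return("need at least one trait column")
  if (!identical(dim(object@mask), dim(object@values)))
    return("mask and values dimensions differ")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (length(object@line) != n || length(object@env) != n)
    return("line/env vectors must have one entry per cell")
  if (anyDuplicated(paste(object@line, object@env, sep = "\r")))
    return("duplicated (line, environment) cells")
  if (is.null(colnames(object@values))) return("trait columns must be named")
  if (any(!is.na(object@values[!object@mask])))
    return("masked entries must be stored as NA")
  if (any(is.na(object@values[object@mask])))
    return("observed entries must not be NA")
  TRUE
})

#' Construct a PhenotypeTable
#'
#' @param values n x nT numeric matrix (or data.frame) of trait values;
#'   \code{NA} entries are treated as missing.
#' @param line,env vectors of line and environment IDs, one per row.
#' @param traitNames optional trait names (default: colnames of values).
#' @return A \linkS4class{PhenotypeTable} in canonical environment-major
#'   (environment, then line) row order.
#' @examples
#' y <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("T1", "T2")))
#' pt <- PhenotypeTable(y, line = c("a", "b", "a", "b"),
#'                      env = c("E1", "E1", "E2", "E2"))
#' @export
PhenotypeTable <- function(values, line, env, traitNames = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(traitNames)) colnames(values) <- traitNames
  if (is.null(colnames(values)))
    colnames(values) <- paste0("trait", seq_len(ncol(values)))
  line <- as.character(line)
  env <- as.character(env)
  ord <- order(env, line)
  values <- values[ord, , drop = FALSE]
  line <- line[ord]
  env <- env[ord]
  mask <- !is.na(values)
  rownames(values) <- NULL
  new("PhenotypeTable", values = values, mask = mask, line = line, env = env)
}

#' MultitraitFit: posterior draws and summaries from the Gibbs sampler
#'
#' @slot spec list echoing the model configuration (kernel, priors, MCMC
#'   lengths, seed).
#' @slot draws list of per-saved-iteration quantities: \code{envMeans}
#'   (array I x nT x S), one trait covariance array per random term, and
#'   \code{R} (nT x nT x S).
#' @slot summaries list of posterior means/sds: \code{linpred}, \code{imputed},
#'   per-term cell-level effects, covariance means.
#' @slot data the \linkS4class{PhenotypeTable} the model was fitted to.
#' @slot terms list describing each random-effect term (name, retained rank).
#' @slot diagnostics list (reconstruction error, acceptance of conservation
#'   invariant, timing).
#' @export
setClass("MultitraitFit",
         representation(spec = "list", draws = "list", summaries = "list",
                        data = "PhenotypeTable", terms = "list",
                        diagnostics = "list"))

## ---- accessors -------------------------------------------------------------

#' @describeIn MarkerMatrix number of lines
#' @param x,object a MarkerMatrix
#' @export
setMethod("nrow", "MarkerMatrix", function(x) nrow(x@values))

#' Line identifiers
#' @param x a MarkerMatrix, KernelMatrix or PhenotypeTable
#' @return character vector of identifiers.
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))

#' @rdname lineIds
#' @export
setMethod("lineIds", "MarkerMatrix", function(x) rownames(x@values))

#' @rdname lineIds
#' @export
setMethod("lineIds", "PhenotypeTable", function(x) x@line)

#' Extract the numeric matrix of values
#' @param x a MarkerMatrix, KernelMatrix or PhenotypeTable
#' @return the underlying numeric matrix.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname values
#' @export
setMethod("values", "MarkerMatrix", function(x) x@values)

#' @rdname values
#' @export
setMethod("values", "KernelMatrix", function(x) x@values)

#' @rdname values
#' @export
setMethod("values", "PhenotypeTable", function(x) x@values)

#' Observation mask of a PhenotypeTable
#' @param x a PhenotypeTable
#' @return logical matrix, TRUE where observed.
#' @export
setGeneric("observedMask", function(x) standardGeneric("observedMask"))

#' @rdname observedMask
#' @export
setMethod("observedMask", "PhenotypeTable", function(x) x@mask)

#' Environment identifiers per cell
#' @param x a PhenotypeTable
#' @export
setGeneric("envIds", function(x) standardGeneric("envIds"))

#' @rdname envIds
#' @export
setMethod("envIds", "PhenotypeTable", function(x) x@env)

#' Trait names
#' @param x a PhenotypeTable
#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))

#' @rdname traitNames
#' @export
setMethod("traitNames", "PhenotypeTable", function(x) colnames(x@values))

#' Retained spectrum of a KernelMatrix
#' @param x a KernelMatrix processed by \code{\link{spectralDecompose}}
#' @return list with elements \code{values} (eigenvalues) and \code{vectors}.
#' @export
setGeneric("spectrum", function(x) standardGeneric("spectrum"))

#' @rdname spectrum
#' @export
setMethod("spectrum", "KernelMatrix", function(x) {
  if (length(x@evalues) == 0)
    stop("no spectral decomposition stored; run spectralDecompose() first")
  list(values = x@evalues, vectors = x@evectors)
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "MarkerMatrix", function(object) {
  cat(sprintf("MarkerMatrix: %d lines x %d markers (%s)\n",
              nrow(object@values), ncol(object@values),
              if (object@scaled) "scaled" else "raw codes"))
})

setMethod("show", "KernelMatrix", function(object) {
  cat(sprintf("KernelMatrix: %d x %d", nrow(object@values), ncol(object@values)))
  if (length(object@evalues))
    cat(sprintf(", retained rank %d (lambda_max %.4g)",
                length(object@evalues), max(object@evalues)))
  cat("\n")
})

setMethod("show", "PhenotypeTable", function(object) {
  cat(sprintf(
    "PhenotypeTable: %d cells (%d lines x %d environments present), %d traits\n",
    nrow(object@values), length(unique(object@line)),
    length(unique(object@env)), ncol(object@values)))
  cat(sprintf("  traits: %s; observed entries: %d/%d\n",
              paste(colnames(object@values), collapse = ", "),
              sum(object@mask), length(object@mask)))
})

setMethod("show", "MultitraitFit", function(object) {
  cat(sprintf("MultitraitFit: kernel '%s'%s, %d saved draws\n",
              object@spec$kernel,
              if (isTRUE(object@spec$gxe)) " + GxE" else "",
              object@spec$nSaved))
  cat(sprintf("  data: %d cells, %d traits; terms: %s\n",
              nrow(object@data@values), ncol(object@data@values),
              paste(vapply(object@terms, `[[`, "", "name"), collapse = ", ")))
})
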