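## CSV readers/writers. Dialect: comma-separated, UTF-8, header row, `NA` or
## empty cells for missing values, named key columns (no positional index
## ambiguity).

#' Read a marker CSV
#'
#' Expected layout: header row, first column \code{line_id}, remaining
#' columns numeric marker codes. Missing marker cells (empty or \code{NA})
#' are mean-imputed per column with a message reporting the count (upstream
#' genotype imputation is out of scope here).
#'
#' @param path CSV file path.
#' @return a raw \linkS4class{MarkerMatrix}.
#' @export
readMarkerCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stop("marker CSV needs a line_id column plus markers")
  if (names(df)[1] != "line_id")
    stop("first column of a marker CSV must be named 'line_id'")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicated line ID(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  m <- df[, -1, drop = FALSE]
  for (j in seq_along(m)) {
    if (!is.numeric(m[[j]])) {
      bad <- which(!is.na(m[[j]]) & is.na(suppressWarnings(as.numeric(m[[j]]))))
      if (length(bad))
        stop(sprintf("non-numeric marker value at row %d, column '%s'",
                     bad[1], names(m)[j]))
      m[[j]] <- as.numeric(m[[j]])
    }
  }
  m <- as.matrix(m)
  nmiss <- sum(is.na(m))
  if (nmiss > 0) {
    message(sprintf("mean-imputing %d missing marker cell(s)", nmiss))
    for (j in seq_len(ncol(m))) {
      na <- is.na(m[, j])
      if (any(na)) m[na, j] <- mean(m[, j], na.rm = TRUE)
    }
  }
  MarkerMatrix(m, lineIds = ids)
}

#' Write a MarkerMatrix as CSV
#'
#' @param markers a \linkS4class{MarkerMatrix}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMarkerCSV <- function(markers, path) {
  stopifnot(is(markers, "MarkerMatrix"))
  df <- data.frame(line_id = rownames(markers@values), markers@values,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype CSV
#'
#' Expected layout: columns \code{line_id}, \code{env_id}, then one numeric
#' column per trait; empty or \code{NA} cells become masked entries.
#' Duplicate (line, environment) pairs are rejected; rows may arrive in any
#' order (the table is canonicalised to environment-major order).
#'
#' @param path CSV file path.
#' @return a \linkS4class{PhenotypeTable}.
#' @export
readPhenotypeCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("line_id", "env_id")
  if (!all(need %in% names(df)[1:2]))
    stop("phenotype CSV must start with columns 'line_id', 'env_id'")
  if (ncol(df) < 3) stop("phenotype CSV has no trait columns")
  key <- paste(df$line_id, df$env_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicated (line, environment) pair: (%s, %s)",
                 d$line_id, d$env_id))
  }
  traits <- setdiff(names(df), need)
  Y <- as.matrix(df[, traits, drop = FALSE])
  storage.mode(Y) <- "double"
  PhenotypeTable(Y, line = df$line_id, env = df$env_id)
}

#' Write a PhenotypeTable as CSV
#'
#' Masked entries are written as empty cells.
#'
#' @param data a \linkS4class{PhenotypeTable}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePhenotypeCSV <- function(data, path) {
  stopifnot(is(data, "PhenotypeTable"))
  df <- data.frame(line_id = data@line, env_id = data@env, data@values,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
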