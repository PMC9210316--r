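# Fixtures built in code; everything is seeded and small.

# random raw marker matrix with 0/1/2 codes
rawMarkers <- function(J, p, seed = 1) {
  set.seed(seed)
  MarkerMatrix(matrix(sample(0:2, J * p, replace = TRUE), J, p),
               lineIds = sprintf("L%03d", seq_len(J)))
}

scaledMarkers <- function(J, p, seed = 1) scaleMarkers(rawMarkers(J, p, seed))

# MarkerMatrix with explicitly chosen scaled rows (bypasses scaling)
asScaled <- function(m) {
  m <- as.matrix(m)
  rownames(m) <- paste0("L", seq_len(nrow(m)))
  new("MarkerMatrix", values = m, scaled = TRUE)
}

# complete phenotype table on a grid of lines x environments
gridPhenotypes <- function(J, I, nT = 2, seed = 1, sd = 1) {
  set.seed(seed)
  lines <- sprintf("L%03d", seq_len(J))
  envs <- sprintf("E%02d", seq_len(I))
  Y <- matrix(rnorm(J * I * nT, sd = sd), J * I, nT,
              dimnames = list(NULL, paste0("trait", seq_len(nT))))
  PhenotypeTable(Y, line = rep(lines, times = I), env = rep(envs, each = J))
}

# exact flat-prior-intercept BLUP: posterior mean of g for y = 1 mu + g + e,
# g ~ N(0, sg2 K), e ~ N(0, se2 I), flat prior on mu (independent oracle:
# direct dense solves, no sampling)
blupOracle <- function(K, y, sg2 = 1, se2 = 1) {
  n <- length(y)
  V <- sg2 * K + se2 * diag(n)
  Vi <- solve(V)
  one <- rep(1, n)
  mu <- drop(crossprod(one, Vi %*% y)) / drop(crossprod(one, Vi %*% one))
  g <- drop(sg2 * K %*% Vi %*% (y - mu))
  list(mu = mu, g = g)
}

# Monte-Carlo standard error of posterior means from a draws array
# (n x nT x S) via non-overlapping batch means
mcseBatch <- function(draws, nBatch = 20) {
  S <- dim(draws)[3]
  bs <- S %/% nBatch
  bm <- vapply(seq_len(nBatch), function(b)
    apply(draws[, , ((b - 1) * bs + 1):(b * bs), drop = FALSE], c(1, 2), mean),
    matrix(0, dim(draws)[1], dim(draws)[2]))
  if (is.null(dim(bm))) bm <- array(bm, c(1, 1, nBatch))
  apply(bm, c(1, 2), stats::sd) / sqrt(nBatch)
}
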