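## Synthetic multitrait multienvironment data with known ground truth,
## generated from the same model the sampler fits. Genetic effects are drawn
## in kernel space (matrix-normal with the chosen kernel as row covariance),
## so any kernel -- including the Gaussian -- can be the true architecture;
## `markerEffects = TRUE` instead draws i.i.d. marker effects, giving a true
## linear/BRR world for GBLUP-equivalence checks.

.corMat <- function(nT, rho, scale = 1) {
  m <- matrix(rho, nT, nT)
  diag(m) <- 1
  m * scale
}

#' Default simulation configuration
#'
#' Desk-scale emulation of an elite-yield-trial shape: hundreds of lines,
#' a few environments, two highly correlated traits. Defaults: J = 150 lines,
#' p = 300 markers, I = 3 environments, nT = 2 traits, genetic trait
#' correlation 0.9, interaction covariance at half the genetic scale,
#' residual correlation 0.5, environment-mean sd 2 (trait units), allele
#' frequencies uniform on (0.05, 0.95), no missingness.
#'
#' @param J,p,I,nT lines, markers, environments, traits.
#' @param freqRange allele-frequency range for marker simulation.
#' @param envEffectSd standard deviation of the true environment means.
#' @param kernel,kernelParams true genetic architecture.
#' @param sigmaT,sigmaTE,R true trait covariances of the line effect, the
#'   interaction effect, and the residual.
#' @param missingRate fraction of entries masked completely at random.
#' @param markerEffects draw the line effect from i.i.d. marker effects
#'   (true-linear world) instead of kernel space.
#' @return a list usable as \code{config} in the simulators.
#' @export
simConfig <- function(J = 150, p = 300, I = 3, nT = 2,
                      freqRange = c(0.05, 0.95),
                      envEffectSd = 2,
                      kernel = "linear", kernelParams = list(),
                      sigmaT = .corMat(nT, 0.9),
                      sigmaTE = .corMat(nT, 0.9, 0.5),
                      R = .corMat(nT, 0.5),
                      missingRate = 0,
                      markerEffects = FALSE) {
  cfg <- list(J = J, p = p, I = I, nT = nT, freqRange = freqRange,
              envEffectSd = envEffectSd, kernel = kernel,
              kernelParams = kernelParams, sigmaT = as.matrix(sigmaT),
              sigmaTE = as.matrix(sigmaTE), R = as.matrix(R),
              missingRate = missingRate, markerEffects = markerEffects)
  if (cfg$missingRate < 0 || cfg$missingRate >= 1)
    stop("missingRate must lie in [0, 1)")
  if (any(cfg$freqRange <= 0) || any(cfg$freqRange >= 1))
    stop("allele frequency range must lie inside (0, 1)")
  if (min(J, p, I, nT) < 1) stop("J, p, I, nT must all be >= 1")
  cfg
}

#' Simulate a biallelic marker matrix
#'
#' Per-marker allele frequency drawn uniformly from \code{config$freqRange};
#' genotype codes 0/1/2 drawn Binomial(2, freq) per line (GBS-style dosage
#' codes, no LD or pedigree structure).
#'
#' @param config list from \code{\link{simConfig}}.
#' @param seed integer seed.
#' @return a raw \linkS4class{MarkerMatrix}.
#' @export
simulateMarkers <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  J <- config$J; p <- config$p
  freq <- runif(p, config$freqRange[1], config$freqRange[2])
  X <- vapply(freq, function(q) rbinom(J, 2L, q), numeric(J))
  X <- matrix(X, J, p)
  MarkerMatrix(X, lineIds = sprintf("L%04d", seq_len(J)))
}

#' Simulate a multitrait multienvironment dataset with known truth
#'
#' Assembles, in environment-major cell order,
#' \deqn{Y = X_E \beta_E + Z_L g + Z_{EL} gE + \epsilon}
#' with \eqn{g \sim MN(0, K_l, \Sigma_T)},
#' \eqn{gE \sim MN(0, K_L \circ K_E, \Sigma_{TE})},
#' \eqn{\epsilon \sim MN(0, I, R)} and environment means
#' \eqn{N(0, envEffectSd^2)}; then masks a \code{missingRate} fraction of
#' entries completely at random. All components are stored so recovery tests
#' can compare against exact truth.
#'
#' @param config list from \code{\link{simConfig}}.
#' @param seed integer seed (drives markers and all effects).
#' @param markers optional \linkS4class{MarkerMatrix} to reuse (e.g. to hold
#'   the kernel fixed across replicates); simulated from \code{config} when
#'   absent.
#' @return list with \code{markers} (raw \linkS4class{MarkerMatrix}),
#'   \code{phenotypes} (masked \linkS4class{PhenotypeTable}), and
#'   \code{truth}: \code{envMeans}, \code{g} (J x nT), \code{gE} (n x nT),
#'   \code{eps}, \code{linpred}, \code{Y} (unmasked), \code{sigmaT},
#'   \code{sigmaTE}, \code{R}, \code{kernel} (the true line
#'   \linkS4class{KernelMatrix}).
#' @export
simulateMultitrait <- function(config = simConfig(), seed = NULL,
                               markers = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  J <- config$J; I <- config$I; nT <- config$nT
  if (is.null(markers)) {
    markers <- simulateMarkers(config)         # uses current RNG state
  } else {
    stopifnot(is(markers, "MarkerMatrix"))
    J <- nrow(markers@values)
  }
  Xs <- scaleMarkers(markers)
  kLine <- do.call(buildKernel, c(list(X = Xs, kernel = config$kernel),
                                  config$kernelParams))
  kLine <- spectralDecompose(kLine)

  lines <- rownames(markers@values)
  ## zero-padded IDs keep the generation order identical to the canonical
  ## (lexicographic env-major) order imposed by PhenotypeTable
  envs <- sprintf("E%02d", seq_len(I))
  line <- rep(lines, times = I)
  env <- rep(envs, each = J)
  n <- J * I

  envMeans <- matrix(rnorm(I * nT, 0, config$envEffectSd), I, nT,
                     dimnames = list(envs, paste0("trait", seq_len(nT))))
  if (isTRUE(config$markerEffects)) {
    ## true-linear world: i.i.d. marker effects with trait covariance chosen
    ## so that g = X beta has row covariance X X' = K_linear and column
    ## covariance sigmaT, matching the kernel-space draw in distribution
    beta <- matrix(rnorm(config$p * nT), config$p, nT) %*% chol(config$sigmaT)
    g <- Xs@values %*% beta
  } else {
    g <- rMatrixNormal(1, kLine, config$sigmaT)
  }
  rownames(g) <- lines
  KL <- expandLineKernel(KernelMatrix(kLine@values), line)
  KE <- envBlockKernel(env)
  KLE <- interactionKernel(KL, KE)
  gE <- rMatrixNormal(1, KLE, config$sigmaTE)
  eps <- matrix(rnorm(n * nT), n, nT) %*% chol(config$R)
  fixed <- envMeans[match(env, envs), , drop = FALSE]
  linpred <- fixed + g[match(line, lines), , drop = FALSE] + gE
  Y <- linpred + eps
  colnames(Y) <- paste0("trait", seq_len(nT))

  Ymasked <- Y
  if (config$missingRate > 0) {
    drop <- runif(n * nT) < config$missingRate
    ## keep at least one observed entry per trait so priors stay defined
    for (t in seq_len(nT)) if (all(drop[(t - 1) * n + seq_len(n)]))
      drop[(t - 1) * n + 1] <- FALSE
    Ymasked[matrix(drop, n, nT)] <- NA_real_
  }
  phenotypes <- PhenotypeTable(Ymasked, line = line, env = env)

  list(markers = markers, phenotypes = phenotypes,
       truth = list(envMeans = envMeans, g = g, gE = gE, eps = eps,
                    linpred = linpred, Y = Y,
                    line = line, env = env,
                    sigmaT = config$sigmaT, sigmaTE = config$sigmaTE,
                    R = config$R, kernel = kLine))
}
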