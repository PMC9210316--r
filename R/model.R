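## Gibbs sampler for the Bayesian multitrait multienvironment kernel model
##
##   Y = X_E beta_E + Z_L g + Z_EL gE + eps
##
## with g ~ MN(0, K_l, Sigma_T), gE ~ MN(0, K_L o K_E, Sigma_TE),
## eps ~ MN(0, I_n, R), one fixed mean per environment per trait (flat prior;
## the global trait intercept is absorbed into the environment means), and
## inverse-Wishart priors on every covariance. Each random term is sampled in
## the eigenbasis of its (repaired) cell-level kernel: for eigenpair
## (lambda_m, v_m) the nT-vector of coefficients b_m has conditional
## precision R^-1 + lambda_m^-1 Sigma^-1, which is diagonalised jointly with
## R once per sweep so the whole term updates in a few dense matrix products.

.defaultPriors <- function(data, termNames) {
  Y <- data@values
  nT <- ncol(Y)
  v0 <- nT + 2                      # weakly informative, finite IW mean
  vobs <- apply(Y, 2, function(col) {
    x <- col[!is.na(col)]
    if (length(x) > 1) var(x) else 1
  })
  vobs[!is.finite(vobs) | vobs <= 0] <- 1
  nterms <- length(termNames)
  ## variance-partition heuristic: half the observed variance shared equally
  ## among the random terms, half to the residual; IW mean = S/(v0 - nT - 1)
  ## and v0 - nT - 1 = 1, so the scale equals the targeted prior mean.
  pri <- lapply(termNames, function(nm)
    list(df = v0, scale = diag(0.5 * vobs / nterms, nT)))
  names(pri) <- termNames
  pri$residual <- list(df = v0, scale = diag(0.5 * vobs, nT))
  pri
}

.initMissing <- function(data) {
  Y <- data@values
  mask <- data@mask
  Yimp <- Y
  gmean <- colMeans(Y, na.rm = TRUE)
  gmean[!is.finite(gmean)] <- 0
  for (e in unique(data@env)) {
    rows <- which(data@env == e)
    for (t in seq_len(ncol(Y))) {
      miss <- rows[!mask[rows, t]]
      if (length(miss) == 0) next
      obs <- Y[rows, t]
      m <- mean(obs, na.rm = TRUE)
      Yimp[miss, t] <- if (is.finite(m)) m else gmean[t]
    }
  }
  Yimp
}

#' Fit the Bayesian multitrait multienvironment kernel model
#'
#' Runs the Gibbs sampler for the kernel regression of multiple (possibly
#' partially missing) traits on genome-wide markers across environments:
#' fixed per-environment trait means, a kernel-structured line main effect,
#' optionally a genotype-by-environment interaction effect with the Hadamard
#' kernel \eqn{K_L \circ K_E}, unstructured trait covariances for each random
#' term and for the residual (all inverse-Wishart), and data augmentation of
#' missing trait values by their Gaussian conditional given the row's
#' observed traits.
#'
#' @param data a \linkS4class{PhenotypeTable}.
#' @param markers a \linkS4class{MarkerMatrix}; every line in \code{data} must
#'   be present. Scaled automatically when raw.
#' @param kernel kernel name passed to \code{\link{buildKernel}}.
#' @param kernelParams list with any of \code{gamma}, \code{offset},
#'   \code{degree}.
#' @param gxe include the genotype-by-environment interaction term?
#' @param nIter,burnIn,thin MCMC length, burn-in and thinning. Defaults
#'   (10000 / 2000 / 5) are production settings; tests use shorter chains.
#' @param priors named list (\code{line}, \code{gxe}, \code{residual}) of
#'   \code{list(df, scale)} inverse-Wishart settings; missing entries get the
#'   defaults described in the package vignette.
#' @param fixedCov named list of covariance matrices to hold fixed instead of
#'   sampling (same names as \code{priors}); used for conjugate checks.
#' @param seed integer seed; identical seed, spec and data give bit-identical
#'   draws.
#' @param keepEffectDraws store full per-draw cell-level effects per term
#'   (memory heavy; effects are always summarised online).
#' @param verbose emit a progress message every 100 iterations.
#' @return a \linkS4class{MultitraitFit}.
#' @seealso \code{\link{predict}}, \code{\link{geneticCorrelations}}
#' @export
fitMultitrait <- function(data, markers,
                          kernel = "linear",
                          kernelParams = list(),
                          gxe = TRUE,
                          nIter = 10000, burnIn = 2000, thin = 5,
                          priors = NULL, fixedCov = NULL,
                          seed = NULL,
                          keepEffectDraws = FALSE,
                          verbose = FALSE) {
  stopifnot(is(data, "PhenotypeTable"), is(markers, "MarkerMatrix"))
  if (nIter <= burnIn) stop("nIter must exceed burnIn")
  if (thin < 1) stop("thin must be >= 1")
  missingLines <- setdiff(unique(data@line), rownames(markers@values))
  if (length(missingLines))
    stop(sprintf("phenotyped lines absent from the marker matrix: %s",
                 paste(utils::head(missingLines, 5), collapse = ", ")))
  if (!is.null(seed)) set.seed(as.integer(seed))

  n <- nrow(data@values)
  nT <- ncol(data@values)
  traits <- colnames(data@values)

  ## kernels: line kernel -> expand to cells -> (optional) Hadamard with the
  ## environment block kernel; each decomposed for the eigenspace updates
  Xs <- if (markers@scaled) markers else scaleMarkers(markers)
  kArgs <- c(list(X = Xs, kernel = kernel), kernelParams)
  kLine <- do.call(buildKernel, kArgs)
  KL <- spectralDecompose(expandLineKernel(kLine, data@line))
  terms <- list(line = list(name = "line", V = KL@evectors,
                            lambda = KL@evalues))
  if (gxe) {
    KE <- envBlockKernel(data@env)
    KLE <- spectralDecompose(interactionKernel(
      KernelMatrix(KL@values), KE))
    terms$gxe <- list(name = "gxe", V = KLE@evectors, lambda = KLE@evalues)
  }
  termNames <- names(terms)

  pri <- .defaultPriors(data, termNames)
  for (nm in names(priors)) pri[[nm]] <- priors[[nm]]
  for (nm in c(termNames, "residual")) {
    if (pri[[nm]]$df <= nT - 1) stop("prior df must exceed nT - 1")
    .checkSPD(pri[[nm]]$scale, sprintf("prior scale for '%s'", nm))
  }
  updateCov <- setNames(!(c(termNames, "residual") %in% names(fixedCov)),
                        c(termNames, "residual"))

  envFac <- factor(data@env, levels = unique(data@env))
  I <- nlevels(envFac)
  envRows <- split(seq_len(n), envFac)
  nPerEnv <- lengths(envRows)
  sparseEnv <- vapply(envRows, function(r) sum(rowSums(data@mask[r, ,
                      drop = FALSE]) > 0) < 2, logical(1))
  if (any(sparseEnv))
    warning(sprintf("environments with <2 observed cells (means weakly determined): %s",
                    paste(levels(envFac)[sparseEnv], collapse = ", ")))

  ## state
  Yimp <- .initMissing(data)
  mask <- data@mask
  anyMissRow <- which(rowSums(!mask) > 0)
  patterns <- if (length(anyMissRow))
    vapply(anyMissRow, function(i) paste(mask[i, ] * 1, collapse = ""),
           character(1)) else character(0)
  beta <- matrix(0, I, nT, dimnames = list(levels(envFac), traits))
  for (e in seq_len(I)) beta[e, ] <- colMeans(Yimp[envRows[[e]], , drop = FALSE])
  Sigma <- lapply(termNames, function(nm)
    if (updateCov[nm]) pri[[nm]]$scale / (pri[[nm]]$df - nT - 1)
    else as.matrix(fixedCov[[nm]]))
  names(Sigma) <- termNames
  R <- if (updateCov["residual"])
    pri$residual$scale / (pri$residual$df - nT - 1)
  else as.matrix(fixedCov$residual)
  B <- lapply(terms, function(tm) matrix(0, length(tm$lambda), nT))
  eff <- lapply(terms, function(tm) matrix(0, n, nT))

  nSaved <- (nIter - burnIn) %/% thin
  draws <- list(envMeans = array(NA_real_, c(I, nT, nSaved),
                                 dimnames = list(levels(envFac), traits, NULL)),
                R = array(NA_real_, c(nT, nT, nSaved),
                          dimnames = list(traits, traits, NULL)))
  for (nm in termNames)
    draws[[paste0("Sigma_", nm)]] <-
      array(NA_real_, c(nT, nT, nSaved), dimnames = list(traits, traits, NULL))
  if (keepEffectDraws)
    effDraws <- lapply(terms, function(tm) array(NA_real_, c(n, nT, nSaved)))

  runMean <- function() matrix(0, n, nT, dimnames = list(NULL, traits))
  sums <- list(linpred = runMean(), linpred2 = runMean(),
               imputed = runMean(), imputed2 = runMean())
  effSums <- lapply(terms, function(tm) list(m = runMean(), m2 = runMean()))
  maxRecon <- 0
  s <- 0L

  for (iter in seq_len(nIter)) {
    ## (1) fixed per-environment means | effects, R  (flat prior)
    resid0 <- Yimp - Reduce(`+`, eff)
    cR <- chol(R)
    for (e in seq_len(I)) {
      rows <- envRows[[e]]
      beta[e, ] <- colMeans(resid0[rows, , drop = FALSE]) +
        drop(crossprod(cR, rnorm(nT))) / sqrt(nPerEnv[e])
    }
    fixedM <- beta[as.integer(envFac), , drop = FALSE]

    ## (2) eigen-coefficients of each random term
    U <- chol(R)                              # R = U'U
    Rinv <- chol2inv(U)
    for (nm in termNames) {
      tm <- terms[[nm]]
      Epart <- Yimp - fixedM
      for (other in termNames) if (other != nm) Epart <- Epart - eff[[other]]
      Et <- crossprod(tm$V, Epart)            # r x nT projected residual
      SigInv <- chol2inv(chol(Sigma[[nm]]))
      M <- U %*% SigInv %*% t(U)
      eM <- eigen((M + t(M)) / 2, symmetric = TRUE)
      Q <- eM$vectors
      phi <- pmax(eM$values, 0)
      cvec <- 1 / tm$lambda
      G <- crossprod(Q, solve(t(U), t(Et)))   # nT x r
      denom <- 1 + outer(phi, cvec)           # nT x r
      H <- G / denom
      Z <- matrix(rnorm(nT * length(cvec)), nT)
      TQ <- t(U) %*% Q
      Bdraw <- TQ %*% (H + Z / sqrt(denom))   # nT x r
      B[[nm]] <- t(Bdraw)
      eff[[nm]] <- tm$V %*% B[[nm]]
    }

    ## (3) trait covariance of each term | coefficients
    for (nm in termNames) {
      if (!updateCov[nm]) next
      r <- length(terms[[nm]]$lambda)
      S <- pri[[nm]]$scale + crossprod(B[[nm]], B[[nm]] / terms[[nm]]$lambda)
      Sigma[[nm]] <- rInvWishart(1, pri[[nm]]$df + r, (S + t(S)) / 2)
    }

    ## (4) residual covariance | full residual
    Eres <- Yimp - fixedM - Reduce(`+`, eff)
    if (updateCov["residual"]) {
      SR <- pri$residual$scale + crossprod(Eres)
      R <- rInvWishart(1, pri$residual$df + n, (SR + t(SR)) / 2)
    }

    ## conservation invariant: fitted + residual == current imputed Y
    maxRecon <- max(maxRecon,
                    max(abs(fixedM + Reduce(`+`, eff) + Eres - Yimp)))

    ## (5) impute missing traits | linear predictor, observed traits, R
    if (length(anyMissRow)) {
      eta <- fixedM + Reduce(`+`, eff)
      for (pat in sort(unique(patterns))) {
        rows <- anyMissRow[patterns == pat]
        obs <- which(strsplit(pat, "")[[1]] == "1")
        miss <- setdiff(seq_len(nT), obs)
        if (length(obs)) {
          cnd <- conditionalNormal(rep(0, nT), R, obs, rep(0, length(obs)))
          W <- R[miss, obs, drop = FALSE] %*%
            chol2inv(chol(R[obs, obs, drop = FALSE]))
          cm <- eta[rows, miss, drop = FALSE] +
            (Yimp[rows, obs, drop = FALSE] - eta[rows, obs, drop = FALSE]) %*% t(W)
          cc <- cnd$cov
        } else {
          cm <- eta[rows, miss, drop = FALSE]
          cc <- R
        }
        Zm <- matrix(rnorm(length(rows) * length(miss)), length(rows))
        Yimp[rows, miss] <- cm + Zm %*% chol((cc + t(cc)) / 2)
      }
    }

    ## save
    if (iter > burnIn && (iter - burnIn) %% thin == 0) {
      s <- s + 1L
      draws$envMeans[, , s] <- beta
      draws$R[, , s] <- R
      for (nm in termNames) draws[[paste0("Sigma_", nm)]][, , s] <- Sigma[[nm]]
      eta <- fixedM + Reduce(`+`, eff)
      sums$linpred <- sums$linpred + eta
      sums$linpred2 <- sums$linpred2 + eta^2
      sums$imputed <- sums$imputed + Yimp
      sums$imputed2 <- sums$imputed2 + Yimp^2
      for (nm in termNames) {
        effSums[[nm]]$m <- effSums[[nm]]$m + eff[[nm]]
        effSums[[nm]]$m2 <- effSums[[nm]]$m2 + eff[[nm]]^2
        if (keepEffectDraws) effDraws[[nm]][, , s] <- eff[[nm]]
      }
    }
    if (verbose && iter %% 100 == 0)
      message(sprintf("iter %d/%d  tr(R) = %.4g", iter, nIter, sum(diag(R))))
  }

  postSd <- function(sx, sx2) {
    v <- sx2 / nSaved - (sx / nSaved)^2
    sqrt(pmax(v, 0) * nSaved / max(nSaved - 1, 1))
  }
  summaries <- list(
    linpred = list(mean = sums$linpred / nSaved,
                   sd = postSd(sums$linpred, sums$linpred2)),
    imputed = list(mean = sums$imputed / nSaved,
                   sd = postSd(sums$imputed, sums$imputed2)),
    effects = lapply(effSums, function(z)
      list(mean = z$m / nSaved, sd = postSd(z$m, z$m2))),
    envMeans = apply(draws$envMeans, c(1, 2), mean),
    R = apply(draws$R, c(1, 2), mean))
  for (nm in termNames)
    summaries[[paste0("Sigma_", nm)]] <-
      apply(draws[[paste0("Sigma_", nm)]], c(1, 2), mean)
  if (keepEffectDraws) draws$effects <- effDraws

  spec <- list(kernel = kernel, kernelParams = kernelParams, gxe = gxe,
               nIter = nIter, burnIn = burnIn, thin = thin, seed = seed,
               priors = pri, fixedCov = names(fixedCov), nSaved = nSaved)
  new("MultitraitFit", spec = spec, draws = draws, summaries = summaries,
      data = data,
      terms = lapply(terms, function(tm)
        list(name = tm$name, rank = length(tm$lambda))),
      diagnostics = list(maxReconstructionError = maxRecon))
}

#' Posterior-mean predictions from a fitted model
#'
#' For entries that were masked during fitting, the prediction is the
#' posterior mean of the imputed value, which conditions on the row's
#' observed traits through the residual covariance R (this is what gives the
#' MT_P scenario its advantage). For observed entries it is the posterior
#' mean of the linear predictor, reported for reference.
#'
#' @param object a \linkS4class{MultitraitFit}.
#' @param cells optional integer vector of cell (row) indices to return.
#' @param ... ignored.
#' @return an n' x nT matrix of predictions.
#' @export
setMethod("predict", "MultitraitFit", function(object, cells = NULL, ...) {
  n <- nrow(object@data@values)
  if (is.null(cells)) cells <- seq_len(n)
  cells <- as.integer(cells)
  if (any(cells < 1 | cells > n)) stop("unknown cell indices requested")
  mask <- object@data@mask
  pred <- object@summaries$linpred$mean
  pred[!mask] <- object@summaries$imputed$mean[!mask]
  pred[cells, , drop = FALSE]
})

#' Posterior-mean genetic correlation matrix
#'
#' Per saved draw, converts the trait covariance of a random term to a
#' correlation matrix, then averages across draws. The diagonal is exactly 1.
#'
#' @param fit a \linkS4class{MultitraitFit}.
#' @param term which random term's trait covariance to use (default the line
#'   main effect).
#' @return an nT x nT correlation matrix.
#' @export
geneticCorrelations <- function(fit, term = "line") {
  stopifnot(is(fit, "MultitraitFit"))
  arr <- fit@draws[[paste0("Sigma_", term)]]
  if (is.null(arr)) stop(sprintf("no such random term: '%s'", term))
  S <- dim(arr)[3]
  acc <- matrix(0, dim(arr)[1], dim(arr)[2])
  for (s in seq_len(S)) acc <- acc + stats::cov2cor(arr[, , s])
  out <- acc / S
  diag(out) <- 1
  dimnames(out) <- dimnames(arr)[1:2]
  out
}
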