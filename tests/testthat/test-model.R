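# Gibbs sampler: conjugate closed-form equivalences with fixed variance
# components, determinism, conservation, canonical ordering, prediction
# contract.

test_that("with fixed variances the sampler reproduces the BLUP closed form", {
  set.seed(10)
  J <- 30
  markers <- rawMarkers(J, 50, seed = 10)
  Xs <- scaleMarkers(markers)
  K <- values(spectralDecompose(linearKernel(Xs)))  # the operator sampled on
  g0 <- drop(rMatrixNormal(1, K, matrix(1), seed = 11))
  y <- 2 + g0 + rnorm(J, 0, 1)
  pt <- PhenotypeTable(matrix(y, ncol = 1, dimnames = list(NULL, "y")),
                       line = rownames(values(markers)), env = rep("E1", J))

  fit <- fitMultitrait(pt, markers, kernel = "linear", gxe = FALSE,
                       nIter = 6000, burnIn = 1000, thin = 1,
                       fixedCov = list(line = matrix(1),
                                       residual = matrix(1)),
                       seed = 12, keepEffectDraws = TRUE)
  oracle <- blupOracle(K, y, sg2 = 1, se2 = 1)
  est <- fit@summaries$effects$line$mean[, 1]
  mcse <- mcseBatch(fit@draws$effects$line)[, 1]
  expect_true(all(abs(est - oracle$g) <= 3 * mcse))

  # predictions for fully observed rows = posterior mean linear predictor,
  # which matches mu + BLUP within the same Monte-Carlo error
  pred <- predict(fit)[, 1]
  expect_true(all(abs(pred - (oracle$mu + oracle$g)) <= 4 * mcse + 0.02))
})

test_that("all-zero response shrinks every effect to zero", {
  J <- 20
  markers <- rawMarkers(J, 30, seed = 2)
  pt <- PhenotypeTable(matrix(0, J * 2, 2,
                              dimnames = list(NULL, c("a", "b"))),
                       line = rep(rownames(values(markers)), 2),
                       env = rep(c("E1", "E2"), each = J))
  fit <- fitMultitrait(pt, markers, kernel = "gaussian", gxe = TRUE,
                       nIter = 800, burnIn = 300, thin = 1, seed = 3)
  expect_lte(max(abs(fit@summaries$effects$line$mean)), 0.1)
  expect_lte(max(abs(fit@summaries$effects$gxe$mean)), 0.1)
  expect_lte(max(abs(fit@summaries$envMeans)), 0.1)
})

test_that("joint fit with diagonal fixed covariances equals univariate fits", {
  J <- 30
  markers <- rawMarkers(J, 40, seed = 4)
  sim <- simulateMultitrait(
    simConfig(J = J, p = 40, I = 2, nT = 2, sigmaT = diag(2), R = diag(2),
              sigmaTE = diag(1e-8, 2), envEffectSd = 1),
    seed = 5, markers = markers)
  pt <- sim$phenotypes
  diagCov <- list(line = diag(2), residual = diag(2))
  joint <- fitMultitrait(pt, markers, kernel = "linear", gxe = FALSE,
                         nIter = 4000, burnIn = 1000, thin = 1,
                         fixedCov = diagCov, seed = 6,
                         keepEffectDraws = TRUE)
  mc <- 0
  for (t in 1:2) {
    uni <- fitMultitrait(
      PhenotypeTable(values(pt)[, t, drop = FALSE], line = lineIds(pt),
                     env = envIds(pt)),
      markers, kernel = "linear", gxe = FALSE,
      nIter = 4000, burnIn = 1000, thin = 1,
      fixedCov = list(line = matrix(1), residual = matrix(1)),
      seed = 7 + t, keepEffectDraws = TRUE)
    dj <- joint@summaries$effects$line$mean[, t]
    du <- uni@summaries$effects$line$mean[, 1]
    mcse <- sqrt(mcseBatch(joint@draws$effects$line)[, t]^2 +
                   mcseBatch(uni@draws$effects$line)[, 1]^2)
    expect_true(all(abs(dj - du) <= 3 * mcse))
    mc <- max(mc, max(abs(dj - du)))
  }
  expect_lt(mc, 0.2)  # sanity: agreement is tight in absolute terms too
})

test_that("linear-kernel fit equals the marker-effect ridge solution", {
  # dual-route check: p x p marker-effect solve vs the kernel-space sampler
  J <- 25; p <- 40
  markers <- rawMarkers(J, p, seed = 8)
  Xs <- values(scaleMarkers(markers))
  set.seed(9)
  y <- 1 + drop(Xs %*% rnorm(p, 0, 1)) + rnorm(J, 0, 0.7)
  pt <- PhenotypeTable(matrix(y, ncol = 1, dimnames = list(NULL, "y")),
                       line = rownames(Xs), env = rep("E1", J))
  lam <- 0.7^2  # se2 / sg2 with sg2 = 1
  fit <- fitMultitrait(pt, markers, kernel = "linear", gxe = FALSE,
                       nIter = 6000, burnIn = 1000, thin = 1,
                       fixedCov = list(line = matrix(1),
                                       residual = matrix(lam)),
                       seed = 10, keepEffectDraws = TRUE)
  # ridge route: flat-prior intercept by GLS, then beta = (X'X + lam I)^-1 X'r
  V <- tcrossprod(Xs) + lam * diag(J)
  Vi <- solve(V)
  one <- rep(1, J)
  mu <- drop(crossprod(one, Vi %*% y)) / drop(crossprod(one, Vi %*% one))
  beta <- solve(crossprod(Xs) + lam * diag(p), crossprod(Xs, y - mu))
  gRidge <- drop(Xs %*% beta)
  est <- fit@summaries$effects$line$mean[, 1]
  mcse <- mcseBatch(fit@draws$effects$line)[, 1]
  expect_true(all(abs(est - gRidge) <= 3 * mcse))
})

test_that("chains are deterministic and conservative, and the cell order is canonical", {
  sim <- simulateMultitrait(simConfig(J = 25, p = 40, I = 2, nT = 2,
                                      missingRate = 0.15), seed = 20)
  args <- list(data = sim$phenotypes, markers = sim$markers,
               kernel = "gaussian", gxe = TRUE, nIter = 300, burnIn = 100,
               thin = 2, seed = 21)
  f1 <- do.call(fitMultitrait, args)
  f2 <- do.call(fitMultitrait, args)
  expect_identical(f1@draws$R, f2@draws$R)
  expect_identical(f1@draws$envMeans, f2@draws$envMeans)
  expect_identical(f1@summaries$linpred$mean, f2@summaries$linpred$mean)

  # conservation: fitted + residual reconstructs imputed Y at every iteration
  expect_lt(f1@diagnostics$maxReconstructionError, 1e-10)

  # permuted input rows canonicalise to the same table, hence the same fit
  pt <- sim$phenotypes
  set.seed(22)
  perm <- sample(nrow(values(pt)))
  ptPerm <- PhenotypeTable(values(pt)[perm, ], line = lineIds(pt)[perm],
                           env = envIds(pt)[perm])
  expect_identical(values(ptPerm), values(pt))
  f3 <- fitMultitrait(ptPerm, sim$markers, kernel = "gaussian", gxe = TRUE,
                      nIter = 300, burnIn = 100, thin = 2, seed = 21)
  expect_identical(f3@summaries$linpred$mean, f1@summaries$linpred$mean)
})

test_that("observed auxiliary traits sharpen predictions through R (MT_P mechanism)", {
  # residual correlation 0.9: observing trait 2 far above its mean must pull
  # the prediction of trait 1 upward relative to masking it
  J <- 40
  cfg <- simConfig(J = J, p = 60, I = 2, nT = 2,
                   sigmaT = matrix(c(1, .5, .5, 1), 2),
                   sigmaTE = diag(1e-6, 2),
                   R = matrix(c(1, .9, .9, 1), 2))
  sim <- simulateMultitrait(cfg, seed = 30)
  Y <- values(sim$phenotypes)
  testCell <- 5L
  yMT <- Y; yMT[testCell, ] <- NA                       # both traits masked
  yMTP <- Y
  yMTP[testCell, 1] <- NA                               # trait 1 masked
  yMTP[testCell, 2] <- mean(Y[, 2], na.rm = TRUE) + 3   # trait 2 high
  mkFit <- function(y) fitMultitrait(
    PhenotypeTable(y, lineIds(sim$phenotypes), envIds(sim$phenotypes)),
    sim$markers, kernel = "linear", gxe = FALSE,
    nIter = 1200, burnIn = 400, thin = 2, seed = 31)
  pMT <- predict(mkFit(yMT))[testCell, 1]
  pMTP <- predict(mkFit(yMTP))[testCell, 1]
  expect_gt(pMTP, pMT)
})

test_that("genetic correlations are per-draw correlations averaged", {
  sim <- simulateMultitrait(simConfig(J = 30, p = 40, I = 2, nT = 2),
                            seed = 40)
  fit <- fitMultitrait(sim$phenotypes, sim$markers, kernel = "linear",
                       gxe = FALSE, nIter = 400, burnIn = 100, thin = 2,
                       seed = 41)
  gc <- geneticCorrelations(fit)
  expect_equal(unname(diag(gc)), c(1, 1))
  expect_true(all(gc >= -1 & gc <= 1))
  arr <- fit@draws$Sigma_line
  manual <- mean(vapply(seq_len(dim(arr)[3]), function(s)
    stats::cov2cor(arr[, , s])[1, 2], numeric(1)))
  expect_equal(gc[1, 2], manual)
  expect_error(geneticCorrelations(fit, term = "nope"), "no such")
})

test_that("input validation errors are informative", {
  sim <- simulateMultitrait(simConfig(J = 10, p = 15, I = 2, nT = 2), seed = 1)
  other <- rawMarkers(5, 15, seed = 2)  # line IDs L001.. overlap; rename
  rownames(other@values) <- paste0("X", 1:5)
  expect_error(fitMultitrait(sim$phenotypes, other, nIter = 10, burnIn = 2),
               "absent from the marker matrix")
  expect_error(fitMultitrait(sim$phenotypes, sim$markers, nIter = 10,
                             burnIn = 10), "exceed")
  expect_error(predict(fitMultitrait(sim$phenotypes, sim$markers,
                                     nIter = 40, burnIn = 10, thin = 1,
                                     seed = 1), cells = 999), "unknown cell")
})
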