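## Fivefold CV2 evaluation: cells (line x environment rows) are partitioned,
## so a line is typically in training in some environments and in testing in
## others -- the incomplete-field-trial prediction problem. Two masking
## scenarios: MT (all traits of a test cell masked) and MT_P (only the target
## traits masked, auxiliary traits stay observed and sharpen the prediction
## through the residual trait covariance).

#' Random CV2 fold assignment over cells
#'
#' Uniformly random partition of the n cells into k folds whose sizes differ
#' by at most one; a cell appears in exactly one fold.
#'
#' @param data a \linkS4class{PhenotypeTable}.
#' @param k number of folds (default 5).
#' @param seed integer seed; the assignment is deterministic given it.
#' @return list with \code{foldOfCell} (integer vector in 1..k), \code{k} and
#'   \code{seed}.
#' @export
cv2Folds <- function(data, k = 5, seed = NULL) {
  stopifnot(is(data, "PhenotypeTable"))
  n <- nrow(data@values)
  if (k > n) stop("more folds than cells")
  if (k < 2) stop("need at least 2 folds")
  if (!is.null(seed)) set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(k), n))
  list(foldOfCell = fold, k = as.integer(k), seed = seed)
}

#' Apply an MT or MT_P masking scenario to one test fold
#'
#' Returns a copy of the phenotype table in which the test-fold cells have
#' been masked according to the scenario: under MT every trait entry is
#' masked; under MT_P only \code{targetTraits} are masked and
#' \code{observedTraits} remain observed. Training cells and originally
#' missing entries are untouched; masking never unmasks.
#'
#' @param data a \linkS4class{PhenotypeTable}.
#' @param folds a fold assignment from \code{\link{cv2Folds}}.
#' @param testFold which fold is the testing set.
#' @param scenario \code{"MT"} or \code{"MT_P"}.
#' @param targetTraits traits to be predicted (masked in test cells). Under
#'   MT_P this must be a proper subset of the traits; under MT it defaults to
#'   all traits.
#' @param observedTraits traits kept observed in test cells (MT_P only;
#'   defaults to all non-target traits).
#' @return a masked \linkS4class{PhenotypeTable}.
#' @export
maskScenario <- function(data, folds, testFold,
                         scenario = c("MT", "MT_P"),
                         targetTraits = NULL, observedTraits = NULL) {
  stopifnot(is(data, "PhenotypeTable"))
  scenario <- match.arg(scenario)
  if (!testFold %in% seq_len(folds$k)) stop("testFold outside 1..k")
  traits <- colnames(data@values)
  if (is.null(targetTraits)) {
    targetTraits <- if (scenario == "MT") traits else traits[1]
  }
  bad <- setdiff(targetTraits, traits)
  if (length(bad))
    stop(sprintf("target trait(s) absent from data: %s",
                 paste(bad, collapse = ", ")))
  if (scenario == "MT") {
    maskCols <- traits
  } else {
    if (is.null(observedTraits)) observedTraits <- setdiff(traits, targetTraits)
    if (length(intersect(targetTraits, observedTraits)))
      stop("target and observed trait sets must be disjoint")
    if (length(observedTraits) == 0)
      stop("MT_P requires at least one observed trait in test cells")
    maskCols <- targetTraits
  }
  testRows <- which(folds$foldOfCell == testFold)
  values <- data@values
  values[testRows, maskCols] <- NA_real_
  PhenotypeTable(values, line = data@line, env = data@env)
}

#' Per-environment, per-trait mean squared error of prediction
#'
#' \eqn{MSE = \frac{1}{T}\sum_{i=1}^{T} (y_i - \hat f(x_i))^2} over the
#' entries selected by \code{evaluatedMask} (entries that are observed in the
#' truth but were masked for fitting), stratified by environment and trait.
#' Strata with no evaluated entries are omitted.
#'
#' @param truth the unmasked \linkS4class{PhenotypeTable}.
#' @param predictions n x nT matrix of predictions in the truth's row order.
#' @param evaluatedMask n x nT logical matrix selecting evaluated entries.
#' @return data.frame with columns \code{env}, \code{trait}, \code{T},
#'   \code{mse}.
#' @export
mseByEnvTrait <- function(truth, predictions, evaluatedMask) {
  stopifnot(is(truth, "PhenotypeTable"))
  if (!identical(dim(predictions), dim(truth@values)) ||
      !identical(dim(evaluatedMask), dim(truth@values)))
    stop("predictions/evaluatedMask dimensions do not match the truth")
  if (any(evaluatedMask & !truth@mask))
    stop("evaluatedMask selects entries unobserved in the truth")
  traits <- colnames(truth@values)
  out <- list()
  for (e in unique(truth@env)) {
    rows <- truth@env == e
    for (t in seq_along(traits)) {
      sel <- evaluatedMask[rows, t]
      if (!any(sel)) next
      y <- truth@values[rows, t][sel]
      yhat <- predictions[rows, t][sel]
      out[[length(out) + 1L]] <- data.frame(
        env = e, trait = traits[t], T = sum(sel),
        mse = mean((y - yhat)^2))
    }
  }
  if (!length(out)) stop("no evaluated entries in any stratum")
  do.call(rbind, out)
}

#' Aggregate per-fold MSE rows across folds and environments
#'
#' Across-fold value per (environment, trait) stratum is the unweighted mean
#' over folds; the across-environment value per trait is the unweighted mean
#' of the per-environment across-fold values (not a pooled MSE over cells) --
#' the rule that reproduces the published across-environment tables from the
#' per-environment ones.
#'
#' @param rows data.frame with columns \code{fold}, \code{env}, \code{trait},
#'   \code{mse} (extra grouping columns such as \code{method}, \code{scenario}
#'   are carried through).
#' @return list with \code{byEnv} (env x trait across-fold means) and
#'   \code{acrossEnv} (per-trait means of the per-environment values), both
#'   data.frames retaining any extra grouping columns.
#' @export
aggregateMSE <- function(rows) {
  if (nrow(rows) < 1) stop("no rows to aggregate")
  extras <- setdiff(names(rows), c("fold", "env", "trait", "T", "mse"))
  keyEnv <- c(extras, "env", "trait")
  byEnv <- aggregate(rows["mse"], rows[keyEnv], mean)
  keyTrait <- c(extras, "trait")
  acrossEnv <- aggregate(byEnv["mse"], byEnv[keyTrait], mean)
  list(byEnv = byEnv, acrossEnv = acrossEnv)
}

#' Percent improvement of one method over another
#'
#' \eqn{100 (mse_{ref} - mse_{best}) / mse_{best}}: positive when the
#' candidate in the denominator is the better (smaller-MSE) method.
#'
#' @param mseRef MSE of the reference (worse) method.
#' @param mseBest MSE of the candidate method.
#' @return percentage improvement.
#' @examples
#' percentImprovement(21.19, 14.24)  # ~48.8
#' @export
percentImprovement <- function(mseRef, mseBest) {
  if (any(c(mseRef, mseBest) <= 0)) stop("MSE values must be positive")
  100 * (mseRef - mseBest) / mseBest
}

#' Run a paired CV2 experiment over a grid of model specifications
#'
#' For each fold, the same masked training table (identical folds and masks)
#' is fitted with every method in the grid, predictions at the masked test
#' entries are scored per environment and trait, and per-fold rows plus
#' across-fold and across-environment aggregates are returned. The paired
#' design means percent improvements compare methods on byte-identical
#' training data.
#'
#' @param data a complete-truth \linkS4class{PhenotypeTable}.
#' @param markers a \linkS4class{MarkerMatrix}.
#' @param specGrid named list of specifications; each element is a list with
#'   any of \code{kernel}, \code{kernelParams}, \code{gxe} (names become the
#'   \code{method} labels; \code{"brr"} and \code{"gblup"} map to the linear
#'   kernel).
#' @param scenario \code{"MT"} or \code{"MT_P"}.
#' @param targetTraits,observedTraits trait sets passed to
#'   \code{\link{maskScenario}}.
#' @param k number of folds.
#' @param seed integer seed driving fold assignment and every fit.
#' @param nIter,burnIn,thin MCMC settings forwarded to
#'   \code{\link{fitMultitrait}}.
#' @param reference method name used as the baseline of the
#'   percent-improvement table (default: first method).
#' @return list with \code{perFold} (tidy data.frame
#'   \code{fold,env,trait,scenario,gxe,method,T,mse}), \code{byEnv},
#'   \code{acrossEnv}, \code{improvement} (percent improvement of each method
#'   over the reference, per trait, across environments) and \code{folds}.
#' @export
runCVExperiment <- function(data, markers, specGrid,
                            scenario = c("MT", "MT_P"),
                            targetTraits = NULL, observedTraits = NULL,
                            k = 5, seed = 1,
                            nIter = 1500, burnIn = 500, thin = 2,
                            reference = NULL) {
  scenario <- match.arg(scenario)
  if (!length(specGrid)) stop("empty specification grid")
  if (is.null(names(specGrid)) || any(names(specGrid) == ""))
    stop("specGrid must be a named list (names are method labels)")
  folds <- cv2Folds(data, k = k, seed = seed)
  traits <- colnames(data@values)
  if (is.null(targetTraits))
    targetTraits <- if (scenario == "MT") traits else traits[1]

  perFold <- list()
  for (f in seq_len(k)) {
    masked <- maskScenario(data, folds, f, scenario,
                           targetTraits = targetTraits,
                           observedTraits = observedTraits)
    evalMask <- data@mask & !masked@mask   # masked for fitting, observed truth
    for (m in names(specGrid)) {
      sp <- specGrid[[m]]
      kernel <- if (is.null(sp$kernel)) m else sp$kernel
      fit <- fitMultitrait(masked, markers,
                           kernel = kernel,
                           kernelParams = if (is.null(sp$kernelParams))
                             list() else sp$kernelParams,
                           gxe = isTRUE(sp$gxe),
                           nIter = nIter, burnIn = burnIn, thin = thin,
                           seed = seed + 1000L * f)
      pred <- predict(fit)
      rows <- mseByEnvTrait(data, pred, evalMask)
      rows <- cbind(fold = f, rows, scenario = scenario,
                    gxe = isTRUE(sp$gxe), method = m)
      perFold[[length(perFold) + 1L]] <- rows
    }
  }
  perFold <- do.call(rbind, perFold)
  agg <- aggregateMSE(perFold[, c("fold", "env", "trait", "method", "mse")])

  if (is.null(reference)) reference <- names(specGrid)[1]
  ref <- agg$acrossEnv[agg$acrossEnv$method == reference, ]
  imp <- do.call(rbind, lapply(names(specGrid), function(m) {
    cand <- agg$acrossEnv[agg$acrossEnv$method == m, ]
    idx <- match(cand$trait, ref$trait)
    data.frame(method = m, trait = cand$trait,
               mse = cand$mse,
               improvementOverRef = percentImprovement(ref$mse[idx], cand$mse))
  }))
  list(perFold = perFold, byEnv = agg$byEnv, acrossEnv = agg$acrossEnv,
       improvement = imp, folds = folds)
}
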