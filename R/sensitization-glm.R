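# Lagged-predictor elastic-net encoding models and sensitization
# classification.

.FAMILIES <- c("locomotion_state", "velocity", "scale", "shear", "zshift")

#' Build a lagged design matrix
#'
#' Expands the five predictor families (locomotion state, velocity, scale,
#' shear, Z-shift) into temporally shifted copies at every integer-frame
#' delay spanning -maxLagS..+maxLagS seconds. A positive delay means the
#' predictor leads the response (the column at delay d holds x(t - d)).
#' Rows with undefined shifted values are trimmed symmetrically at both ends.
#' Columns are z-scored; when `scaleStats` (from a previous design, normally
#' the pre-CSD epoch) is supplied, its means and SDs are reused so that
#' coefficients are comparable per physical unit across epochs. Zero-variance
#' columns are dropped and recorded.
#'
#' @param locomotion List with `state` (logical) and `velocity` series.
#' @param deformation List with `scale`, `shear`, `zshift` series.
#' @param frameRateHz Frame rate.
#' @param maxLagS Maximum lag in seconds (default 6).
#' @param rows Optional frame indices restricting the epoch (default all).
#' @param scaleStats Optional list with `mean`, `sd`, `dropped` from another
#'   design.
#' @return A `LaggedDesign` list: `matrix` (trimmed rows x columns), `meta`
#'   data.frame (`family`, `delay_s`, `delay_frames`), `rows` (frame indices
#'   of the retained rows), `scale_stats`.
#' @export
buildDesign <- function(locomotion, deformation, frameRateHz, maxLagS = 6,
                        rows = NULL, scaleStats = NULL) {
  series <- list(locomotion_state = as.numeric(locomotion$state),
                 velocity = as.numeric(locomotion$velocity),
                 scale = as.numeric(deformation$scale),
                 shear = as.numeric(deformation$shear),
                 zshift = as.numeric(deformation$zshift))
  n <- length(series[[1]])
  stopifnot(all(vapply(series, length, 1L) == n))
  if (is.null(rows)) rows <- seq_len(n)
  nd <- as.integer(round(maxLagS * frameRateHz))
  if (length(rows) <= 2 * nd + 1)
    stop("epoch shorter than twice the maximum lag", call. = FALSE)
  delays <- -nd:nd
  keep <- rows[(nd + 1):(length(rows) - nd)]
  cols <- vector("list", length(series) * length(delays))
  meta <- data.frame(family = rep(names(series), each = length(delays)),
                     delay_frames = rep(delays, times = length(series)))
  meta$delay_s <- meta$delay_frames / frameRateHz
  k <- 0L
  for (fam in names(series)) {
    x <- series[[fam]]
    for (d in delays) {
      k <- k + 1L
      cols[[k]] <- x[keep - d]
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- paste0(meta$family, "@", meta$delay_frames)
  if (is.null(scaleStats)) {
    mu <- colMeans(X)
    sds <- apply(X, 2, sd)
    dropped <- sds == 0
    scaleStats <- list(mean = mu, sd = sds, dropped = dropped)
  }
  X <- sweep(X, 2, scaleStats$mean)
  ok <- !scaleStats$dropped
  X[, ok] <- sweep(X[, ok, drop = FALSE], 2, scaleStats$sd[ok], "/")
  structure(list(matrix = X[, ok, drop = FALSE], meta = meta[ok, ],
                 dropped = meta[!ok, ], rows = keep,
                 scale_stats = scaleStats),
            class = "LaggedDesign")
}

# Gaussian deviance explained of predictions against a null prediction.
#' @noRd
.devExplained <- function(y, yhat, yNull) {
  sse <- sum((y - yhat)^2)
  sse0 <- sum((y - yNull)^2)
  if (sse0 == 0) return(0)
  1 - sse / sse0
}

#' Fit a lagged elastic-net encoding model
#'
#' Fits a Gaussian elastic net (alpha = 0.01, i.e. predominantly ridge) on
#' the first 75% of the epoch; the regularization strength is chosen by
#' 10-fold blocked (contiguous-fold) cross-validation within the training
#' segment at the minimum CV error. Deviance explained is evaluated on the
#' held-out last 25% against the intercept-only (training-mean) null model;
#' the afferent counts as well fit when held-out deviance explained reaches
#' `wellFitThreshold` (default 0.05).
#'
#' @param design A `LaggedDesign` from [buildDesign()].
#' @param z Standardized response series over the full recording (subset with
#'   `design$rows`) or of length `nrow(design$matrix)`.
#' @param trainFraction Fraction of the epoch used for training (default
#'   0.75, contiguous first block).
#' @param alpha Elastic-net mixing parameter (default 0.01).
#' @param seed Integer seed (CV folds are deterministic blocks, but glmnet
#'   internals are seeded for reproducibility).
#' @param nfolds Number of CV folds (default 10).
#' @param wellFitThreshold Held-out deviance-explained threshold (default
#'   0.05).
#' @return A `GlmFit` list: `beta` data.frame (`family`, `delay_s`,
#'   `delay_frames`, `beta`), `intercept`, `alpha`, `lambda`,
#'   `dev_explained_holdout`, `dev_explained_train`, `well_fit`.
#' @export
fitGlm <- function(design, z, trainFraction = 0.75, alpha = 0.01, seed = 1L,
                   nfolds = 10L, wellFitThreshold = 0.05) {
  X <- design$matrix
  y <- if (length(z) == nrow(X)) as.numeric(z) else as.numeric(z)[design$rows]
  stopifnot(length(y) == nrow(X))
  if (sd(y) == 0) stop("zero-variance response", call. = FALSE)
  nTrain <- floor(trainFraction * length(y))
  trainIdx <- seq_len(nTrain)
  holdIdx <- (nTrain + 1):length(y)
  foldid <- as.integer(ceiling(seq_len(nTrain) / (nTrain / nfolds)))
  foldid[foldid > nfolds] <- nfolds
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  cvf <- glmnet::cv.glmnet(X[trainIdx, , drop = FALSE], y[trainIdx],
                           alpha = alpha, foldid = foldid,
                           standardize = FALSE, family = "gaussian")
  lam <- cvf$lambda.min
  yNull <- mean(y[trainIdx])
  predHold <- as.numeric(predict(cvf, X[holdIdx, , drop = FALSE], s = lam))
  predTrain <- as.numeric(predict(cvf, X[trainIdx, , drop = FALSE], s = lam))
  devHold <- .devExplained(y[holdIdx], predHold, yNull)
  devTrain <- .devExplained(y[trainIdx], predTrain, yNull)
  b <- as.numeric(coef(cvf, s = lam))
  betaDf <- data.frame(family = design$meta$family,
                       delay_s = design$meta$delay_s,
                       delay_frames = design$meta$delay_frames,
                       beta = b[-1])
  structure(list(beta = betaDf, intercept = b[1], alpha = alpha,
                 lambda = lam, dev_explained_holdout = devHold,
                 dev_explained_train = devTrain,
                 well_fit = devHold >= wellFitThreshold,
                 train_idx = trainIdx, hold_idx = holdIdx, seed = seed,
                 nfolds = nfolds, threshold = wellFitThreshold),
            class = "GlmFit")
}

#' Per-family peak coefficient magnitudes
#'
#' @param fit A `GlmFit`.
#' @return Named vector: max |beta| over delays for each predictor family.
#' @export
familyPeakBeta <- function(fit) {
  v <- tapply(abs(fit$beta$beta), fit$beta$family, max)
  out <- setNames(numeric(length(.FAMILIES)), .FAMILIES)
  out[names(v)] <- as.numeric(v)
  out
}

#' Predictor-family contributions to deviance explained
#'
#' Refits the model after removing each family group (locomotion = state +
#' velocity; deformation = scale + shear + Z-shift; and each deformation
#' member individually) and reports the drop in held-out deviance explained,
#' floored at zero.
#'
#' @param design A `LaggedDesign`.
#' @param z Response series (as in [fitGlm()]).
#' @param fit The full-model `GlmFit`.
#' @return Named numeric vector of deviance-explained deltas for
#'   `locomotion`, `deformation`, `scale`, `shear`, `zshift`.
#' @export
familyContributions <- function(design, z, fit) {
  groups <- list(locomotion = c("locomotion_state", "velocity"),
                 deformation = c("scale", "shear", "zshift"),
                 scale = "scale", shear = "shear", zshift = "zshift")
  out <- setNames(numeric(length(groups)), names(groups))
  for (g in names(groups)) {
    keep <- !(design$meta$family %in% groups[[g]])
    sub <- design
    sub$matrix <- design$matrix[, keep, drop = FALSE]
    sub$meta <- design$meta[keep, ]
    red <- fitGlm(sub, z, alpha = fit$alpha, seed = fit$seed,
                  nfolds = fit$nfolds, wellFitThreshold = fit$threshold)
    out[g] <- max(0, fit$dev_explained_holdout - red$dev_explained_holdout)
  }
  out
}

#' Classify sensitization from pre/post encoding fits
#'
#' Decision table over the pre/post well-fit flags and per-family peak
#' coefficient magnitudes:
#' both well fit and any family's peak |beta| rises by at least
#' `relIncrease` (relative, default 10%) -> `sensitized_both_fit`; both well
#' fit, no family rises and at least one falls by `relIncrease` ->
#' `desensitized_worse`; both well fit otherwise -> `unchanged`; well fit
#' only post -> `sensitized_unmasked`; only pre -> `desensitized_lost`;
#' neither -> `never_fit`. An absolute floor on the peak change guards
#' against rises of near-zero baselines and against the upward noise bias of
#' a maximum over delays.
#'
#' @param fitPre,fitPost `GlmFit` objects for the same afferent.
#' @param relIncrease Relative change margin (default 0.10).
#' @param absFloor Minimum absolute peak-|beta| change (default 0.1, in
#'   units of the standardized response per predictor SD).
#' @return A `SensitizationCall` list: `category`, `family_summary_pre`,
#'   `family_summary_post`.
#' @export
classifySensitization <- function(fitPre, fitPost, relIncrease = 0.10,
                                  absFloor = 0.1) {
  pkPre <- familyPeakBeta(fitPre)
  pkPost <- familyPeakBeta(fitPost)
  category <- if (fitPre$well_fit && fitPost$well_fit) {
    rises <- pkPost >= pkPre * (1 + relIncrease) & (pkPost - pkPre) > absFloor
    falls <- pkPost <= pkPre * (1 - relIncrease) & (pkPre - pkPost) > absFloor
    if (any(rises)) "sensitized_both_fit"
    else if (any(falls)) "desensitized_worse"
    else "unchanged"
  } else if (fitPost$well_fit) "sensitized_unmasked"
  else if (fitPre$well_fit) "desensitized_lost"
  else "never_fit"
  structure(list(category = category, family_summary_pre = pkPre,
                 family_summary_post = pkPost),
            class = "SensitizationCall")
}

#' Is a call sensitized?
#'
#' @param call A `SensitizationCall`.
#' @return TRUE for `sensitized_both_fit` or `sensitized_unmasked`.
#' @export
isSensitized <- function(call)
  call$category %in% c("sensitized_both_fit", "sensitized_unmasked")

#' Cohort summary of sensitization calls
#'
#' Tabulates call categories and, when per-afferent ongoing-activity classes
#' are given, builds the sensitized-vs-ongoing-class contingency table with a
#' chi-squared test of independence.
#'
#' @param calls List of `SensitizationCall` objects.
#' @param ongoingClasses Optional character vector of ongoing-activity
#'   classes ("activated"/"suppressed"/"none"), aligned with `calls`.
#' @return List with `category_counts`, and when classes are given
#'   `contingency`, `chisq_statistic`, `p_value`, `degenerate` (TRUE when the
#'   table has a single row or column and the test is undefined).
#' @export
cohortSummary <- function(calls, ongoingClasses = NULL) {
  if (!length(calls)) stop("empty cohort", call. = FALSE)
  cats <- vapply(calls, function(x) x$category, character(1))
  out <- list(category_counts = table(cats))
  if (!is.null(ongoingClasses)) {
    stopifnot(length(ongoingClasses) == length(calls))
    sens <- vapply(calls, isSensitized, logical(1))
    tab <- table(sensitized = sens, ongoing = ongoingClasses)
    degenerate <- nrow(tab) < 2 || ncol(tab) < 2
    out$contingency <- tab
    out$degenerate <- degenerate
    if (!degenerate) {
      ct <- suppressWarnings(chisq.test(tab))
      out$chisq_statistic <- unname(ct$statistic)
      out$p_value <- ct$p.value
    }
  }
  out
}
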