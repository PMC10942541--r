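# Pipeline orchestration and cohort-level statistics.

#' Run the full analysis pipeline on one session
#'
#' Executes, in order: locomotion segmentation, deformation extraction,
#' per-ROI signal conditioning and event detection, fiber clustering, CSD
#' wave characterization, ongoing-activity classification, and pre/post
#' encoding-model fits with sensitization classification. Traces are
#' standardized against quiet-wakefulness samples of the baseline epoch so
#' that pre- and post-CSD activity share one scale. Sessions without a CSD
#' trigger skip the wave, ongoing-activity, and post-CSD model stages.
#'
#' @param session A [RecordingSession-class] or a path readable by
#'   [readSession()].
#' @param outDir Optional output directory for CSV tables and a JSON log.
#' @param seed Integer seed (HMM restarts, model CV).
#' @param fitGlms Logical; fit the per-fiber encoding models (default TRUE).
#' @param postMarginS Seconds after the wave offset excluded from the
#'   post-CSD model epoch (default 120).
#' @return A `PipelineReport` list with elements `locomotion`, `deformation`,
#'   `fibers` (FiberMap), `roi_events`, `fiber_z`, `fiber_events`, `wave`,
#'   `ongoing`, `glm` (per-fiber pre/post fits and `SensitizationCall`s),
#'   `summary` (named numbers), and `paths` of written files.
#' @export
runPipeline <- function(session, outDir = NULL, seed = 1L, fitGlms = TRUE,
                        postMarginS = 120) {
  if (is.character(session)) session <- readSession(session)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  rate <- frameRate(session)
  n <- nFrames(session)
  trigger <- csdTriggerFrame(session)
  hasCsd <- !is.na(trigger)
  preRows <- if (hasCsd) seq_len(trigger - 1L) else seq_len(n)

  loco <- stage("locomotion", locomotionSeries(session, seed = seed))
  deform <- stage("deformation", deformationSeries(session))
  quietPre <- loco$stillness_mask & seq_len(n) %in% preRows

  sig <- stage("signals", {
    zM <- dffM <- matrix(0, nRois(session), n)
    evs <- vector("list", nRois(session))
    for (i in seq_len(nRois(session))) {
      st <- standardizedTrace(roiTraces(session)[i, ],
                              neuropilTraces(session)[i, ],
                              quietPre, rate)
      zM[i, ] <- st$z
      dffM[i, ] <- st$dff
      evs[[i]] <- detectEvents(st$z, st$dff, rate)
    }
    list(z = zM, dff = dffM, events = evs)
  })

  graph <- stage("fiber_clustering", eventCorrelation(sig$events, quietPre))
  fibers <- clusterFibers(graph)
  fiberIds <- sort(unique(fibers))
  fiberZ <- t(vapply(fiberIds, function(f)
    fiberTrace(sig$z, which(fibers == f)), numeric(n)))
  fiberDff <- t(vapply(fiberIds, function(f)
    fiberTrace(sig$dff, which(fibers == f)), numeric(n)))
  fiberEvents <- lapply(seq_along(fiberIds), function(i)
    detectEvents(fiberZ[i, ], fiberDff[i, ], rate))

  wave <- NULL
  if (hasCsd) {
    wave <- stage("csd_wave", {
      win <- detectWaveWindow(fovTrace(session), trigger, rate)
      fits <- fitBinOnsets(session, win)
      est <- tryCatch(estimateSpeedDirection(fits), error = function(e) NULL)
      list(window = win, fits = fits, estimate = est)
    })
  }

  ongoing <- NULL
  if (hasCsd) {
    ongoing <- stage("ongoing_activity", {
      offsetFrame <- wave$window$offset_frame
      lapply(seq_along(fiberIds), function(i) {
        preB <- binOngoingRate(fiberEvents[[i]],
                               loco$stillness_mask & seq_len(n) < trigger,
                               rate)
        nPreBins <- floor((trigger - 1) / .frames(60, rate))
        preB <- preB[preB$bin <= nPreBins, ]
        shift <- function(m) c(m[offsetFrame:n], rep(FALSE, offsetFrame - 1L))
        evShift <- fiberEvents[[i]]
        evShift$onset_frame <- pmax(1L, evShift$onset_frame - offsetFrame + 1L)
        evShift$offset_frame <- evShift$offset_frame - offsetFrame + 1L
        evShift <- evShift[evShift$offset_frame >= 1L, ]
        attr(evShift, "n_frames") <- n - offsetFrame + 1L
        postB <- binOngoingRate(evShift, shift(loco$stillness_mask)[seq_len(n - offsetFrame + 1L)],
                                rate)
        classifyOngoingChange(preB, postB)
      })
    })
  }

  glm <- NULL
  if (fitGlms) {
    glm <- stage("sensitization_glm", {
      desPre <- buildDesign(loco, deform, rate, rows = preRows)
      fitsPre <- lapply(seq_along(fiberIds), function(i)
        fitGlm(desPre, fiberZ[i, ], seed = seed))
      out <- list(design_pre = desPre, fits_pre = fitsPre)
      if (hasCsd) {
        postStart <- wave$window$offset_frame + .frames(postMarginS, rate)
        postRows <- postStart:n
        desPost <- buildDesign(loco, deform, rate, rows = postRows,
                               scaleStats = desPre$scale_stats)
        fitsPost <- lapply(seq_along(fiberIds), function(i)
          fitGlm(desPost, fiberZ[i, ], seed = seed))
        calls <- lapply(seq_along(fiberIds), function(i)
          classifySensitization(fitsPre[[i]], fitsPost[[i]]))
        out$design_post <- desPost
        out$fits_post <- fitsPost
        out$calls <- calls
      }
      out
    })
  }

  summary <- c(
    n_rois = nRois(session), n_fibers = length(fiberIds),
    bout_rate_per_min = boutRate(loco$bouts, n / rate / 60),
    stillness_occupancy = {
      occ <- vapply(seq_along(fiberIds), function(i) {
        ind <- eventIndicator(fiberEvents[[i]], n)
        mean(ind[quietPre])
      }, numeric(1))
      mean(occ)
    })
  if (hasCsd && !is.null(wave$estimate)) {
    summary <- c(summary,
                 wave_speed_mm_per_min = wave$estimate$speed_mm_per_min,
                 wave_direction_deg = wave$estimate$direction_deg)
  }
  if (!is.null(ongoing)) {
    cls <- vapply(ongoing, function(x) x$classification, character(1))
    summary <- c(summary,
                 frac_activated = mean(cls == "activated"),
                 frac_suppressed = mean(cls == "suppressed"))
  }
  if (!is.null(glm$calls)) {
    cats <- vapply(glm$calls, function(x) x$category, character(1))
    summary <- c(summary, frac_sensitized = mean(cats %in%
      c("sensitized_both_fit", "sensitized_unmasked")))
  }

  report <- structure(list(locomotion = loco, deformation = deform,
                           fibers = fibers, roi_events = sig$events,
                           fiber_z = fiberZ, fiber_events = fiberEvents,
                           graph = graph, wave = wave, ongoing = ongoing,
                           glm = glm, summary = summary,
                           paths = character(0)),
                      class = "PipelineReport")
  if (!is.null(outDir)) report$paths <- .writeReport(report, session, outDir)
  report
}

#' @noRd
.writeReport <- function(report, session, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  paths <- character(0)
  p <- file.path(outDir, "bouts.csv")
  write.csv(report$locomotion$bouts, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(outDir, "fiber_map.csv")
  write.csv(data.frame(roi_id = seq_along(report$fibers) - 1L,
                       fiber_id = as.integer(report$fibers)), p,
            row.names = FALSE)
  paths <- c(paths, p)
  evTab <- do.call(rbind, lapply(seq_along(report$roi_events), function(i) {
    ev <- report$roi_events[[i]]
    if (!nrow(ev)) return(NULL)
    data.frame(roi = i - 1L,
               onset_s = (ev$onset_frame - 1) / frameRate(session),
               offset_s = ev$offset_frame / frameRate(session),
               peak_dff = ev$peak_dff)
  }))
  p <- file.path(outDir, "events.csv")
  write.csv(if (is.null(evTab)) data.frame() else evTab, p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(report$wave)) {
    p <- file.path(outDir, "wave_bins.csv")
    write.csv(as.data.frame(report$wave$fits), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(report$ongoing)) {
    p <- file.path(outDir, "ongoing_classes.csv")
    write.csv(data.frame(
      fiber = seq_along(report$ongoing) - 1L,
      class = vapply(report$ongoing, function(x) x$classification, character(1)),
      latency_min = vapply(report$ongoing, function(x) x$onset_latency_min, numeric(1)),
      duration_min = vapply(report$ongoing, function(x) x$duration_min, numeric(1)),
      baseline_rate = vapply(report$ongoing, function(x) x$baseline_mean, numeric(1))),
      p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(report$glm$calls)) {
    p <- file.path(outDir, "sensitization_calls.csv")
    write.csv(data.frame(
      fiber = seq_along(report$glm$calls) - 1L,
      category = vapply(report$glm$calls, function(x) x$category, character(1))),
      p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(outDir, "summary.json")
  jsonlite::write_json(as.list(report$summary), p, auto_unbox = TRUE,
                       digits = NA)
  paths <- c(paths, p)
  paths
}

#' Paired two-sample statistics with bootstrap CI
#'
#' Two-tailed paired t-test or Wilcoxon matched-pairs signed-rank test, plus
#' a seeded percentile bootstrap confidence interval of the mean difference
#' (2,000 resamples by default).
#'
#' @param pre,post Paired per-session metrics (equal length, >= 3).
#' @param test "paired_t" or "wilcoxon".
#' @param nBoot Bootstrap resamples (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @param confLevel Confidence level (default 0.95).
#' @return List with `statistic`, `p`, `ci` (length 2), `mean_diff`,
#'   `degenerate` (TRUE when all differences are zero, where the Wilcoxon
#'   test is undefined and p is reported as 1).
#' @export
pairedStats <- function(pre, post, test = c("paired_t", "wilcoxon"),
                        nBoot = 2000L, seed = 1L, confLevel = 0.95) {
  test <- match.arg(test)
  if (length(pre) != length(post)) stop("pre/post lengths differ", call. = FALSE)
  if (length(pre) < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- post - pre
  degenerate <- all(d == 0)
  if (test == "paired_t") {
    ht <- t.test(post, pre, paired = TRUE)
    statistic <- unname(ht$statistic)
    p <- ht$p.value
    if (degenerate) { statistic <- 0; p <- 1 }
  } else {
    if (degenerate) {
      statistic <- NA_real_; p <- 1
    } else {
      ht <- suppressWarnings(wilcox.test(post, pre, paired = TRUE))
      statistic <- unname(ht$statistic)
      p <- ht$p.value
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  boots <- vapply(seq_len(nBoot), function(b)
    mean(d[sample.int(length(d), replace = TRUE)]), numeric(1))
  a <- (1 - confLevel) / 2
  list(statistic = statistic, p = p,
       ci = unname(quantile(boots, c(a, 1 - a))), mean_diff = mean(d),
       degenerate = degenerate)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment; adjusted values are monotone and
#' never smaller than the raw p-values.
#'
#' @param pValues Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
fdrAdjust <- function(pValues) {
  if (any(!is.finite(pValues) | pValues < 0 | pValues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pValues, method = "BH")
}
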