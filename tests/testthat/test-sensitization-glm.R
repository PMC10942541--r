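# small helper: design from a cached session's planted series
plainDesign <- function() {
  if (!is.null(.fixtureCache$design)) return(.fixtureCache$design)
  gen <- cachedSession("plain")
  loco <- list(state = gen$truth$locomotion$state,
               velocity = gen$truth$locomotion$velocity)
  des <- buildDesign(loco, gen$truth$deformation, frameRate(gen$session))
  .fixtureCache$design <- des
  des
}

test_that("lagged design has families x delays columns with exact shifts", {
  n <- 400
  loco <- list(state = rep(c(FALSE, TRUE), n / 2), velocity = rnorm(n))
  def <- list(scale = rnorm(n), shear = rnorm(n), zshift = rnorm(n))
  des <- buildDesign(loco, def, frameRateHz = 1)
  expect_equal(ncol(des$matrix), 5 * 13)   # 13 delays per family at 1 Hz
  expect_equal(nrow(des$matrix), n - 12)
  # impulse shift oracle: impulse at frame k appears at row k + d - nd
  imp <- numeric(n); k <- 200; imp[k] <- 1
  des2 <- buildDesign(list(state = rep(c(FALSE, TRUE), n / 2), velocity = imp),
                      def, frameRateHz = 1)
  for (d in c(-6, 0, 6)) {
    col <- which(des2$meta$family == "velocity" & des2$meta$delay_frames == d)
    rowHit <- which(abs(des2$matrix[, col]) == max(abs(des2$matrix[, col])))
    expect_equal(des2$rows[rowHit], k + d)
  }
  # constant predictor: its columns are dropped and recorded
  def0 <- def; def0$shear <- rep(1, n)
  des3 <- buildDesign(loco, def0, frameRateHz = 1)
  expect_equal(ncol(des3$matrix), 4 * 13)
  expect_true(all(des3$dropped$family == "shear"))
  expect_error(buildDesign(loco, def, 1, rows = 1:10), "shorter")
})

test_that("elastic-net fit attains near-perfect deviance on exact linear responses", {
  des <- plainDesign()
  col <- which(des$meta$family == "zshift" & des$meta$delay_frames == 0)
  z <- 0.7 * des$matrix[, col]
  fit <- fitGlm(des, z, seed = 1)
  expect_gte(fit$dev_explained_holdout, 0.99)
  expect_true(fit$well_fit)
  pk <- fit$beta[which.max(abs(fit$beta$beta)), ]
  expect_equal(pk$family, "zshift")
  expect_equal(pk$delay_frames, 0)
})

test_that("planted couplings are recovered within 20% at the planted delay", {
  des <- plainDesign()
  X <- des$matrix; meta <- des$meta
  set.seed(13)
  errs <- c(); delays <- c()
  for (beta in c(0.5, 1.0)) for (fam in c("zshift", "scale")) {
    col <- which(meta$family == fam & meta$delay_frames == 0)
    drive <- beta * X[, col]
    z <- drive + rnorm(nrow(X), 0, sd(drive))     # SNR 1
    fit <- fitGlm(des, z, seed = 1)
    bf <- fit$beta[fit$beta$family == fam, ]
    pk <- max(abs(bf$beta))
    errs <- c(errs, abs(pk - beta) / beta)
    delays <- c(delays, bf$delay_frames[which.max(abs(bf$beta))])
  }
  expect_lte(median(errs), 0.2)
  expect_true(all(abs(delays) <= 1))
})

test_that("pure-noise responses are rarely called well fit", {
  des <- plainDesign()
  set.seed(14)
  wf <- vapply(1:25, function(i)
    fitGlm(des, rnorm(nrow(des$matrix)), seed = i)$well_fit, logical(1))
  expect_lte(mean(wf), 0.05 + 1e-9)
  expect_error(fitGlm(des, rep(1, nrow(des$matrix))), "zero-variance")
})

test_that("family ablation attributes deviance to the driving family", {
  des <- plainDesign()
  X <- des$matrix; meta <- des$meta
  set.seed(15)
  zc <- X[, which(meta$family == "zshift" & meta$delay_frames == 0)]
  z <- 0.8 * zc + rnorm(nrow(X), 0, sd(zc))
  fit <- fitGlm(des, z, seed = 1)
  fc <- familyContributions(des, z, fit)
  expect_gt(fc[["deformation"]], fc[["locomotion"]] + 0.05)
  sc <- X[, which(meta$family == "locomotion_state" & meta$delay_frames == 0)]
  z2 <- 0.8 * sc + rnorm(nrow(X), 0, sd(sc))
  fc2 <- familyContributions(des, z2, fitGlm(des, z2, seed = 1))
  expect_gt(fc2[["locomotion"]], fc2[["deformation"]])
  # null response: all deltas ~ 0
  fc0 <- familyContributions(des, rnorm(nrow(X)), fitGlm(des, rnorm(nrow(X)), seed = 2))
  expect_true(all(fc0 < 0.02))
})

test_that("sensitization decision table covers all six categories", {
  mkFit <- function(wellFit, peaks) {
    beta <- data.frame(family = names(peaks), delay_s = 0, delay_frames = 0,
                       beta = as.numeric(peaks))
    structure(list(beta = beta, well_fit = wellFit), class = "GlmFit")
  }
  fams <- c(locomotion_state = 0.2, velocity = 0.1, scale = 0.5,
            shear = 0.4, zshift = 0.5)
  pre <- mkFit(TRUE, fams)
  expect_equal(classifySensitization(pre, mkFit(TRUE, fams * c(1, 1, 2, 2, 2)))$category,
               "sensitized_both_fit")
  expect_equal(classifySensitization(pre, mkFit(TRUE, fams))$category, "unchanged")
  expect_equal(classifySensitization(pre, mkFit(TRUE, fams * 0.5))$category,
               "desensitized_worse")
  expect_equal(classifySensitization(pre, mkFit(FALSE, fams * 0))$category,
               "desensitized_lost")
  expect_equal(classifySensitization(mkFit(FALSE, fams * 0), mkFit(TRUE, fams))$category,
               "sensitized_unmasked")
  expect_equal(classifySensitization(mkFit(FALSE, fams * 0), mkFit(FALSE, fams * 0))$category,
               "never_fit")
  # small relative changes below the margin stay unchanged
  expect_equal(classifySensitization(pre, mkFit(TRUE, fams * 1.05))$category,
               "unchanged")
})

test_that("cohort summaries tabulate calls and test independence", {
  mkCall <- function(cat) structure(list(category = cat), class = "SensitizationCall")
  calls <- lapply(c(rep("sensitized_both_fit", 10), rep("never_fit", 30)), mkCall)
  ong <- rep(c("activated", "none"), 20)
  cs <- cohortSummary(calls, ong)
  expect_equal(sum(cs$category_counts), 40)
  expect_false(cs$degenerate)
  expect_true(cs$p_value >= 0 && cs$p_value <= 1)
  # all-one-category cohort: degenerate table flagged
  csd <- cohortSummary(lapply(rep("never_fit", 5), mkCall), rep("none", 5))
  expect_true(csd$degenerate)
  expect_error(cohortSummary(list()), "empty")
  # planted dependence is detected at adequate n
  set.seed(16)
  ong2 <- rep(c("activated", "none"), each = 60)
  calls2 <- lapply(seq_along(ong2), function(i)
    mkCall(if (ong2[i] == "activated" && runif(1) < 0.6) "sensitized_both_fit"
           else "never_fit"))
  expect_lt(cohortSummary(calls2, ong2)$p_value, 0.01)
})
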