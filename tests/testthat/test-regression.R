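test_that("no-intercept OLS reproduces hand-derived fits", {
  # identical vectors: coefficient 1, zero residuals
  v <- c(0, 2, 5, 1, 3)
  fit <- fit_section(v, v)
  expect_equal(unname(fit$coefficients), 1)
  expect_equal(fit$residuals, rep(0, 5))
  expect_equal(fit$rank, 1L)

  # u-hat = sum(t*c)/sum(c^2) = 6/3 = 2
  fit <- fit_section(c(1, 2, 3), c(1, 1, 1))
  expect_equal(unname(fit$coefficients), 2)
  expect_equal(fit$residuals, c(-1, 0, 1))
  expect_equal(fit$fitted + fit$residuals, c(1, 2, 3))
})

test_that("collinear controls give a rank-deficient minimum-norm fit", {
  set.seed(2)
  c1 <- stats::runif(50)
  chip <- 2 * c1 + stats::rnorm(50, sd = 0.1)
  fit2 <- fit_section(chip, cbind(a = c1, b = 3 * c1))
  expect_equal(fit2$rank, 1L)
  fit1 <- fit_section(chip, c1)
  expect_equal(fit2$fitted, fit1$fitted, tolerance = 1e-9)
  expect_equal(fit2$residuals, fit1$residuals, tolerance = 1e-9)
})

test_that("degenerate inputs error or pass through as specified", {
  expect_error(fit_section(c(1, 2), cbind(c(1, 0), c(0, 1))),
               "too few observations")
  expect_error(fit_section(c(1, NA, 3), c(1, 1, 1)), "non-finite")
  expect_error(fit_section(c(1, 2, 3), c(1, 1)), "different lengths")

  # all-zero control: rank 0, residuals equal the observations
  fit <- fit_section(c(1, 2, 3), c(0, 0, 0))
  expect_equal(fit$rank, 0L)
  expect_equal(unname(fit$coefficients), 0)
  expect_equal(fit$residuals, c(1, 2, 3))
})

test_that("coefficients match an independent normal-equations solve", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(10:200, 1L)
    K <- sample(1:3, 1L)
    C <- matrix(stats::rnorm(n * K), n, K)
    chip <- stats::rnorm(n)
    fit <- fit_section(chip, C)
    expect_equal(unname(fit$coefficients), normal_equations_fit(chip, C),
                 tolerance = 1e-8)
    # normal equations: residuals orthogonal to every control
    for (k in seq_len(K)) {
      expect_lt(abs(sum(fit$residuals * C[, k])) /
                  (sqrt(sum(fit$residuals^2)) * sqrt(sum(C[, k]^2)) + 1e-12),
                1e-8)
    }
  }
})

test_that("a control orthogonal to both chip and the fit changes nothing", {
  set.seed(13)
  n <- 100L
  c1 <- stats::rnorm(n)
  chip <- 1.5 * c1 + stats::rnorm(n, sd = 0.2)
  fit1 <- fit_section(chip, c1)
  # build a vector orthogonal to chip and c1
  ortho <- stats::rnorm(n)
  basis <- qr.Q(qr(cbind(chip, c1)))
  ortho <- ortho - basis %*% crossprod(basis, ortho)
  fit2 <- fit_section(chip, cbind(c1, drop(ortho)))
  expect_equal(max(abs(fit2$residuals - fit1$residuals)), 0, tolerance = 1e-9)
  expect_equal(unname(fit2$coefficients[2L]), 0, tolerance = 1e-9)
})

test_that("optional intercept shifts the fit but defaults off", {
  chip <- c(2, 3, 4)
  ctrl <- c(0, 1, 2)
  no_int <- fit_section(chip, ctrl)
  with_int <- fit_section(chip, ctrl, intercept = TRUE)
  expect_equal(unname(with_int$coefficients),
               c(2, 1))  # chip = 2 + 1 * ctrl exactly
  expect_equal(with_int$residuals, rep(0, 3), tolerance = 1e-12)
  expect_gt(sum(no_int$residuals^2), 0)
})

test_that("normalize_section regresses out shared structure", {
  set.seed(23)
  counts <- random_counts(600, lambda = 0.8)
  chip_tr <- make_track(5L * counts)
  ctrl_tr <- make_track(counts)
  ns <- normalize_section(chip_tr, list(input = ctrl_tr), "+")
  expect_equal(max(abs(ns$residuals)), 0, tolerance = 1e-9)
  expect_equal(unname(ns$fit$coefficients), 5, tolerance = 1e-9)

  # all-zero controls: nothing to regress out, residuals = smoothed chip
  zero_tr <- make_track(integer(600))
  ns <- normalize_section(chip_tr, list(input = zero_tr), "+")
  sm <- smooth_and_sample(chip_tr, "+")
  expect_equal(ns$residuals, sm$values)
  expect_equal(ns$fit$rank, 0L)

  # all-zero ChIP: pass-through of zero residuals without fitting
  expect_message(
    ns <- normalize_section(zero_tr, list(input = ctrl_tr), "+"),
    "all-zero ChIP")
  expect_equal(ns$residuals, rep(0, length(ns$centres)))
  expect_null(ns$fit)
})

test_that("residuals are invariant to control depth and scale with ChIP depth", {
  set.seed(29)
  base <- random_counts(800, lambda = 0.6)
  peak <- integer(800)
  peak[300:320] <- 3L
  chip_tr <- make_track(base + peak)
  ctrl_tr <- make_track(base)
  ref <- normalize_section(chip_tr, list(ctrl_tr), "+")$residuals
  for (c_scale in c(0.1, 1, 7.3)) {
    # scaling a control only rescales its coefficient
    scaled_ctrl <- ctrl_tr
    scaled_ctrl$counts_sense <- ctrl_tr$counts_sense * c_scale
    res <- normalize_section(chip_tr, list(scaled_ctrl), "+")$residuals
    expect_equal(max(abs(res - ref)) / (max(abs(ref)) + 1e-300), 0,
                 tolerance = 1e-9)
    # scaling the ChIP sample scales the residuals exactly
    scaled_chip <- chip_tr
    scaled_chip$counts_sense <- chip_tr$counts_sense * c_scale
    res <- normalize_section(scaled_chip, list(ctrl_tr), "+")$residuals
    expect_equal(max(abs(res - c_scale * ref)) /
                   (c_scale * max(abs(ref)) + 1e-300), 0, tolerance = 1e-9)
  }
})

test_that("sense and antisense strands are fitted independently", {
  set.seed(37)
  sense <- random_counts(500)
  anti <- random_counts(500)
  chip_tr <- make_track(2L * sense, 3L * anti)
  ctrl_tr <- make_track(sense, anti)
  fit_p <- normalize_section(chip_tr, list(ctrl_tr), "+")$fit
  fit_m <- normalize_section(chip_tr, list(ctrl_tr), "-")$fit
  expect_equal(unname(fit_p$coefficients), 2, tolerance = 1e-9)
  expect_equal(unname(fit_m$coefficients), 3, tolerance = 1e-9)
})
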