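px <- 0.16
params_default <- detection_params(psf_sigma = 0.13 / px)

test_that("detection parameter invariants are enforced", {
  expect_error(detection_params(localization_error = 0), "localization_error")
  expect_error(detection_params(deflation_loops = -1), "deflation_loops")
  expect_error(detection_params(psf_sigma = 1, window_radius = 1),
               "window_radius")
})

test_that("an all-zero frame yields no candidates", {
  expect_equal(nrow(detect_candidates(matrix(0, 20, 20), params_default)), 0)
})

test_that("a clean bright spot yields exactly one candidate at its peak", {
  fr <- render_spot_window(21, 10, 7, 2000, 5, 0.13 / px)
  cand <- detect_candidates(fr, params_default)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$col, 11)  # x = 10 px -> column 11
  expect_equal(cand$row, 8)
})

test_that("well-separated SNR-10 spots are both detected almost always", {
  s_px <- 0.13 / px
  photons <- photons_for_snr(10, 10, s_px)
  sep <- 10 * s_px
  hits <- 0L
  set.seed(5)
  for (i in 1:100) {
    mu <- render_spot_window(31, 10, 15, photons, 10, s_px) +
          render_spot_window(31, 10 + sep, 15, photons, 0, s_px)
    fr <- matrix(rpois(length(mu), mu), nrow(mu))
    if (nrow(detect_candidates(fr, params_default)) == 2L) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("frames smaller than the fitting window are rejected", {
  expect_error(detect_candidates(matrix(0, 3, 3), params_default), "window")
})

test_that("noiseless fits recover sub-pixel positions to 0.01 px", {
  s_px <- 0.13 / px
  fr <- render_spot_window(21, 5.30, 7.80, 2000, 5, s_px)
  cand <- detect_candidates(fr, params_default)
  fit <- fit_gaussian(fr, cand[1, ], params_default, px)
  expect_lt(abs(fit$x / px - 5.30), 0.01)
  expect_lt(abs(fit$y / px - 7.80), 0.01)
  expect_lt(abs(fit$amplitude - 2000) / 2000, 0.01)
  expect_lt(abs(fit$background - 5), 0.1)
  expect_true(fit$converged)
})

test_that("a spot on a pixel center with symmetric window fits exactly there", {
  s_px <- 0.13 / px
  fr <- render_spot_window(21, 10, 10, 1000, 2, s_px)
  fit <- fit_gaussian(fr, list(row = 11, col = 11), params_default, px)
  expect_equal(fit$x / px, 10, tolerance = 1e-6)
  expect_equal(fit$y / px, 10, tolerance = 1e-6)
})

test_that("localizations are translation-equivariant under pixel shifts", {
  s_px <- 0.13 / px
  fr1 <- render_spot_window(25, 8.3, 9.1, 2000, 5, s_px)
  fr2 <- render_spot_window(25, 8.3 + 3, 9.1 + 2, 2000, 5, s_px)
  f1 <- fit_gaussian(fr1, detect_candidates(fr1, params_default)[1, ],
                     params_default, px)
  f2 <- fit_gaussian(fr2, detect_candidates(fr2, params_default)[1, ],
                     params_default, px)
  expect_equal(f2$x - f1$x, 3 * px, tolerance = 1e-3)
  expect_equal(f2$y - f1$y, 2 * px, tolerance = 1e-3)
})

test_that("candidate count is monotone in the localization error", {
  set.seed(8)
  mu <- render_spot_window(31, 12, 14, 300, 10, 0.13 / px) +
        render_spot_window(31, 22, 20, 150, 0, 0.13 / px)
  fr <- matrix(rpois(length(mu), mu), nrow(mu))
  errs <- c(1e-9, 1e-6, 1e-3, 1e-1)
  counts <- vapply(errs, function(e) {
    nrow(detect_candidates(fr, detection_params(localization_error = e,
                                                psf_sigma = 0.13 / px)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("false positives on pure noise stay within the stated bound", {
  # loose contract: FP rate per tested pixel <= 10x localization_error
  set.seed(13)
  err <- 1e-3
  p <- detection_params(localization_error = err, psf_sigma = 0.13 / px)
  n_frames <- 40
  fp <- 0L; tests <- 0L
  for (i in seq_len(n_frames)) {
    fr <- matrix(rnorm(64 * 64, mean = 100, sd = 5), 64, 64)
    fp <- fp + nrow(detect_candidates(fr, p))
    tests <- tests + 64L * 64L
  }
  expect_lte(fp / tests, 10 * err)
})

test_that("a movie of empty frames localizes to an empty table", {
  mov <- structure(list(frames = replicate(3, matrix(0, 20, 20),
                                           simplify = FALSE),
                        pixel_size = px, dt = 0.1), class = "movie")
  locs <- localize_movie(mov, params_default)
  expect_equal(nrow(locs), 0)
})

test_that("deflation recovers a dim spot under a bright neighbor", {
  s_px <- 0.13 / px
  sep <- 2 * s_px
  set.seed(17)
  mu <- render_spot_window(25, 12, 12, 3000, 5, s_px) +
        render_spot_window(25, 12 + sep, 12, 600, 0, s_px)
  fr <- matrix(rpois(length(mu), mu), nrow(mu))
  mov <- structure(list(frames = list(fr), pixel_size = px, dt = 0.1),
                   class = "movie")
  locs <- localize_movie(mov, params_default)
  expect_equal(nrow(locs), 2)
  expect_true(any(locs$pass > 0))
  # both true positions recovered within half a pixel
  d1 <- min(abs(locs$x / px - 12))
  d2 <- min(abs(locs$x / px - (12 + sep)))
  expect_lt(d1, 0.5)
  expect_lt(d2, 0.5)
})

test_that("deflation does not re-detect residuals of a clean single spot", {
  s_px <- 0.13 / px
  mu <- render_spot_window(25, 10.4, 13.6, 2000, 5, s_px)
  mov <- structure(list(frames = list(mu), pixel_size = px, dt = 0.1),
                   class = "movie")
  p0 <- detection_params(psf_sigma = s_px, deflation_loops = 0)
  p3 <- detection_params(psf_sigma = s_px, deflation_loops = 3)
  l0 <- localize_movie(mov, p0)
  l3 <- localize_movie(mov, p3)
  expect_equal(nrow(l0), 1)
  expect_equal(nrow(l3), 1)
  expect_equal(l3$x, l0$x, tolerance = 1e-6)
})

test_that("localization RMSE approaches the CRLB on noisy spots", {
  # quick version of the precision benchmark (the full-size run lives in
  # the acceptance suite): 500 SNR-10 spots, RMSE within 1.3x CRLB
  s_px <- 0.13 / px
  bg <- 10
  photons <- photons_for_snr(10, bg, s_px)
  p <- detection_params(psf_sigma = s_px)
  size <- 2L * p$window_radius + 1L
  ctr <- p$window_radius  # x of the central pixel (0-based px units)
  set.seed(21)
  err <- matrix(NA_real_, 500, 2)
  for (i in 1:500) {
    x0 <- ctr + runif(1, -0.5, 0.5); y0 <- ctr + runif(1, -0.5, 0.5)
    mu <- render_spot_window(size, x0, y0, photons, bg, s_px)
    fr <- matrix(rpois(length(mu), mu), nrow(mu))
    fit <- fit_gaussian(fr, list(row = ctr + 1L, col = ctr + 1L), p, 1)
    if (fit$converged) err[i, ] <- c(fit$x - x0, fit$y - y0)
  }
  err <- err[stats::complete.cases(err), ]
  crlb <- crlb_localization(photons, bg, s_px)
  rmse <- sqrt(mean(err^2))
  expect_lt(rmse, 1.3 * crlb)
})
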