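px <- 0.16

test_that("a constant image gives a flat profile", {
  img <- matrix(7, 40, 40)
  pr <- extract_profile(img, rbind(c(1, 3), c(5, 3)), px)
  expect_true(all(abs(pr$intensity - 7) < 1e-9))
  expect_equal(pr$arclength[1], 0)
  expect_true(all(diff(pr$arclength) > 0))
})

test_that("profiles reproduce stripe values along a perpendicular path", {
  img <- matrix(rep(1:40, each = 40), 40, 40)  # value = column index
  pr <- extract_profile(img, rbind(c(0.5, 3), c(5.5, 3)), px,
                        width = 0.3, step = px)
  # value at arclength s: column = x_px + 1 with x_px = (0.5 + s)/px
  expected <- (0.5 + pr$arclength) / px + 1
  expect_true(all(abs(pr$intensity - expected) < 1e-6))
})

test_that("a synthetic intensity peak is located at the right arclength", {
  img <- matrix(0, 50, 100)
  s_peak <- 10  # um along a straight path starting at x = 0.5 um
  for (r in 1:50) {
    x_um <- (seq_len(100) - 1) * px
    img[r, ] <- 100 * exp(-((x_um - 0.5 - s_peak)^2) / (2 * 0.5^2))
  }
  pr <- extract_profile(img, rbind(c(0.5, 4), c(15, 4)), px, step = 0.1)
  expect_lt(abs(pr$arclength[which.max(pr$intensity)] - s_peak), 0.1 + 1e-9)
})

test_that("profile extraction is linear in image intensity", {
  set.seed(51)
  img <- matrix(runif(40 * 40, 0, 100), 40, 40)
  path <- rbind(c(1, 2), c(4, 4))
  p1 <- extract_profile(img, path, px)
  p3 <- extract_profile(3 * img, path, px)
  expect_equal(p3$intensity, 3 * p1$intensity)
})

test_that("paths leaving the image are rejected naming the vertex", {
  img <- matrix(0, 20, 20)
  expect_error(extract_profile(img, rbind(c(1, 1), c(50, 1)), px),
               "vertex 2")
})

test_that("background subtraction follows the stated contract", {
  expect_equal(as.numeric(subtract_background(c(10, 20), 10)), c(0, 10))
  expect_equal(as.numeric(subtract_background(c(5, 8), 0)), c(5, 8))
  out <- subtract_background(c(5, 20), 10)
  expect_equal(attr(out, "n_negative"), 1)
  expect_equal(as.numeric(out), c(-5, 10))
  clipped <- subtract_background(c(5, 20), 10, clip = TRUE)
  expect_equal(as.numeric(clipped), c(0, 10))
  expect_error(subtract_background(1, NA), "finite")
})

test_that("background-subtracted blank regions average to zero", {
  set.seed(52)
  b <- 40
  img <- matrix(rnorm(50 * 50, mean = b, sd = 3), 50, 50)
  pr <- extract_profile(img, rbind(c(1, 4), c(6, 4)), px)
  sub <- subtract_background(pr, mean(img))
  expect_lt(abs(mean(sub$intensity)), 1)
})

test_that("intensity ratios behave on shared grids", {
  a <- structure(data.frame(arclength = seq(0, 5, 0.1), intensity = 10),
                 class = c("profile_curve", "data.frame"))
  b <- a; b$intensity <- 5
  expect_true(all(intensity_ratio(a, a)$ratio == 1))
  expect_true(all(intensity_ratio(a, b)$ratio == 2))
  # linearly varying ratio is recovered
  grid <- seq(0, 5, 0.1)
  target <- 0.5 + (2 - 0.5) * grid / 5
  a2 <- a; a2$intensity <- target * b$intensity
  expect_equal(intensity_ratio(a2, b)$ratio, target, tolerance = 1e-9)
  # grid mismatch is rejected; resampling fixes it
  c2 <- structure(data.frame(arclength = seq(0, 5, 0.25), intensity = 10),
                  class = c("profile_curve", "data.frame"))
  expect_error(intensity_ratio(a, c2), "grid")
  expect_silent(intensity_ratio(a, resample_profile(c2, a$arclength)))
})

test_that("zero denominators are masked and counted", {
  a <- structure(data.frame(arclength = 0:2, intensity = c(1, 2, 3)),
                 class = c("profile_curve", "data.frame"))
  b <- structure(data.frame(arclength = 0:2, intensity = c(1, 0, 3)),
                 class = c("profile_curve", "data.frame"))
  r <- intensity_ratio(a, b)
  expect_true(is.na(r$ratio[2]))
  expect_equal(attr(r, "n_masked"), 1)
})

test_that("edge-box intensities are background-corrected", {
  img <- matrix(10, 60, 60)
  img[, 50:60] <- 35  # bright rim on the right
  boxes <- list(c(8.0, 1, 9.0, 2), c(8.0, 3, 9.0, 4))
  bg_box <- c(1, 1, 3, 3)
  out <- measure_edge_intensity(img, boxes, bg_box, pixel_size = px)
  expect_equal(unname(out$values), c(25, 25))
  expect_equal(unname(out$summary["median"]), 25)
  # boxes identical to background content -> 0
  out0 <- measure_edge_intensity(img, list(c(1, 1, 2, 2)), bg_box, px)
  expect_equal(unname(out0$values), 0)
  expect_error(measure_edge_intensity(img, list(), bg_box, px), "empty")
})

test_that("myelination classes follow the fragment-length rules", {
  # no MBP along the whole axon -> unmyelinated
  un <- classify_myelination(data.frame(start = 0, end = 50, signal = "nav"))
  expect_equal(un$class, "unmyelinated")
  # >10 um channel fragments interspaced with MBP -> partially myelinated
  pm <- classify_myelination(data.frame(
    start = c(0, 15, 35), end = c(15, 35, 47),
    signal = c("nav", "mbp", "nav")))
  expect_equal(pm$class, "partially_myelinated")
  # node-like fragments (<10 um) interspaced with MBP -> myelinated
  my <- classify_myelination(data.frame(
    start = c(0, 2, 32, 34), end = c(2, 32, 34, 64),
    signal = c("nav", "mbp", "nav", "mbp")))
  expect_equal(my$class, "myelinated")
  expect_false(my$boundary_case)
})

test_that("exactly-10-um fragments go to partially_myelinated, flagged", {
  call <- classify_myelination(data.frame(
    start = c(0, 10), end = c(10, 30), signal = c("nav", "mbp")))
  expect_equal(call$class, "partially_myelinated")
  expect_true(call$boundary_case)
})

test_that("malformed fragment tables are rejected", {
  expect_error(classify_myelination(data.frame(start = c(5, 0),
                                               end = c(6, 1),
                                               signal = "nav")), "sorted")
  expect_error(classify_myelination(data.frame(start = c(0, 1),
                                               end = c(2, 3),
                                               signal = "nav")),
               "non-overlapping")
  expect_error(classify_myelination(data.frame(start = 0, end = 0,
                                               signal = "nav")), "end")
})

test_that("fragments recovered from noisy tracings reproduce the truth class", {
  specs <- list(
    data.frame(signal = "nav", length = 40),
    data.frame(signal = c("nav", "mbp", "nav"), length = c(15, 20, 12)),
    data.frame(signal = c("nav", "mbp", "nav", "mbp"),
               length = c(3, 25, 2, 25)))
  for (i in seq_along(specs)) {
    tr <- simulate_axon_tracing(specs[[i]], intensity_levels =
                                  c(nav = 100, mbp = 5),
                                noise_sigma = 2, seed = 60 + i)
    fx <- extract_fragments(tr$profile, background_mean = 5,
                            background_sd = 2,
                            gaps_are_mbp = nrow(specs[[i]]) > 1)
    expect_equal(classify_myelination(fx)$class, tr$truth$class)
  }
})
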