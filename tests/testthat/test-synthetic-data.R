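test_that("motion model invariants are enforced", {
  expect_error(motion_model("bound", D = 1), "D = 0")
  expect_error(motion_model("confined"), "confinement_radius")
  expect_error(motion_model("confined", confinement_radius = -1),
               "confinement_radius")
  expect_error(motion_model("transport", velocity = 0), "velocity")
  expect_error(motion_model("brownian", D = NaN), "'D'")
  expect_error(motion_model("brownian", sigma_loc = -0.1), "sigma_loc")
})

test_that("bound molecules with zero noise never move", {
  tr <- simulate_trajectory(motion_model("bound"), 10, 0.1, origin = c(2, 3))
  expect_equal(tr$observed$x, rep(2, 10))
  expect_equal(tr$observed$y, rep(3, 10))
  expect_equal(tr$observed, tr$truth)
})

test_that("transport advances velocity*dt per frame along the path", {
  tr <- simulate_trajectory(motion_model("transport", velocity = 1),
                            11, 0.1, origin = c(0, 0))
  disp <- sqrt(diff(range(tr$truth$x))^2 + diff(range(tr$truth$y))^2)
  expect_equal(disp, 1.0)  # 10 steps of 0.1 um
  # follows a bent polyline by arclength, not by straight-line extrapolation
  bent <- rbind(c(0, 0), c(0.5, 0), c(0.5, 5))
  tr2 <- simulate_trajectory(motion_model("transport", velocity = 1),
                             11, 0.1, path = bent, start_arclength = 0)
  expect_equal(tr2$truth$x[11], 0.5)
  expect_equal(tr2$truth$y[11], 0.5)
})

test_that("brownian steps reproduce the closed-form MSD", {
  # per-step 2D MSD = 4 D dt; Monte-Carlo over 1e5 steps, 2% tolerance
  tr <- simulate_trajectory(motion_model("brownian", D = 0.5), 1e5, 0.1,
                            seed = 42)
  msd <- mean(diff(tr$truth$x)^2 + diff(tr$truth$y)^2)
  expect_lt(abs(msd - 4 * 0.5 * 0.1) / (4 * 0.5 * 0.1), 0.02)
})

test_that("observed MSD includes the localization-noise offset", {
  # MSD(dt) = 4 D dt + 4 sigma_loc^2 for observed (noisy) positions
  D <- 0.2; dt <- 0.1; sl <- 0.05
  tr <- simulate_trajectory(motion_model("brownian", D = D, sigma_loc = sl),
                            1e5, dt, seed = 43)
  msd <- mean(diff(tr$observed$x)^2 + diff(tr$observed$y)^2)
  expect_lt(abs(msd - (4 * D * dt + 4 * sl^2)) / (4 * D * dt + 4 * sl^2),
            0.02)
})

test_that("confined trajectories never leave the confinement disk", {
  for (seed in 1:5) {
    tr <- simulate_trajectory(
      motion_model("confined", D = 0.5, confinement_radius = 0.15),
      2000, 0.1, origin = c(1, -2), seed = seed)
    r <- sqrt((tr$truth$x - 1)^2 + (tr$truth$y + 2)^2)
    expect_lte(max(r), 0.15)
  }
})

test_that("identical seeds reproduce trajectories bit-identically", {
  a <- simulate_trajectory(motion_model("brownian", D = 1, sigma_loc = 0.02),
                           50, 0.1, seed = 7)
  b <- simulate_trajectory(motion_model("brownian", D = 1, sigma_loc = 0.02),
                           50, 0.1, seed = 7)
  expect_identical(a, b)
})

test_that("rendered frames conserve the photon budget before noise", {
  # noiseless render (excess factor 0 makes the camera deterministic at the
  # mean): total intensity = photons + background, within PSF truncation
  sc <- scene_config(n_molecules = 3, n_frames = 2,
                     state_mix = c(bound = 1, confined = 0, brownian = 0,
                                   transport = 0),
                     photons_per_frame = 1000, background_photons = 2,
                     bleach_prob = 0, blink_off_prob = 0,
                     em_gain_noise_factor = 0, seed = 5)
  out <- render_movie(sc)
  fr <- out$movie$frames[[1]]
  expected <- 3 * 1000 + 2 * length(fr)
  expect_lt(abs(sum(fr) - expected) / expected, 0.005)
})

test_that("zero-photon zero-background scenes render all-zero frames", {
  sc <- scene_config(n_molecules = 2, n_frames = 2, photons_per_frame = 0,
                     background_photons = 0, read_noise_sd = 0, seed = 1)
  out <- render_movie(sc)
  expect_true(all(vapply(out$movie$frames,
                         function(f) all(f == 0), logical(1))))
})

test_that("empty scenes yield a valid empty-truth movie, not an error", {
  sc <- scene_config(n_molecules = 0, n_frames = 3, background_photons = 5,
                     seed = 2)
  out <- render_movie(sc)
  expect_equal(nrow(out$truth), 0)
  expect_length(out$movie$frames, 3)
})

test_that("re-rendering with a fixed seed is bit-identical", {
  sc <- scene_config(n_molecules = 20, n_frames = 5, seed = 99)
  a <- render_movie(sc)
  b <- render_movie(sc)
  expect_identical(a$movie$frames, b$movie$frames)
  expect_identical(a$truth, b$truth)
})

test_that("negative photon means are rejected", {
  expect_error(scene_config(photons_per_frame = -1), "photons_per_frame")
  expect_error(scene_config(background_photons = -1), "background_photons")
  expect_error(scene_config(state_mix = c(bound = 0.5, confined = 0.2,
                                          brownian = 0.2, transport = 0.2)),
               "sum to 1")
})

test_that("two-channel spot scenes honor the colocalization construction", {
  # coloc_fraction 1 with zero registration noise: B coincides with A
  sc <- simulate_two_channel_spots(50, 1, registration_sigma = 0, seed = 1)
  expect_equal(sc$a$x, sc$b$x)
  expect_equal(sc$a$y, sc$b$y)
  # coloc_fraction 0: all A-B nearest distances exceed min_separation
  sc0 <- simulate_two_channel_spots(100, 0, field_size = 30,
                                    min_separation = 0.2, seed = 2)
  d <- nearest_neighbor_distances(sc0$a, sc0$b)
  expect_true(all(d > 0.2))
  expect_true(!any(sc0$truth$colocalized))
})

test_that("overcrowded spot fields are rejected with a density message", {
  expect_error(
    simulate_two_channel_spots(200, 0, field_size = 1, min_separation = 2,
                               seed = 1),
    "field too small")
})

test_that("axon tracings record the implied myelination class", {
  un <- simulate_axon_tracing(data.frame(signal = "nav", length = 50),
                              seed = 1)
  expect_equal(un$truth$class, "unmyelinated")
  pm <- simulate_axon_tracing(
    data.frame(signal = c("nav", "mbp", "nav"), length = c(15, 20, 15)),
    seed = 2)
  expect_equal(pm$truth$class, "partially_myelinated")
  my <- simulate_axon_tracing(
    data.frame(signal = c("nav", "mbp", "nav", "mbp"),
               length = c(2, 30, 2, 30)),
    seed = 3)
  expect_equal(my$truth$class, "myelinated")
  expect_error(simulate_axon_tracing(
    data.frame(signal = "nav", length = -5)), "lengths")
})
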