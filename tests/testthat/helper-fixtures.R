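# Fixture builders shared across test files. Rendering here goes through an
# independently written integrated-Gaussian expression (not add_psf) so
# fitting tests check recovery against a separately coded forward model.

# render one spot window: integrated symmetric Gaussian + constant
# background; x0/y0 in px with the center of pixel [1,1] at (0,0)
render_spot_window <- function(size, x0, y0, photons, background, sigma_px) {
  idx <- seq_len(size)
  fx <- pnorm((idx - 0.5 - x0) / sigma_px) - pnorm((idx - 1.5 - x0) / sigma_px)
  fy <- pnorm((idx - 0.5 - y0) / sigma_px) - pnorm((idx - 1.5 - y0) / sigma_px)
  photons * (fy %o% fx) + background
}

# total photons so that the peak-pixel SNR (peak / sqrt(peak + background),
# Poisson) equals a target, for a centered spot
photons_for_snr <- function(snr, background, sigma_px) {
  peak_frac <- (pnorm(0.5 / sigma_px) - pnorm(-0.5 / sigma_px))^2
  peak <- (snr^2 + snr * sqrt(snr^2 + 4 * background)) / 2
  peak / peak_frac
}

# brute-force RC oracle: explicit loops, independent of the implementation
rc_brute_force <- function(x, y) {
  cx <- mean(x); cy <- mean(y)
  best <- -Inf
  for (i in seq_along(x)) {
    d <- sqrt((x[i] - cx)^2 + (y[i] - cy)^2)
    if (d > best) best <- d
  }
  best
}

# brute-force nearest-neighbor oracle: all-pairs loops
nn_brute_force <- function(origin, target) {
  out <- numeric(nrow(origin))
  for (i in seq_len(nrow(origin))) {
    best <- Inf
    for (j in seq_len(nrow(target))) {
      d <- sqrt((origin$x[i] - target$x[j])^2 + (origin$y[i] - target$y[j])^2)
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# simulated localization table for a field of trafficking molecules with
# ground-truth ids: the bound/confined/brownian/transport state mixture of
# the scene generator's defaults, diffusion capped at D_max_sim
simulate_field_locs <- function(n_mol, field, n_frames, dt, D_max_sim = 0.5,
                                sigma_loc = 0.03, seed = 1) {
  set.seed(seed)
  mix <- c(bound = 0.4, confined = 0.2, brownian = 0.2, transport = 0.2)
  do.call(rbind, lapply(seq_len(n_mol), function(m) {
    st <- sample(names(mix), 1, prob = mix)
    mod <- switch(st,
      bound = motion_model("bound", sigma_loc = sigma_loc),
      confined = motion_model("confined", D = 0.3, confinement_radius = 0.1,
                              sigma_loc = sigma_loc),
      brownian = motion_model("brownian", D = runif(1, 0, D_max_sim),
                              sigma_loc = sigma_loc),
      transport = motion_model("transport", velocity = sample(c(-1, 1), 1),
                               sigma_loc = sigma_loc))
    tr <- simulate_trajectory(mod, n_frames, dt,
                              origin = runif(2, 0, field))
    cbind(tr$observed, mol = m)
  }))
}

# fraction of true consecutive localization pairs joined into one track
link_accuracy <- function(tracks, truth_locs) {
  m <- merge(tracks, truth_locs, by = c("frame", "x", "y"))
  m <- m[order(m$mol, m$frame), ]
  ok <- 0L; tot <- 0L
  for (mm in split(m, m$mol)) {
    tot <- tot + nrow(mm) - 1L
    ok <- ok + sum(diff(mm$track_id) == 0 & diff(mm$frame) == 1)
  }
  ok / tot
}
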