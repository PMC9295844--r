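#' Scene configuration for movie rendering
#'
#' Describes a simulated pulse-chase single-molecule acquisition: a sparse
#' set of labeled molecules moving on and around a neurite-like path, imaged
#' with a symmetric Gaussian PSF on an EMCCD-like camera. Defaults follow a
#' typical 100x / EMCCD single-molecule setup: 0.16 um pixels, 0.13 um PSF
#' sigma, 100 ms frames.
#'
#' @param path_geometry polyline (um), the neurite midline. Default: straight
#'   segment from (1, y_mid) to (nx*pixel - 1, y_mid).
#' @param n_molecules total number of labeled molecules.
#' @param state_mix named probabilities over states
#'   `c(bound=, confined=, brownian=, transport=)`; must sum to 1.
#' @param n_frames,dt number of frames and frame interval (s).
#' @param image_size c(rows, cols) in pixels.
#' @param pixel_size um per pixel.
#' @param psf_sigma PSF standard deviation (um).
#' @param photons_per_frame mean photons emitted per molecule per frame.
#' @param background_photons mean background photons per pixel per frame.
#' @param em_gain_noise_factor EMCCD excess-noise factor applied to shot
#'   noise (sqrt(2) is the standard high-gain approximation).
#' @param read_noise_sd Gaussian read noise s.d. (photons), default 0.
#' @param bleach_prob per-frame photobleaching probability (absorbing).
#' @param blink_off_prob,blink_on_prob per-frame transition probabilities of
#'   the 2-state (on/off) blinking Markov chain.
#' @param D,confinement_radius,velocity,sigma_loc motion parameters handed to
#'   [motion_model()] for the respective states. `sigma_loc` is only used
#'   when exporting ground-truth "observed" positions; rendered movies get
#'   their localization noise from photon statistics.
#' @param seed integer seed.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(path_geometry = NULL,
                         n_molecules = 20,
                         state_mix = c(bound = 0.4, confined = 0.2,
                                       brownian = 0.2, transport = 0.2),
                         n_frames = 50, dt = 0.1,
                         image_size = c(64, 64),
                         pixel_size = 0.16, psf_sigma = 0.13,
                         photons_per_frame = 500, background_photons = 10,
                         em_gain_noise_factor = sqrt(2), read_noise_sd = 0,
                         bleach_prob = 0.01,
                         blink_off_prob = 0.05, blink_on_prob = 0.5,
                         D = 0.3, confinement_radius = 0.1, velocity = 1,
                         sigma_loc = 0.03,
                         seed = 1L) {
  states <- c("bound", "confined", "brownian", "transport")
  if (is.null(names(state_mix)) || !setequal(names(state_mix), states)) {
    stop("'state_mix' must be named with: ", paste(states, collapse = ", "),
         call. = FALSE)
  }
  state_mix <- state_mix[states]
  if (abs(sum(state_mix) - 1) > 1e-9) {
    stop("'state_mix' must sum to 1", call. = FALSE)
  }
  if (any(state_mix < 0)) stop("'state_mix' must be nonnegative", call. = FALSE)
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (pixel_size <= 0) stop("'pixel_size' must be > 0", call. = FALSE)
  if (photons_per_frame < 0) stop("'photons_per_frame' must be >= 0", call. = FALSE)
  if (background_photons < 0) stop("'background_photons' must be >= 0", call. = FALSE)
  for (p in c(bleach_prob, blink_off_prob, blink_on_prob)) {
    if (!is.finite(p) || p < 0 || p > 1) {
      stop("bleach/blink probabilities must be in [0, 1]", call. = FALSE)
    }
  }
  if (is.null(path_geometry)) {
    ymid <- image_size[1L] / 2 * pixel_size
    path_geometry <- rbind(c(1, ymid),
                           c(image_size[2L] * pixel_size - 1, ymid))
  }
  structure(list(path_geometry = as_path(path_geometry),
                 n_molecules = as.integer(n_molecules),
                 state_mix = state_mix, n_frames = as.integer(n_frames),
                 dt = dt, image_size = as.integer(image_size),
                 pixel_size = pixel_size, psf_sigma = psf_sigma,
                 photons_per_frame = photons_per_frame,
                 background_photons = background_photons,
                 em_gain_noise_factor = em_gain_noise_factor,
                 read_noise_sd = read_noise_sd,
                 bleach_prob = bleach_prob,
                 blink_off_prob = blink_off_prob,
                 blink_on_prob = blink_on_prob,
                 D = D, confinement_radius = confinement_radius,
                 velocity = velocity, sigma_loc = sigma_loc,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# integrated symmetric Gaussian PSF: photon flux of one emitter into each
# pixel of an image, computed over a +-5 sigma bounding box (separable erf
# products). x_um/y_um are emitter positions; returns a full-size matrix.
add_psf <- function(frame, x_um, y_um, photons, pixel_size, psf_sigma) {
  nr <- nrow(frame); nc <- ncol(frame)
  s_px <- psf_sigma / pixel_size
  xc <- x_um / pixel_size  # px, pixel [1,1] center at 0
  yc <- y_um / pixel_size
  half <- ceiling(5 * s_px)
  c0 <- max(1L, floor(xc + 1) - half); c1 <- min(nc, ceiling(xc + 1) + half)
  r0 <- max(1L, floor(yc + 1) - half); r1 <- min(nr, ceiling(yc + 1) + half)
  if (c0 > c1 || r0 > r1) return(frame)
  cols <- c0:c1; rows <- r0:r1
  # pixel col c spans x in [c - 1.5, c - 0.5]
  fx <- stats::pnorm(cols - 0.5 - xc, sd = s_px) -
        stats::pnorm(cols - 1.5 - xc, sd = s_px)
  fy <- stats::pnorm(rows - 0.5 - yc, sd = s_px) -
        stats::pnorm(rows - 1.5 - yc, sd = s_px)
  frame[rows, cols] <- frame[rows, cols] + photons * (fy %o% fx)
  frame
}

# EMCCD-like camera: Poisson shot noise inflated by the excess-noise factor,
# plus additive Gaussian read noise. Mean is preserved; variance is
# F^2 * mu + read_noise_sd^2.
apply_camera_noise <- function(mu, excess_factor, read_noise_sd) {
  shot <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
  out <- mu + excess_factor * (shot - mu)
  if (read_noise_sd > 0) {
    out <- out + matrix(stats::rnorm(length(mu), sd = read_noise_sd),
                        nrow(mu), ncol(mu))
  }
  out
}

#' Render a simulated single-molecule movie
#'
#' Simulates molecule motion (per [simulate_trajectory()] mechanics), on/off
#' blinking (2-state Markov chain), absorbing photobleaching, and image
#' formation: each frame is the sum over emitting molecules of an integrated
#' symmetric 2D Gaussian PSF scaled to the molecule's photon budget, plus
#' uniform background, passed through an EMCCD-like noise model (Poisson shot
#' noise with a multiplicative excess-noise factor, optional Gaussian read
#' noise).
#'
#' @param scene a [scene_config()].
#' @return a list with `movie` (class `movie`: list of frame matrices plus
#'   `pixel_size`, `dt` metadata) and `truth` (data.frame with one row per
#'   molecule-frame: `track_id`, `frame`, `x`, `y` true position um, `state`,
#'   `emitting`).
#' @examples
#' out <- render_movie(scene_config(n_molecules = 5, n_frames = 10, seed = 2))
#' dim(out$movie$frames[[1]])
#' @export
render_movie <- function(scene) {
  stopifnot(inherits(scene, "scene_config"))
  set.seed(scene$seed)
  nr <- scene$image_size[1L]; nc <- scene$image_size[2L]
  n_frames <- scene$n_frames
  total_len <- path_arclength(scene$path_geometry)
  total_len <- total_len[length(total_len)]

  # assign states and build per-molecule trajectories
  n <- scene$n_molecules
  truth_rows <- vector("list", n)
  states <- if (n > 0) {
    sample(names(scene$state_mix), n, replace = TRUE, prob = scene$state_mix)
  } else character(0)

  frames <- lapply(seq_len(n_frames), function(i) matrix(0, nr, nc))

  for (m in seq_len(n)) {
    st <- states[m]
    s0 <- stats::runif(1, 0, total_len)
    origin <- drop(path_point_at(scene$path_geometry, s0))
    mod <- switch(st,
      bound = motion_model("bound"),
      confined = motion_model("confined", D = scene$D,
                              confinement_radius = scene$confinement_radius),
      brownian = motion_model("brownian", D = scene$D),
      transport = motion_model("transport", D = 0,
                               velocity = scene$velocity * sample(c(-1, 1), 1)))
    tr <- simulate_trajectory(mod, max(n_frames, 2L), scene$dt,
                              origin = origin,
                              path = if (st == "transport") scene$path_geometry,
                              start_arclength = s0)
    tr$truth <- tr$truth[seq_len(n_frames), , drop = FALSE]
    # photophysics: blinking 2-state chain (start on), absorbing bleaching
    on <- logical(n_frames)
    cur_on <- TRUE; bleached <- FALSE
    for (f in seq_len(n_frames)) {
      if (!bleached && stats::runif(1) < scene$bleach_prob) bleached <- TRUE
      if (bleached) { on[f] <- FALSE; next }
      on[f] <- cur_on
      cur_on <- if (cur_on) stats::runif(1) >= scene$blink_off_prob
                else stats::runif(1) < scene$blink_on_prob
    }
    for (f in which(on)) {
      frames[[f]] <- add_psf(frames[[f]], tr$truth$x[f], tr$truth$y[f],
                             scene$photons_per_frame,
                             scene$pixel_size, scene$psf_sigma)
    }
    truth_rows[[m]] <- data.frame(track_id = m, frame = tr$truth$frame,
                                  x = tr$truth$x, y = tr$truth$y,
                                  state = st, emitting = on)
  }

  frames <- lapply(frames, function(fr) {
    apply_camera_noise(fr + scene$background_photons,
                       scene$em_gain_noise_factor, scene$read_noise_sd)
  })

  truth <- if (n > 0) do.call(rbind, truth_rows) else {
    data.frame(track_id = integer(0), frame = integer(0),
               x = numeric(0), y = numeric(0),
               state = character(0), emitting = logical(0))
  }
  movie <- structure(list(frames = frames, pixel_size = scene$pixel_size,
                          dt = scene$dt, scene = scene),
                     class = "movie")
  list(movie = movie, truth = truth)
}

#' @export
print.movie <- function(x, ...) {
  cat(sprintf("<movie> %d frames of %dx%d px, pixel %g um, dt %g s\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$pixel_size, x$dt))
  invisible(x)
}
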