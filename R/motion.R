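#' Motion models for single-molecule trajectory simulation
#'
#' A molecule undergoing membrane trafficking is in one of four dynamic
#' states: stably bound (immobile), locally exploring (confined diffusion
#' within a small zone), freely diffusing (2D Brownian motion), or actively
#' transported (motor-driven, constant speed along the neurite). These states
#' leave distinct signatures in the radius of confinement: binding and local
#' exploration give small RCs, diffusion and transport give large RCs.
#'
#' @param kind one of `"bound"`, `"confined"`, `"brownian"`, `"transport"`.
#' @param D diffusion coefficient (um^2/s, >= 0). Must be 0 for `"bound"`.
#' @param confinement_radius radius of the confinement zone (um); required
#'   and > 0 for `"confined"`.
#' @param velocity signed speed along the path (um/s); required and nonzero
#'   for `"transport"`.
#' @param sigma_loc localization noise standard deviation per axis (um, >= 0),
#'   added to the true position of every observed localization.
#' @return an object of class `motion_model`.
#' @examples
#' motion_model("brownian", D = 0.5)
#' motion_model("transport", velocity = 1, sigma_loc = 0.03)
#' @export
motion_model <- function(kind = c("bound", "confined", "brownian", "transport"),
                         D = 0, confinement_radius = NULL, velocity = NULL,
                         sigma_loc = 0) {
  kind <- match.arg(kind)
  for (nm in c("D", "sigma_loc")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    }
  }
  if (D < 0) stop("'D' must be >= 0", call. = FALSE)
  if (sigma_loc < 0) stop("'sigma_loc' must be >= 0", call. = FALSE)
  if (kind == "bound" && (D != 0 || !is.null(velocity) && any(velocity != 0))) {
    stop("a 'bound' model must have D = 0 and no velocity", call. = FALSE)
  }
  if (kind == "confined") {
    if (is.null(confinement_radius) || !is.finite(confinement_radius) ||
        confinement_radius <= 0) {
      stop("'confinement_radius' must be > 0 for a confined model",
           call. = FALSE)
    }
  }
  if (kind == "transport") {
    if (is.null(velocity) || !is.finite(velocity) || velocity == 0) {
      stop("'velocity' must be nonzero and finite for a transport model",
           call. = FALSE)
    }
  }
  structure(list(kind = kind, D = D,
                 confinement_radius = confinement_radius,
                 velocity = velocity, sigma_loc = sigma_loc),
            class = "motion_model")
}

#' @export
print.motion_model <- function(x, ...) {
  cat("<motion_model>", x$kind,
      sprintf("D=%g um^2/s", x$D),
      if (!is.null(x$confinement_radius))
        sprintf("Rconf=%g um", x$confinement_radius),
      if (!is.null(x$velocity)) sprintf("v=%g um/s", x$velocity),
      sprintf("sigma_loc=%g um", x$sigma_loc), "\n")
  invisible(x)
}

# reflect radial distances into [0, R] (disk with reflecting boundary)
reflect_radius <- function(r, R) {
  # fold r into [0, 2R] then mirror the upper half
  r <- r %% (2 * R)
  ifelse(r > R, 2 * R - r, r)
}

#' Simulate one single-molecule trajectory
#'
#' Generates the true positions of one molecule over `n_frames` frames at
#' interval `dt`, plus the observed positions after adding independent
#' Gaussian localization noise (`sigma_loc` per axis).
#'
#' State mechanics: `bound` stays at the origin; `brownian` takes i.i.d.
#' Gaussian steps with per-axis variance `2 * D * dt` (so the 2D mean squared
#' step is `4 D dt`); `confined` takes Brownian steps inside a disk of radius
#' `confinement_radius` centered on the origin with a reflecting boundary;
#' `transport` advances `velocity * dt` of arclength per frame along `path`
#' (optionally with Brownian jitter if `D > 0`).
#'
#' @param model a [motion_model()].
#' @param n_frames number of frames (>= 2).
#' @param dt frame interval (s, > 0).
#' @param origin 2-vector, starting position (um). For `transport` the
#'   molecule starts at arclength `start_arclength` on `path` and `origin`
#'   is ignored.
#' @param path polyline (um) for transport; default a long straight line
#'   along +x through the origin.
#' @param start_arclength starting arclength on `path` (um) for transport.
#' @param seed optional integer seed for reproducibility.
#' @return a list with elements `observed` (data.frame `frame`, `x`, `y`;
#'   frame 0-based, positions um), `truth` (same shape, noise-free true
#'   positions), and `state` (the model kind).
#' @examples
#' tr <- simulate_trajectory(motion_model("brownian", D = 0.5),
#'                           n_frames = 20, dt = 0.1, seed = 1)
#' head(tr$observed)
#' @export
simulate_trajectory <- function(model, n_frames, dt, origin = c(0, 0),
                                path = NULL, start_arclength = 0,
                                seed = NULL) {
  stopifnot(inherits(model, "motion_model"))
  if (!is.numeric(n_frames) || n_frames < 2) {
    stop("'n_frames' must be >= 2", call. = FALSE)
  }
  if (!is.numeric(dt) || !is.finite(dt) || dt <= 0) {
    stop("'dt' must be a finite positive number", call. = FALSE)
  }
  stop_if_not_finite(origin, "origin")
  n_frames <- as.integer(n_frames)
  if (!is.null(seed)) set.seed(seed)

  step_sd <- sqrt(2 * model$D * dt)
  pos <- matrix(0, n_frames, 2L)

  if (model$kind == "bound") {
    pos[, 1L] <- origin[1L]
    pos[, 2L] <- origin[2L]
  } else if (model$kind == "brownian") {
    dx <- matrix(stats::rnorm(2L * (n_frames - 1L), sd = step_sd),
                 n_frames - 1L, 2L)
    inc <- apply(dx, 2L, cumsum)
    if (is.null(dim(inc))) inc <- matrix(inc, 1L)  # n_frames == 2
    pos <- rbind(c(0, 0), inc)
    pos[, 1L] <- pos[, 1L] + origin[1L]
    pos[, 2L] <- pos[, 2L] + origin[2L]
  } else if (model$kind == "confined") {
    R <- model$confinement_radius
    cur <- c(0, 0)  # relative to confinement center
    pos[1L, ] <- cur
    for (i in seq_len(n_frames - 1L)) {
      prop <- cur + stats::rnorm(2L, sd = step_sd)
      r <- sqrt(sum(prop^2))
      if (r > R) {
        prop <- prop * (reflect_radius(r, R) / r)
      }
      cur <- prop
      pos[i + 1L, ] <- cur
    }
    pos <- sweep(pos, 2L, -as.numeric(origin))
  } else {  # transport
    if (is.null(path)) {
      reach <- abs(model$velocity) * dt * n_frames + 1
      path <- rbind(origin - c(reach, 0), origin + c(reach, 0))
      start_arclength <- reach
    }
    s <- start_arclength + model$velocity * dt * (seq_len(n_frames) - 1L)
    pos <- path_point_at(path, s)
    if (model$D > 0) {
      jit <- matrix(stats::rnorm(2L * (n_frames - 1L), sd = step_sd),
                    n_frames - 1L, 2L)
      pos[-1L, ] <- pos[-1L, , drop = FALSE] + apply(jit, 2L, cumsum)
    }
  }

  obs <- pos
  if (model$sigma_loc > 0) {
    obs <- obs + matrix(stats::rnorm(2L * n_frames, sd = model$sigma_loc),
                        n_frames, 2L)
  }
  frames <- seq_len(n_frames) - 1L
  list(observed = data.frame(frame = frames, x = obs[, 1L], y = obs[, 2L]),
       truth = data.frame(frame = frames, x = pos[, 1L], y = pos[, 2L]),
       state = model$kind)
}
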