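#' Simulate a two-channel spot field with a known colocalized fraction
#'
#' Generates channel-A spot centroids uniformly in a square field. A chosen
#' fraction of them receive a channel-B partner displaced by isotropic
#' Gaussian registration noise (per-axis s.d. `registration_sigma`); the
#' remaining channel-B spots are placed uniformly but farther than
#' `min_separation` from every A spot, so they cannot colocalize by chance.
#' This is the ground-truth scene for testing object-based colocalization at
#' a distance cutoff (e.g., the 50 nm vesicle-colocalization cutoff).
#'
#' @param n_spots number of spots per channel (>= 1).
#' @param coloc_fraction true colocalized fraction in `[0, 1]`;
#'   `round(coloc_fraction * n_spots)` A spots get a partner.
#' @param field_size side of the square field (um).
#' @param registration_sigma per-axis Gaussian displacement of the partner
#'   spot (um), emulating channel registration error.
#' @param min_separation minimum distance (um) of non-partnered B spots from
#'   every A spot (> 0).
#' @param seed integer seed.
#' @return list with `a`, `b` (data.frames `x`, `y` in um, class
#'   `spot_set`) and `truth` (data.frame `spot` index into `a`,
#'   `colocalized` logical).
#' @examples
#' sc <- simulate_two_channel_spots(100, 0.3, field_size = 20, seed = 1)
#' mean(sc$truth$colocalized)
#' @export
simulate_two_channel_spots <- function(n_spots, coloc_fraction,
                                       field_size = 20,
                                       registration_sigma = 0.02,
                                       min_separation = 0.2,
                                       seed = NULL) {
  if (n_spots < 1) stop("'n_spots' must be >= 1", call. = FALSE)
  if (coloc_fraction < 0 || coloc_fraction > 1) {
    stop("'coloc_fraction' must be in [0, 1]", call. = FALSE)
  }
  if (min_separation <= 0) stop("'min_separation' must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_spots <- as.integer(n_spots)

  ax <- stats::runif(n_spots, 0, field_size)
  ay <- stats::runif(n_spots, 0, field_size)
  n_coloc <- round(coloc_fraction * n_spots)

  bx <- numeric(n_spots); by <- numeric(n_spots)
  if (n_coloc > 0) {
    bx[seq_len(n_coloc)] <- ax[seq_len(n_coloc)] +
      stats::rnorm(n_coloc, sd = registration_sigma)
    by[seq_len(n_coloc)] <- ay[seq_len(n_coloc)] +
      stats::rnorm(n_coloc, sd = registration_sigma)
  }
  n_free <- n_spots - n_coloc
  if (n_free > 0) {
    placed <- 0L
    max_tries <- 2000L * n_free
    tries <- 0L
    while (placed < n_free) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop(sprintf(paste0("field too small: could not place %d background ",
                            "spots at min_separation %g um in a %g um field ",
                            "(spot density too high)"),
                     n_free, min_separation, field_size), call. = FALSE)
      }
      px <- stats::runif(1, 0, field_size)
      py <- stats::runif(1, 0, field_size)
      if (min((px - ax)^2 + (py - ay)^2) > min_separation^2) {
        placed <- placed + 1L
        bx[n_coloc + placed] <- px
        by[n_coloc + placed] <- py
      }
    }
  }
  a <- structure(data.frame(x = ax, y = ay),
                 class = c("spot_set", "data.frame"), channel = "A")
  b <- structure(data.frame(x = bx, y = by),
                 class = c("spot_set", "data.frame"), channel = "B")
  truth <- data.frame(spot = seq_len(n_spots),
                      colocalized = seq_len(n_spots) <= n_coloc)
  list(a = a, b = b, truth = truth)
}
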