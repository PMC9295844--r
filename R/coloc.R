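#' Segment fluorescent spots (vesicles) in one channel
#'
#' Standard deterministic pipeline for computer-aided vesicle segmentation:
#' Gaussian smoothing, white top-hat background subtraction, Otsu (or fixed)
#' thresholding, connected-component labeling, and a minimum-area filter.
#' Centroids are intensity-weighted and reported in um.
#'
#' @param image numeric matrix.
#' @param pixel_size um per pixel.
#' @param min_area minimum spot area (um^2).
#' @param smooth_sigma Gaussian smoothing sigma (px); 0 disables.
#' @param tophat_radius structuring-disc radius (px) for background
#'   subtraction; 0 disables.
#' @param threshold `"otsu"` or a numeric absolute threshold on the
#'   processed image.
#' @param channel channel label attached to the result.
#' @return data.frame (class `spot_set`): `x`, `y` (um), `area` (um^2),
#'   `intensity` (summed pixel values over the spot).
#' @export
segment_spots <- function(image, pixel_size, min_area = 0.02,
                          smooth_sigma = 1, tophat_radius = 7,
                          threshold = "otsu", channel = "A") {
  if (!is.matrix(image) || !all(is.finite(image))) {
    stop("'image' must be a finite numeric matrix", call. = FALSE)
  }
  empty <- structure(data.frame(x = numeric(0), y = numeric(0),
                                area = numeric(0), intensity = numeric(0)),
                     class = c("spot_set", "data.frame"), channel = channel)
  if (max(image) == min(image)) {
    warning("constant image: no spots segmented")
    return(empty)
  }
  # EBImage images index x (columns of our matrices) first
  img <- EBImage::Image(t(image))
  work <- img
  if (smooth_sigma > 0) work <- EBImage::gblur(work, sigma = smooth_sigma)
  if (tophat_radius > 0) {
    kern <- EBImage::makeBrush(2L * as.integer(tophat_radius) + 1L,
                               shape = "disc")
    work <- EBImage::whiteTopHat(work, kern)
  }
  if (identical(threshold, "otsu")) {
    rng <- range(work)
    if (diff(rng) == 0) {
      warning("flat image after preprocessing: no spots segmented")
      return(empty)
    }
    norm <- (work - rng[1L]) / diff(rng)
    thr <- EBImage::otsu(norm) * diff(rng) + rng[1L]
  } else {
    thr <- threshold
  }
  mask <- work > thr
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) return(empty)
  # centroids are weighted by the processed (smoothed, background-
  # subtracted) intensity so a noise floor does not pull them off-center
  mom <- EBImage::computeFeatures.moment(lab, ref = work)
  shp <- EBImage::computeFeatures.shape(lab)
  area_um2 <- shp[, "s.area"] * pixel_size^2
  keep <- area_um2 >= min_area
  if (!any(keep)) return(empty)
  # intensity-weighted centroids: EBImage is 1-based, our origin pixel is 0
  inten <- vapply(which(keep), function(i) sum(image[t(lab) == i]),
                  numeric(1))
  structure(data.frame(x = (mom[keep, "m.cx"] - 1) * pixel_size,
                       y = (mom[keep, "m.cy"] - 1) * pixel_size,
                       area = area_um2[keep], intensity = inten),
            class = c("spot_set", "data.frame"), channel = channel)
}

#' Nearest-neighbor distances from an origin channel to a target channel
#'
#' For each origin spot, the Euclidean distance to the nearest target spot.
#' The measure is asymmetric: the origin channel matters (e.g., Nav1.2
#' vesicles as origin against Nav1.6 vesicles as target).
#'
#' @param origin,target `spot_set`s (or data.frames with `x`, `y` in um).
#' @return numeric vector of distances (um), one per origin spot, in origin
#'   order.
#' @export
nearest_neighbor_distances <- function(origin, target) {
  if (nrow(origin) == 0L) stop("empty origin spot set", call. = FALSE)
  if (nrow(target) == 0L) stop("empty target spot set", call. = FALSE)
  # row-wise minimum over the full distance matrix, chunked to bound memory
  out <- numeric(nrow(origin))
  chunk <- max(1L, as.integer(1e7 / nrow(target)))
  for (start in seq(1L, nrow(origin), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(origin))
    d2 <- outer(origin$x[idx], target$x, "-")^2 +
          outer(origin$y[idx], target$y, "-")^2
    out[idx] <- sqrt(apply(d2, 1L, min))
  }
  out
}

#' Colocalized fraction at a distance cutoff
#'
#' Fraction of origin spots whose nearest-neighbor distance is at or below
#' the cutoff (closed boundary). The default 0.05 um (50 nm) is the standard
#' object-based vesicle-colocalization cutoff.
#'
#' @param distances nearest-neighbor distances (um), from
#'   [nearest_neighbor_distances()].
#' @param cutoff distance cutoff (um, > 0), default 0.05.
#' @return list (class `coloc_result`): `fraction`, `cutoff`, `n`,
#'   `distances`.
#' @export
colocalization_fraction <- function(distances, cutoff = 0.05) {
  if (length(distances) == 0L) stop("empty distance vector", call. = FALSE)
  if (any(distances < 0)) {
    stop("negative distances: upstream computation is broken", call. = FALSE)
  }
  if (cutoff <= 0) stop("'cutoff' must be > 0", call. = FALSE)
  structure(list(fraction = mean(distances <= cutoff), cutoff = cutoff,
                 n = length(distances), distances = distances),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %.1f%% of %d origin spots within %g um\n",
              100 * x$fraction, x$n, x$cutoff))
  invisible(x)
}
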