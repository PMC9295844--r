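# bilinear interpolation of an image at sub-pixel positions; x/y in px with
# the center of pixel [1,1] at (0,0); points outside the image return NA
interp_bilinear <- function(image, x_px, y_px) {
  nr <- nrow(image); nc <- ncol(image)
  cx <- x_px + 1; cy <- y_px + 1  # continuous 1-based index
  c0 <- floor(cx); r0 <- floor(cy)
  fx <- cx - c0; fy <- cy - r0
  ok <- cx >= 1 & cx <= nc & cy >= 1 & cy <= nr
  c0 <- pmin(pmax(c0, 1L), nc); r0 <- pmin(pmax(r0, 1L), nr)
  c1 <- pmin(c0 + 1L, nc); r1 <- pmin(r0 + 1L, nr)
  v <- (1 - fx) * (1 - fy) * image[cbind(r0, c0)] +
       fx * (1 - fy) * image[cbind(r0, c1)] +
       (1 - fx) * fy * image[cbind(r1, c0)] +
       fx * fy * image[cbind(r1, c1)]
  v[!ok] <- NA_real_
  v
}

#' Extract an intensity profile along a neurite path
#'
#' Samples the image at regular arclength steps along a user-drawn polyline
#' (e.g., the AIS midline). At each step the intensity is the mean over a
#' short segment perpendicular to the path, of the given width, using
#' bilinear interpolation. Background is \emph{not} subtracted here; see
#' [subtract_background()].
#'
#' @param image numeric matrix.
#' @param path polyline (um), must lie inside the image.
#' @param pixel_size um per pixel.
#' @param width averaging width perpendicular to the path (um), default 0.5.
#' @param step arclength sampling step (um), default 0.1.
#' @return data.frame (class `profile_curve`): `arclength` (um, starting at
#'   0), `intensity`.
#' @export
extract_profile <- function(image, path, pixel_size, width = 0.5,
                            step = 0.1) {
  p <- as_path(path)
  vx <- p[, 1L] / pixel_size; vy <- p[, 2L] / pixel_size
  bad <- which(vx < 0 | vx > ncol(image) - 1 | vy < 0 | vy > nrow(image) - 1)
  if (length(bad) > 0L) {
    stop(sprintf("path vertex %d at (%.3g, %.3g) um lies outside the image",
                 bad[1L], p[bad[1L], 1L], p[bad[1L], 2L]), call. = FALSE)
  }
  if (width < pixel_size) width <- pixel_size
  total <- path_arclength(p); total <- total[length(total)]
  s <- seq(0, total, by = step)
  centers <- path_point_at(p, s)
  tangents <- path_tangent_at(p, s)
  normals <- cbind(-tangents[, 2L], tangents[, 1L])
  n_off <- max(1L, ceiling(width / pixel_size))
  offsets <- seq(-width / 2, width / 2, length.out = n_off + 1L)
  vals <- vapply(seq_along(s), function(i) {
    px <- (centers[i, 1L] + offsets * normals[i, 1L]) / pixel_size
    py <- (centers[i, 2L] + offsets * normals[i, 2L]) / pixel_size
    mean(interp_bilinear(image, px, py), na.rm = TRUE)
  }, numeric(1))
  structure(data.frame(arclength = s, intensity = vals),
            class = c("profile_curve", "data.frame"),
            step = step, width = width)
}

#' Subtract a mean background intensity
#'
#' Subtracts the mean background (measured from a blank region) from
#' intensity values before any further analysis. Negative results are kept
#' (and counted) unless `clip = TRUE`.
#'
#' @param values numeric vector or a `profile_curve`.
#' @param background_mean mean background intensity (finite scalar).
#' @param clip clip negative results to 0 (default FALSE).
#' @return same shape as `values`, background-subtracted; attribute
#'   `n_negative` counts negative results.
#' @export
subtract_background <- function(values, background_mean, clip = FALSE) {
  if (!is.finite(background_mean)) {
    stop("'background_mean' must be finite", call. = FALSE)
  }
  if (inherits(values, "profile_curve")) {
    values$intensity <- subtract_background(values$intensity,
                                            background_mean, clip)
    return(values)
  }
  out <- values - background_mean
  n_neg <- sum(out < 0, na.rm = TRUE)
  if (clip) out[out < 0] <- 0
  attr(out, "n_negative") <- n_neg
  out
}

#' Resample a profile curve onto a new arclength grid
#'
#' Linear interpolation onto `grid`; needed before [intensity_ratio()] when
#' two profiles were sampled on different grids.
#'
#' @param profile a `profile_curve`.
#' @param grid new arclength samples (um), within the profile's range.
#' @return a `profile_curve` on `grid`.
#' @export
resample_profile <- function(profile, grid) {
  out <- stats::approx(profile$arclength, profile$intensity, xout = grid,
                       rule = 1)
  structure(data.frame(arclength = grid, intensity = out$y),
            class = c("profile_curve", "data.frame"),
            step = if (length(grid) > 1L) grid[2L] - grid[1L] else NA_real_)
}

#' Pointwise intensity ratio of two profiles
#'
#' Ratio curve a/b on a shared arclength grid (e.g., the Nav1.2/Nav1.6
#' intensity ratio along the AIS). Positions where the denominator is at or
#' below `epsilon` are masked to NA and counted.
#'
#' @param profile_a,profile_b `profile_curve`s on identical arclength grids
#'   (see [resample_profile()]).
#' @param epsilon denominator mask level (default 1e-9).
#' @return data.frame `arclength`, `ratio`; attribute `n_masked`.
#' @export
intensity_ratio <- function(profile_a, profile_b, epsilon = 1e-9) {
  if (nrow(profile_a) != nrow(profile_b) ||
      any(abs(profile_a$arclength - profile_b$arclength) > 1e-9)) {
    stop("profiles are on different arclength grids; resample first",
         call. = FALSE)
  }
  masked <- !is.na(profile_b$intensity) & profile_b$intensity <= epsilon
  ratio <- profile_a$intensity / profile_b$intensity
  ratio[masked] <- NA_real_
  out <- data.frame(arclength = profile_a$arclength, ratio = ratio)
  attr(out, "n_masked") <- sum(masked)
  out
}

#' Above-background edge intensities from box ROIs
#'
#' Measures mean intensity in small boxes placed along a cell edge (e.g.,
#' the soma rim or dendrite membrane), subtracts the mean of a background
#' box drawn over a blank area, and summarizes the per-box values with the
#' median and percentile spread used in box plots (5th/25th/75th/95th).
#'
#' @param image numeric matrix.
#' @param edge_boxes list of boxes `c(x0, y0, x1, y1)` in um.
#' @param background_box a single box `c(x0, y0, x1, y1)` in um.
#' @param pixel_size um per pixel.
#' @return list: `values` (per-box background-subtracted means), `summary`
#'   (named: median, q25, q75, p5, p95), `background_mean`.
#' @export
measure_edge_intensity <- function(image, edge_boxes, background_box,
                                   pixel_size) {
  if (length(edge_boxes) == 0L) stop("empty edge box list", call. = FALSE)
  box_mean <- function(b) {
    c0 <- max(1L, floor(b[1L] / pixel_size) + 1L)
    c1 <- min(ncol(image), ceiling(b[3L] / pixel_size) + 1L)
    r0 <- max(1L, floor(b[2L] / pixel_size) + 1L)
    r1 <- min(nrow(image), ceiling(b[4L] / pixel_size) + 1L)
    if (c0 > c1 || r0 > r1) stop("box outside image", call. = FALSE)
    mean(image[r0:r1, c0:c1])
  }
  bg <- box_mean(background_box)
  vals <- vapply(edge_boxes, box_mean, numeric(1)) - bg
  qs <- stats::quantile(vals, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  list(values = vals,
       summary = c(p5 = qs[1L], q25 = qs[2L], median = qs[3L],
                   q75 = qs[4L], p95 = qs[5L]),
       background_mean = bg)
}

#' Extract labeled fragments from a noisy axon tracing
#'
#' Reproducible surrogate for the visual fragment calls used on stained
#' axons: samples above `background_mean + k * background_sd` are labeled
#' runs; labeled runs separated by less than `merge_gap` of unlabeled signal
#' are merged. Gaps between labeled fragments are reported as `"mbp"`
#' intervals when `gaps_are_mbp = TRUE` (an MBP costain confirms myelin in
#' the unlabeled stretches, as in the simulated tracings).
#'
#' @param profile a `profile_curve` (channel signal along the axon).
#' @param background_mean,background_sd background statistics.
#' @param k threshold multiplier (default 3).
#' @param merge_gap merge labeled runs separated by less than this (um),
#'   default 1.
#' @param min_fragment labeled runs shorter than this (um) are treated as
#'   noise spikes and dropped (default 0.5).
#' @param gaps_are_mbp treat unlabeled gaps as MBP-positive intervals.
#' @return data.frame `start`, `end` (um), `signal` (`"nav"`/`"mbp"`).
#' @export
extract_fragments <- function(profile, background_mean, background_sd,
                              k = 3, merge_gap = 1, min_fragment = 0.5,
                              gaps_are_mbp = TRUE) {
  thr <- background_mean + k * background_sd
  lab <- profile$intensity > thr
  s <- profile$arclength
  if (!any(lab)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      signal = character(0)))
  }
  r <- rle(lab)
  ends_i <- cumsum(r$lengths)
  starts_i <- c(1L, utils::head(ends_i, -1L) + 1L)
  runs <- data.frame(start = s[starts_i], end = s[ends_i], lab = r$values)
  # merge labeled runs separated by short unlabeled gaps
  nav <- runs[runs$lab, c("start", "end"), drop = FALSE]
  merged <- nav[1L, , drop = FALSE]
  if (nrow(nav) > 1L) {
    for (i in 2L:nrow(nav)) {
      if (nav$start[i] - merged$end[nrow(merged)] < merge_gap) {
        merged$end[nrow(merged)] <- nav$end[i]
      } else {
        merged <- rbind(merged, nav[i, ])
      }
    }
  }
  merged <- merged[merged$end - merged$start >= min_fragment, , drop = FALSE]
  if (nrow(merged) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      signal = character(0)))
  }
  out <- data.frame(start = merged$start, end = merged$end, signal = "nav")
  if (gaps_are_mbp && nrow(merged) > 0L) {
    gaps <- data.frame(start = utils::head(merged$end, -1L),
                       end = merged$start[-1L])
    lead <- if (merged$start[1L] > s[1L])
      data.frame(start = s[1L], end = merged$start[1L]) else NULL
    trail <- if (merged$end[nrow(merged)] < s[length(s)])
      data.frame(start = merged$end[nrow(merged)], end = s[length(s)]) else NULL
    gaps <- rbind(lead, gaps, trail)
    if (!is.null(gaps) && nrow(gaps) > 0L) {
      gaps$signal <- "mbp"
      out <- rbind(out, gaps)
    }
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify axon myelination status from labeled fragments
#'
#' Applies the standard fragment-length rules to an ordered set of
#' non-overlapping intervals labeled `"nav"` (channel signal) or `"mbp"`
#' (myelin): no MBP along the whole axon means \emph{unmyelinated}; channel
#' fragments longer than 10 um interspaced with MBP mean \emph{partially
#' myelinated}; channel signal confined to node-like fragments shorter than
#' 10 um interspaced with MBP means \emph{myelinated}. A fragment of exactly
#' 10 um falls between the two published rules; it is assigned to
#' partially_myelinated (boundary closed upward) and flagged.
#'
#' @param fragments data.frame with `start`, `end` (um) and `signal`
#'   (`"nav"`/`"mbp"`), sorted and non-overlapping.
#' @return list (class `myelination_call`): `class` (one of `unmyelinated`,
#'   `partially_myelinated`, `myelinated`), `fragments`, `boundary_case`,
#'   `trace` (human-readable decision trace).
#' @examples
#' fr <- data.frame(start = c(0, 15, 35), end = c(15, 35, 47),
#'                  signal = c("nav", "mbp", "nav"))
#' classify_myelination(fr)$class  # partially_myelinated
#' @export
classify_myelination <- function(fragments) {
  fragments <- as.data.frame(fragments)
  if (!all(c("start", "end", "signal") %in% names(fragments))) {
    stop("'fragments' needs columns start, end, signal", call. = FALSE)
  }
  if (is.unsorted(fragments$start)) {
    stop("fragments must be sorted by start", call. = FALSE)
  }
  if (any(fragments$end <= fragments$start)) {
    stop("fragments must have end > start", call. = FALSE)
  }
  if (nrow(fragments) > 1L &&
      any(fragments$start[-1L] < fragments$end[-nrow(fragments)] - 1e-9)) {
    stop("fragments must be non-overlapping", call. = FALSE)
  }
  nav_len <- with(fragments, end - start)[fragments$signal == "nav"]
  has_mbp <- any(fragments$signal == "mbp")
  boundary <- FALSE
  if (!has_mbp) {
    cls <- "unmyelinated"
    trace <- "no MBP signal along the whole axon -> unmyelinated"
  } else if (any(nav_len > 10)) {
    cls <- "partially_myelinated"
    trace <- sprintf(paste0("MBP present; longest channel fragment %.2f um ",
                            "> 10 um -> partially_myelinated"), max(nav_len))
  } else if (any(abs(nav_len - 10) < 1e-9)) {
    cls <- "partially_myelinated"
    boundary <- TRUE
    trace <- paste("MBP present; channel fragment of exactly 10 um sits",
                   "between the >10 um and <10 um rules; assigned to",
                   "partially_myelinated (boundary closed upward), flagged")
  } else {
    cls <- "myelinated"
    trace <- sprintf(paste0("MBP present; all channel fragments < 10 um ",
                            "(max %.2f um), node-like -> myelinated"),
                     if (length(nav_len)) max(nav_len) else 0)
  }
  structure(list(class = cls, fragments = fragments,
                 boundary_case = boundary, trace = trace),
            class = "myelination_call")
}

#' @export
print.myelination_call <- function(x, ...) {
  cat("<myelination_call>", x$class,
      if (x$boundary_case) "(boundary case)", "\n ", x$trace, "\n")
  invisible(x)
}
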