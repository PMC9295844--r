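#' Radius of confinement of a trajectory
#'
#' The RC of a trajectory is the distance from its center of mass (the
#' unweighted mean of all localizations) to the farthest localization.
#' Stable binding and local exploration give small RCs; free diffusion and
#' active transport give large RCs, which makes the RC a simple
#' whole-trajectory summary of the dynamic state.
#'
#' @param traj a data.frame with columns `x`, `y` (um) — e.g. one track from
#'   a `track_set` — or a two-column matrix.
#' @return the RC in um.
#' @examples
#' radius_of_confinement(data.frame(x = c(0, 1, 2), y = c(0, 0, 0)))  # 1
#' @export
radius_of_confinement <- function(traj) {
  if (is.matrix(traj)) traj <- data.frame(x = traj[, 1L], y = traj[, 2L])
  if (nrow(traj) < 2L) {
    stop("RC is undefined for trajectories with < 2 localizations",
         call. = FALSE)
  }
  cx <- mean(traj$x); cy <- mean(traj$y)
  max(sqrt((traj$x - cx)^2 + (traj$y - cy)^2))
}

#' Per-track RC values for a track set
#'
#' @param tracks a `track_set` (see [link_tracks()]) or any data.frame with
#'   `track_id`, `x`, `y`.
#' @param min_length minimum localizations per track for inclusion
#'   (default 5; the RC of very short tracks is noise-dominated).
#' @return data.frame `track_id`, `n`, `rc` (um), plus `compartment` when
#'   present in the input.
#' @export
track_rc <- function(tracks, min_length = 5L) {
  ids <- unique(tracks$track_id)
  rows <- lapply(ids, function(id) {
    sel <- tracks$track_id == id
    n <- sum(sel)
    if (n < min_length) return(NULL)
    data.frame(track_id = id, n = n,
               rc = radius_of_confinement(tracks[sel, c("x", "y")]),
               compartment = if ("compartment" %in% names(tracks))
                 tracks$compartment[sel][1L] else NA_character_)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(track_id = integer(0), n = integer(0), rc = numeric(0),
                      compartment = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Binned RC probability density for one condition
#'
#' Density-normalized histogram of RC values over explicit shared bin edges,
#' so that two conditions can be subtracted bin-wise ([differential_pdf()]).
#' Values outside the outermost edges are counted, reported via the
#' `n_excluded` field, and excluded from the density (the density integrates
#' to 1 over the included values).
#'
#' @param rc_values numeric RC values (um, >= 0).
#' @param bin_edges strictly increasing bin edges (um); default 0 to 2 um in
#'   50 nm bins.
#' @param condition condition label.
#' @return object of class `rc_distribution`: list with `condition`,
#'   `rc_values`, `bin_edges`, `pdf` (density per um), `n`, `n_excluded`.
#' @export
rc_pdf <- function(rc_values, bin_edges = seq(0, 2, by = 0.05),
                   condition = "condition") {
  if (length(rc_values) < 1L) stop("need at least one RC value", call. = FALSE)
  if (any(rc_values < 0)) stop("RC values must be >= 0", call. = FALSE)
  if (any(diff(bin_edges) <= 0)) {
    stop("'bin_edges' must be strictly increasing", call. = FALSE)
  }
  inside <- rc_values >= bin_edges[1L] &
            rc_values <= bin_edges[length(bin_edges)]
  n_excluded <- sum(!inside)
  vals <- rc_values[inside]
  if (length(vals) == 0L) {
    stop("no RC values fall within the bin edges", call. = FALSE)
  }
  h <- graphics::hist(vals, breaks = bin_edges, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  structure(list(condition = condition, rc_values = rc_values,
                 bin_edges = bin_edges, pdf = h$density,
                 n = length(vals), n_excluded = n_excluded),
            class = "rc_distribution")
}

#' @export
print.rc_distribution <- function(x, ...) {
  cat(sprintf("<rc_distribution> '%s': n=%d (excluded %d), %d bins over [%g, %g] um\n",
              x$condition, x$n, x$n_excluded, length(x$pdf),
              x$bin_edges[1L], x$bin_edges[length(x$bin_edges)]))
  invisible(x)
}

#' Differential PDF between two conditions
#'
#' Bin-wise subtraction of two RC probability densities sharing the same bin
#' edges: `delta = pdf_a - pdf_b`. A zero delta means equal fraction at that
#' RC; a condition enriched in bound molecules relative to another shows
#' positive delta at small RCs and negative delta at large RCs. The delta
#' integrates to zero by construction.
#'
#' @param a,b `rc_distribution` objects with identical `bin_edges`.
#' @return object of class `differential_pdf`: list with `condition_a`,
#'   `condition_b`, `bin_edges`, `delta` (density difference per um).
#' @export
differential_pdf <- function(a, b) {
  stopifnot(inherits(a, "rc_distribution"), inherits(b, "rc_distribution"))
  if (length(a$bin_edges) != length(b$bin_edges) ||
      any(a$bin_edges != b$bin_edges)) {
    stop("the two distributions must share identical bin edges", call. = FALSE)
  }
  structure(list(condition_a = a$condition, condition_b = b$condition,
                 bin_edges = a$bin_edges, delta = a$pdf - b$pdf),
            class = "differential_pdf")
}

#' Bound and mobile fractions from RC values
#'
#' Binary summary of a condition: the fraction of trajectories whose RC is
#' at or below `rc_threshold` (bound / locally exploring) versus above it
#' (diffusing / transported). The threshold is a reporting choice, not a
#' physical constant; the default 0.2 um is about 3x the localization-noise
#' RC scale under typical single-molecule settings and is always reported
#' alongside results.
#'
#' @param rc_values numeric RC values (um).
#' @param rc_threshold threshold (um, > 0), default 0.2.
#' @return list `bound_fraction`, `mobile_fraction`, `rc_threshold`, `n`.
#' @export
state_fractions <- function(rc_values, rc_threshold = 0.2) {
  if (length(rc_values) == 0L) stop("empty RC input", call. = FALSE)
  if (rc_threshold <= 0) stop("'rc_threshold' must be > 0", call. = FALSE)
  bound <- mean(rc_values <= rc_threshold)
  list(bound_fraction = bound, mobile_fraction = 1 - bound,
       rc_threshold = rc_threshold, n = length(rc_values))
}
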