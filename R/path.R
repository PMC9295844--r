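#' Polyline path utilities
#'
#' Neurite midlines are represented as polylines: a two-column matrix or
#' data.frame of (x, y) vertices in micrometers. These helpers parameterize a
#' polyline by arclength, which the transport simulator and profile extractor
#' use to walk along a path at constant speed or sampling step.
#'
#' @param path two-column matrix/data.frame of vertices (um).
#' @return `path_arclength()`: numeric vector of cumulative arclength at each
#'   vertex, starting at 0. `path_point_at()`: n x 2 matrix of positions.
#'   `path_tangent_at()`: n x 2 matrix of unit tangents.
#' @keywords internal
#' @name path-utils
NULL

as_path <- function(path) {
  p <- as.matrix(path)
  if (ncol(p) != 2L || nrow(p) < 2L) {
    stop("a path needs at least 2 vertices with columns (x, y)", call. = FALSE)
  }
  stop_if_not_finite(p, "path")
  storage.mode(p) <- "double"
  unname(p)
}

#' @rdname path-utils
path_arclength <- function(path) {
  p <- as_path(path)
  seg <- sqrt(rowSums(diff(p)^2))
  c(0, cumsum(seg))
}

#' @rdname path-utils
#' @param s arclength positions (um); clamped to `[0, total length]`.
path_point_at <- function(path, s) {
  p <- as_path(path)
  cs <- path_arclength(p)
  total <- cs[length(cs)]
  s <- pmin(pmax(s, 0), total)
  # segment index for each s (last vertex maps into final segment)
  idx <- findInterval(s, cs, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(p) - 1L)
  seg_len <- cs[idx + 1L] - cs[idx]
  frac <- ifelse(seg_len > 0, (s - cs[idx]) / seg_len, 0)
  p[idx, , drop = FALSE] + frac * (p[idx + 1L, , drop = FALSE] - p[idx, , drop = FALSE])
}

#' @rdname path-utils
path_tangent_at <- function(path, s) {
  p <- as_path(path)
  cs <- path_arclength(p)
  idx <- findInterval(pmin(pmax(s, 0), cs[length(cs)]), cs, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(p) - 1L)
  d <- p[idx + 1L, , drop = FALSE] - p[idx, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  d / ifelse(len > 0, len, 1)
}
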