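#' Read and write movies as multi-page TIFF with a metadata sidecar
#'
#' Movies are stored as 32-bit float multi-page TIFF plus a YAML sidecar
#' (`<stem>.yaml`) holding `pixel_size_um`, `dt_s` and, for simulated
#' movies, the scene seed. Pixel values are photons (not rescaled).
#'
#' @param movie a `movie` object.
#' @param path output TIFF path.
#' @return `write_movie()`: the TIFF path, invisibly. `read_movie()`: a
#'   `movie` object.
#' @export
write_movie <- function(movie, path) {
  # the tiff writer expects [0,1]; photons are rescaled by a factor stored
  # in the sidecar so read_movie() restores the original values
  lo <- min(vapply(movie$frames, min, numeric(1)), 0)
  hi <- max(vapply(movie$frames, max, numeric(1)), lo + 1)
  frames <- lapply(movie$frames, function(f) (f - lo) / (hi - lo))
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(pixel_size_um = movie$pixel_size, dt_s = movie$dt,
               intensity_offset = lo, intensity_scale = hi - lo)
  if (!is.null(movie$scene)) meta$seed <- movie$scene$seed
  yaml::write_yaml(meta, sub("\\.tiff?$", ".yaml", path))
  invisible(path)
}

#' @rdname write_movie
#' @param pixel_size,dt metadata overrides when no sidecar is present.
#' @export
read_movie <- function(path, pixel_size = NULL, dt = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(frames)) frames <- list(frames)
  sidecar <- sub("\\.tiff?$", ".yaml", path)
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    if (is.null(pixel_size)) pixel_size <- meta$pixel_size_um
    if (is.null(dt)) dt <- meta$dt_s
    if (!is.null(meta$intensity_scale)) {
      frames <- lapply(frames, function(f) {
        f * meta$intensity_scale + meta$intensity_offset
      })
    }
  }
  if (is.null(pixel_size)) {
    stop("pixel size unknown: no sidecar and no 'pixel_size' given",
         call. = FALSE)
  }
  structure(list(frames = frames, pixel_size = pixel_size, dt = dt),
            class = "movie")
}

#' Write and read localization and track tables as CSV
#'
#' Plain-CSV interchange for the tabular stages. Localization tables carry
#' columns `frame`, `pass`, `x`, `y` (um), `amplitude`, `background`,
#' `sigma`, `score`, `converged`; track tables carry `track_id`, `frame`,
#' `x`, `y`, `flagged_ambiguous`, `compartment`. Positions use the
#' pixel-(0,0)-center-at-origin convention, in um.
#'
#' @param x the table to write.
#' @param path CSV path.
#' @return the path (write) or the table (read), invisibly/visibly.
#' @export
write_localizations <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  out <- utils::read.csv(path)
  structure(out, class = c("localization_table", "data.frame"))
}

#' @rdname write_localizations
#' @export
write_tracks <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_tracks <- function(path) {
  out <- utils::read.csv(path)
  structure(out, class = c("track_set", "data.frame"))
}

#' Write an RC analysis summary
#'
#' Writes the per-condition PDF as CSV (`bin_left`, `bin_right`, `density`)
#' and, for a differential PDF, the bin-wise `delta`; state-fraction
#' summaries go to JSON.
#'
#' @param x an `rc_distribution` or `differential_pdf`.
#' @param path output CSV path.
#' @export
write_rc_pdf <- function(x, path) {
  edges <- x$bin_edges
  df <- data.frame(bin_left = edges[-length(edges)], bin_right = edges[-1L])
  if (inherits(x, "rc_distribution")) {
    df$density <- x$pdf
  } else if (inherits(x, "differential_pdf")) {
    df$delta <- x$delta
  } else {
    stop("unsupported object", call. = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
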