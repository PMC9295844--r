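#' Tracking parameters
#'
#' MTT-style linking parameters: a track tolerates up to `blinking_frames`
#' consecutive dark frames before termination; candidate associations are
#' gated at the 2D Brownian displacement scale
#' `r_gate(g) = sqrt(4 * D_max * dt * g)` for a gap of `g` frames; at most
#' `max_competitors` candidate tracks are considered per localization, and
#' denser neighborhoods are flagged as ambiguous.
#'
#' @param blinking_frames tolerated consecutive missed frames (>= 0),
#'   default 1.
#' @param max_competitors candidate bound per localization (>= 1), default 3.
#' @param D_max maximum diffusion coefficient (um^2/s, > 0), default 3.
#' @param dt frame interval (s, > 0).
#' @return object of class `tracking_params`.
#' @examples
#' p <- tracking_params(dt = 0.1)
#' gate_radius(p, gap = 1)  # sqrt(4 * 3 * 0.1) ~ 1.095 um
#' @export
tracking_params <- function(blinking_frames = 1, max_competitors = 3,
                            D_max = 3, dt) {
  if (missing(dt) || is.null(dt) || !is.finite(dt) || dt <= 0) {
    stop("'dt' (frame interval, s) is required and must be > 0", call. = FALSE)
  }
  if (blinking_frames < 0) stop("'blinking_frames' must be >= 0", call. = FALSE)
  if (max_competitors < 1) stop("'max_competitors' must be >= 1", call. = FALSE)
  if (D_max <= 0) stop("'D_max' must be > 0", call. = FALSE)
  structure(list(blinking_frames = as.integer(blinking_frames),
                 max_competitors = as.integer(max_competitors),
                 D_max = D_max, dt = dt),
            class = "tracking_params")
}

#' @rdname tracking_params
#' @param params a `tracking_params` object.
#' @param gap frame gap `g` (1 = consecutive frames).
#' @export
gate_radius <- function(params, gap = 1) {
  sqrt(4 * params$D_max * params$dt * gap)
}

# exact minimum-cost assignment of localizations to candidate tracks within
# one connected component of the gated candidate graph. cand is a list over
# component locs: integer vectors of track slots; cost the matching squared
# distances. Maximum cardinality is enforced by pricing "start a new track"
# at `big` per unmatched localization. Returns the chosen track slot per
# loc (NA = new track). Deterministic: locs processed in index order, track
# candidates in increasing-cost order, ties by lower candidate index.
assign_component <- function(cand, cost, big) {
  n <- length(cand)
  best <- list(cost = Inf, pick = rep(NA_integer_, n))
  pick <- rep(NA_integer_, n)
  used <- integer(0)
  recurse <- function(i, acc) {
    if (acc >= best$cost) return()
    if (i > n) {
      best <<- list(cost = acc, pick = pick)
      return()
    }
    ord <- order(cost[[i]], cand[[i]])
    for (j in ord) {
      tr <- cand[[i]][j]
      if (tr %in% used) next
      used <<- c(used, tr); pick[i] <<- tr
      recurse(i + 1L, acc + cost[[i]][j])
      used <<- used[-length(used)]; pick[i] <<- NA_integer_
    }
    recurse(i + 1L, acc + big)  # leave loc i unmatched
  }
  recurse(1L, 0)
  best$pick
}

#' Link localizations into trajectories
#'
#' Frame-to-frame association minimizing summed squared displacements,
#' subject to the diffusion gate `sqrt(4 * D_max * dt * g)` for a gap of `g`
#' frames. Unmatched localizations start new tracks; a track unmatched for
#' more than `blinking_frames` consecutive frames is terminated. Gated
#' candidate pairs are partitioned into connected components and each
#' component is solved exactly (maximum cardinality, then minimum summed
#' squared distance); localizations with more than `max_competitors` tracks
#' in their gate keep only the nearest `max_competitors` and are flagged
#' ambiguous. Input row order does not affect the resulting partition
#' (rows are canonically sorted first).
#'
#' @param localizations data.frame with columns `frame` (integer), `x`, `y`
#'   (um) — e.g. a [localize_movie()] table.
#' @param params [tracking_params()] (carries `dt`).
#' @param min_length tracks with fewer localizations are dropped (default 2;
#'   the radius of confinement is undefined below 2).
#' @return data.frame (class `track_set`): `track_id`, `frame`, `x`, `y`,
#'   `flagged_ambiguous`, `compartment` (initialized `"none"`). Track ids are
#'   consecutive integers in order of first appearance.
#' @export
link_tracks <- function(localizations, params, min_length = 2L) {
  stopifnot(inherits(params, "tracking_params"))
  locs <- as.data.frame(localizations)
  need <- c("frame", "x", "y")
  if (!all(need %in% names(locs))) {
    stop("'localizations' needs columns frame, x, y", call. = FALSE)
  }
  dup <- duplicated(locs[, need])
  if (any(dup)) {
    stop("duplicate (frame, x, y) rows: ",
         paste(utils::head(which(dup), 5L), collapse = ", "), call. = FALSE)
  }
  locs <- locs[order(locs$frame, locs$x, locs$y), need, drop = FALSE]
  rownames(locs) <- NULL
  n <- nrow(locs)
  if (n == 0L) {
    return(structure(data.frame(track_id = integer(0), frame = integer(0),
                                x = numeric(0), y = numeric(0),
                                flagged_ambiguous = logical(0),
                                compartment = character(0)),
                     class = c("track_set", "data.frame")))
  }

  track_of <- integer(n)        # assigned track id per localization row
  ambiguous <- logical(n)
  # active track state
  act_id <- integer(0); act_x <- numeric(0); act_y <- numeric(0)
  act_frame <- integer(0)
  next_id <- 1L
  max_gap <- params$blinking_frames + 1L

  for (f in sort(unique(locs$frame))) {
    rows <- which(locs$frame == f)
    # drop expired tracks
    alive <- (f - act_frame) <= max_gap
    act_id <- act_id[alive]; act_x <- act_x[alive]; act_y <- act_y[alive]
    act_frame <- act_frame[alive]

    cand <- vector("list", length(rows))
    cost <- vector("list", length(rows))
    if (length(act_id) > 0L) {
      for (i in seq_along(rows)) {
        g <- f - act_frame
        d2 <- (locs$x[rows[i]] - act_x)^2 + (locs$y[rows[i]] - act_y)^2
        gate2 <- 4 * params$D_max * params$dt * g
        in_gate <- which(d2 <= gate2)
        if (length(in_gate) > params$max_competitors) {
          ambiguous[rows[i]] <- TRUE
          in_gate <- in_gate[order(d2[in_gate])][seq_len(params$max_competitors)]
        }
        cand[[i]] <- in_gate
        cost[[i]] <- d2[in_gate]
      }
    }

    # connected components of the loc-track candidate graph
    pick <- rep(NA_integer_, length(rows))
    unseen <- which(lengths(cand) > 0L)
    big <- 4 * params$D_max * params$dt * max_gap * (length(rows) + 1L)
    while (length(unseen) > 0L) {
      comp <- unseen[1L]; comp_tracks <- cand[[comp]]
      repeat {
        grow <- unseen[vapply(unseen, function(i) {
          !(i %in% comp) && length(intersect(cand[[i]], comp_tracks)) > 0L
        }, logical(1))]
        if (length(grow) == 0L) break
        comp <- c(comp, grow)
        comp_tracks <- unique(unlist(cand[comp]))
      }
      unseen <- setdiff(unseen, comp)
      comp <- sort(comp)
      if (length(comp) == 1L && length(cand[[comp]]) == 1L) {
        pick[comp] <- cand[[comp]]
      } else if (length(comp) <= 10L) {
        pick[comp] <- assign_component(cand[comp], cost[comp], big)
      } else {
        # dense pathological component: deterministic greedy by global cost
        pairs <- do.call(rbind, lapply(comp, function(i) {
          cbind(i, cand[[i]], cost[[i]])
        }))
        pairs <- pairs[order(pairs[, 3L], pairs[, 1L], pairs[, 2L]), ,
                       drop = FALSE]
        taken <- integer(0)
        for (k in seq_len(nrow(pairs))) {
          i <- pairs[k, 1L]; tr <- pairs[k, 2L]
          if (is.na(pick[i]) && !(tr %in% taken)) {
            pick[i] <- tr; taken <- c(taken, tr)
          }
        }
        ambiguous[rows[comp]] <- TRUE
      }
    }

    # apply assignments / start new tracks
    matched_slots <- integer(0)
    for (i in seq_along(rows)) {
      if (!is.na(pick[i])) {
        slot <- pick[i]
        track_of[rows[i]] <- act_id[slot]
        act_x[slot] <- locs$x[rows[i]]; act_y[slot] <- locs$y[rows[i]]
        act_frame[slot] <- f
        matched_slots <- c(matched_slots, slot)
      } else {
        track_of[rows[i]] <- next_id
        act_id <- c(act_id, next_id)
        act_x <- c(act_x, locs$x[rows[i]]); act_y <- c(act_y, locs$y[rows[i]])
        act_frame <- c(act_frame, f)
        next_id <- next_id + 1L
      }
    }
  }

  out <- data.frame(track_id = track_of, frame = locs$frame,
                    x = locs$x, y = locs$y, flagged_ambiguous = ambiguous,
                    compartment = "none")
  keep_ids <- names(which(table(out$track_id) >= min_length))
  out <- out[out$track_id %in% as.integer(keep_ids), , drop = FALSE]
  # renumber by first appearance
  out <- out[order(out$frame, out$x, out$y), , drop = FALSE]
  first <- !duplicated(out$track_id)
  remap <- stats::setNames(seq_len(sum(first)), out$track_id[first])
  out$track_id <- as.integer(remap[as.character(out$track_id)])
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("track_set", "data.frame"),
            params = params, min_length = as.integer(min_length))
}

#' Assign trajectories to labeled compartments
#'
#' Labels each trajectory by the region (labeled polygon: AIS, soma,
#' distal_axon, dendrite, ...) containing its center of mass; trajectories
#' outside all regions are labeled `"none"`. Regions must not overlap.
#'
#' @param tracks a `track_set` (see [link_tracks()]).
#' @param regions named list of polygons (two-column x, y matrices or
#'   data.frames, um).
#' @return the `track_set` with its `compartment` column filled in.
#' @export
assign_compartment <- function(tracks, regions) {
  stopifnot(is.list(regions), length(names(regions)) == length(regions))
  polys <- lapply(regions, as_path)
  # overlap check: no vertex of one polygon strictly inside another
  if (length(polys) > 1L) {
    for (i in seq_along(polys)) for (j in seq_along(polys)) {
      if (i == j) next
      inside <- pracma::inpolygon(polys[[i]][, 1L], polys[[i]][, 2L],
                                  polys[[j]][, 1L], polys[[j]][, 2L],
                                  boundary = FALSE)
      if (any(inside)) {
        stop(sprintf("regions '%s' and '%s' overlap", names(polys)[i],
                     names(polys)[j]), call. = FALSE)
      }
    }
  }
  ids <- unique(tracks$track_id)
  com <- t(vapply(ids, function(id) {
    sel <- tracks$track_id == id
    c(mean(tracks$x[sel]), mean(tracks$y[sel]))
  }, numeric(2)))
  label <- rep("none", length(ids))
  for (nm in names(polys)) {
    hit <- pracma::inpolygon(com[, 1L], com[, 2L],
                             polys[[nm]][, 1L], polys[[nm]][, 2L],
                             boundary = TRUE)
    label[hit & label == "none"] <- nm
  }
  tracks$compartment <- label[match(tracks$track_id, ids)]
  tracks
}
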