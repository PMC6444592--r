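#' Link per-frame localizations into trajectories
#'
#' For each consecutive frame pair, matches open trajectory ends to the
#' next frame's localizations by a globally optimal one-to-one assignment
#' (Hungarian algorithm) restricted to candidate pairs closer than
#' `max_radius` pixels. The assignment maximizes the number of links and,
#' among such matchings, minimizes the summed distance. Unmatched
#' localizations start new trajectories; unmatched trajectory ends are
#' closed (no gap tolerance: a missed frame terminates the trajectory).
#'
#' @param locs A `localization_table` (needs columns `frame`, `x_px`,
#'   `y_px`), sorted by frame.
#' @param max_radius Linking radius in pixels; default 6 px (936 nm at
#'   the 156 nm pixel pitch).
#' @return A data.frame of class `track_table` with columns
#'   `trajectory_id`, `frame`, `x_px`, `y_px`.
#' @examples
#' locs <- data.frame(frame = rep(1:3, each = 1), x_px = c(5, 5.2, 5.4),
#'                    y_px = c(5, 5, 5))
#' link_localizations(locs)
#' @export
link_localizations <- function(locs, max_radius = 6) {
  stopifnot(max_radius > 0)
  locs <- as.data.frame(locs)
  need <- c("frame", "x_px", "y_px")
  if (!all(need %in% names(locs))) {
    stop("locs must have columns frame, x_px, y_px")
  }
  if (anyDuplicated(locs[need])) {
    stop("duplicate (frame, x, y) localization rows")
  }
  locs <- locs[order(locs$frame), , drop = FALSE]
  if (nrow(locs) == 0L) {
    return(structure(data.frame(trajectory_id = integer(), frame = integer(),
                                x_px = numeric(), y_px = numeric()),
                     class = c("track_table", "data.frame")))
  }
  frames <- sort(unique(locs$frame))
  by_frame <- split(locs, locs$frame)

  first <- by_frame[[as.character(frames[1])]]
  traj_of <- seq_len(nrow(first))          # trajectory id of each open end
  open_xy <- cbind(first$x_px, first$y_px)
  next_id <- nrow(first) + 1L
  out <- list(data.frame(trajectory_id = traj_of, frame = frames[1],
                         x_px = first$x_px, y_px = first$y_px))

  for (k in seq_along(frames)[-1]) {
    cur <- by_frame[[as.character(frames[k])]]
    m <- nrow(cur)
    gap <- frames[k] - frames[k - 1L]
    if (gap != 1L || length(traj_of) == 0L) {
      assn <- rep(NA_integer_, m)           # all starts; old ends close
    } else {
      d <- sqrt(outer(open_xy[, 1], cur$x_px, "-")^2 +
                  outer(open_xy[, 2], cur$y_px, "-")^2)
      assn_prev <- match_frame_pair(d, max_radius)  # per open end: col or NA
      assn <- rep(NA_integer_, m)
      assn[assn_prev[!is.na(assn_prev)]] <-
        which(!is.na(assn_prev))            # per cur loc: open-end row or NA
    }
    new_traj <- integer(m)
    for (j in seq_len(m)) {
      if (!is.na(assn[j])) {
        new_traj[j] <- traj_of[assn[j]]
      } else {
        new_traj[j] <- next_id
        next_id <- next_id + 1L
      }
    }
    out[[k]] <- data.frame(trajectory_id = new_traj, frame = frames[k],
                           x_px = cur$x_px, y_px = cur$y_px)
    traj_of <- new_traj
    open_xy <- cbind(cur$x_px, cur$y_px)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$trajectory_id, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("track_table", "data.frame")
  res
}

# accept simulator track tables (molecule_id) as well as linked ones
normalize_track_ids <- function(tracks) {
  tracks <- as.data.frame(tracks)
  if (!"trajectory_id" %in% names(tracks)) {
    if ("molecule_id" %in% names(tracks)) {
      tracks$trajectory_id <- tracks$molecule_id
    } else {
      stop("tracks need a trajectory_id (or molecule_id) column")
    }
  }
  tracks
}

# Optimal one-to-one matching for one frame pair.
# d: n_prev x n_cur distance matrix. Returns, per previous end, the matched
# current column index or NA. Non-assignment costs `max_radius` per side, so
# any within-radius link (cost <= r < 2r) is preferred over leaving both
# endpoints unmatched; disallowed pairs get a prohibitive cost.
match_frame_pair <- function(d, max_radius) {
  n1 <- nrow(d); n2 <- ncol(d)
  if (n1 == 0L || n2 == 0L) return(rep(NA_integer_, n1))
  big <- (n1 + n2) * (2 * max_radius + 1) + 1e6
  sz <- n1 + n2
  cost <- matrix(big, sz, sz)
  cost[seq_len(n1), seq_len(n2)] <- ifelse(d <= max_radius, d, big)
  cost[seq_len(n1), n2 + seq_len(n1)] <- max_radius          # end closes
  cost[n1 + seq_len(n2), seq_len(n2)] <- max_radius          # new start
  cost[n1 + seq_len(n2), n2 + seq_len(n1)] <- 0              # dummy-dummy
  sol <- as.integer(clue::solve_LSAP(cost))
  assn <- sol[seq_len(n1)]
  assn[assn > n2] <- NA_integer_
  # guard: never keep a disallowed (out-of-radius) pairing
  bad <- !is.na(assn) & d[cbind(seq_len(n1), ifelse(is.na(assn), 1L, assn))] > max_radius
  assn[bad] <- NA_integer_
  assn
}

#' Pool jump distances from linked trajectories
#'
#' Computes Euclidean displacement magnitudes between trajectory points
#' `lag_frames` apart, pooled over all trajectories, in um.
#'
#' @param tracks A `track_table` (columns `trajectory_id`, `frame`,
#'   `x_px`, `y_px`).
#' @param lag_frames Lag in frames (>= 1).
#' @param frame_interval Frame interval in seconds.
#' @param pixel_size Pixel pitch in nm (default 156).
#' @return A [jump_dataset()] with `dt = lag_frames * frame_interval`.
#' @export
compute_jumps <- function(tracks, lag_frames = 1L,
                          frame_interval = 0.0135, pixel_size = 156) {
  stopifnot(lag_frames >= 1L, frame_interval > 0)
  tracks <- normalize_track_ids(tracks)
  px_um <- pixel_size / 1000
  jumps <- unlist(lapply(split(tracks, tracks$trajectory_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    n <- nrow(tr)
    if (n <= lag_frames) return(numeric(0))
    i <- seq_len(n - lag_frames)
    keep <- tr$frame[i + lag_frames] - tr$frame[i] == lag_frames
    sqrt((tr$x_px[i + lag_frames] - tr$x_px[i])^2 +
           (tr$y_px[i + lag_frames] - tr$y_px[i])^2)[keep] * px_um
  }), use.names = FALSE)
  if (length(jumps) == 0L) {
    warning("lag longer than every trajectory: empty jump dataset")
  }
  jump_dataset(jumps, dt = lag_frames * frame_interval)
}

#' Derive residence times from linked trajectories
#'
#' Converts each trajectory into a dwell time. The default convention is
#' `(n_points - 1) * frame_interval` (time between first and last
#' observation); the alternative `n_points * frame_interval` is available
#' via `convention = "n"`. Trajectories that touch the movie's last frame
#' are flagged right-censored.
#'
#' @param tracks A `track_table`.
#' @param frame_interval Frame interval in seconds (> 0).
#' @param last_frame Movie's final frame index; defaults to the maximum
#'   frame present.
#' @param min_points Minimum trajectory length to keep (default 2).
#' @param convention `"n_minus_1"` (default) or `"n"`.
#' @return A [dwell_dataset()].
#' @export
compute_dwells <- function(tracks, frame_interval = 0.5,
                           last_frame = NULL, min_points = 2L,
                           convention = c("n_minus_1", "n")) {
  stopifnot(frame_interval > 0)
  convention <- match.arg(convention)
  tracks <- normalize_track_ids(tracks)
  if (is.null(last_frame)) last_frame <- max(tracks$frame)
  per <- lapply(split(tracks, tracks$trajectory_id), function(tr) {
    c(n = nrow(tr), touches_end = as.integer(max(tr$frame) >= last_frame))
  })
  tab <- do.call(rbind, per)
  keep <- tab[, "n"] >= min_points
  n_pts <- tab[keep, "n"]
  dwells <- if (convention == "n_minus_1") {
    (n_pts - 1) * frame_interval
  } else {
    n_pts * frame_interval
  }
  dwell_dataset(dwells, frame_interval = frame_interval,
                censored = tab[keep, "touches_end"] == 1L)
}

#' Read or write a track table as CSV
#'
#' @param tracks A `track_table`.
#' @param path CSV file path.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("track_table", "data.frame")
  out
}
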