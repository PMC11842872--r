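#' Link localizations into tracks by greedy nearest-neighbour matching
#'
#' Frame-to-frame linking in the style of nearest-neighbour single-particle
#' trackers: localizations are processed frame by frame; each localization is
#' linked to the nearest unclaimed track head within `radius`, unlinked
#' localizations seed new tracks, and a track head may bridge up to
#' `max_gap_frames` missing frames before it is retired. Tie-breaking is
#' deterministic: localizations are considered in input order within a frame,
#' and among equidistant heads the lowest track id wins.
#'
#' @param locs Data frame of localizations with columns `frame` (0-based
#'   integer), `t_s`, `x_um`, `y_um`.
#' @param radius Maximum linking distance (µm), must be positive.
#' @param max_gap_frames Number of consecutive missing frames a track may
#'   bridge (0 = none).
#' @param min_length Minimum number of localizations for a track to be kept.
#' @return Data frame of tracks with columns `track_id`, `frame`, `t_s`,
#'   `x_um`, `y_um`; track ids are 1-based in order of first appearance.
#' @examples
#' locs <- data.frame(frame = 0:4, t_s = 0:4 * 0.0117,
#'                    x_um = cumsum(c(1, rnorm(4, 0, 0.05))),
#'                    y_um = cumsum(c(1, rnorm(4, 0, 0.05))))
#' link_tracks(locs, radius = 0.5)
#' @export
link_tracks <- function(locs, radius, max_gap_frames = 0L, min_length = 1L) {
  if (radius <= 0) stop("`radius` must be positive")
  need <- c("frame", "t_s", "x_um", "y_um")
  empty <- locs[0, need, drop = FALSE]
  empty$track_id <- integer(0)
  if (nrow(locs) == 0) return(empty[, c("track_id", need)])
  stopifnot(all(need %in% names(locs)))

  ord <- order(locs$frame, seq_len(nrow(locs)))
  locs <- locs[ord, need, drop = FALSE]
  frames <- sort(unique(locs$frame))

  head_x <- numeric(0); head_y <- numeric(0)
  head_frame <- integer(0); head_id <- integer(0)
  assign_id <- integer(nrow(locs))
  next_id <- 1L

  for (f in frames) {
    idx <- which(locs$frame == f)
    alive <- which(head_frame >= f - 1L - max_gap_frames & head_frame < f)
    claimed <- rep(FALSE, length(alive))
    for (i in idx) {
      best <- 0L; best_d <- radius
      if (length(alive)) {
        dx <- head_x[alive] - locs$x_um[i]
        dy <- head_y[alive] - locs$y_um[i]
        d <- sqrt(dx * dx + dy * dy)
        d[claimed] <- Inf
        j <- which(d <= best_d)
        if (length(j)) {
          # nearest head; equidistant heads resolved by lowest track id
          dmin <- min(d[j])
          cand <- j[d[j] <= dmin + 1e-12]
          best <- cand[which.min(head_id[alive][cand])]
          best_d <- dmin
        }
      }
      if (best > 0L) {
        k <- alive[best]
        claimed[best] <- TRUE
        assign_id[i] <- head_id[k]
        head_x[k] <- locs$x_um[i]; head_y[k] <- locs$y_um[i]
        head_frame[k] <- f
      } else {
        assign_id[i] <- next_id
        head_x <- c(head_x, locs$x_um[i]); head_y <- c(head_y, locs$y_um[i])
        head_frame <- c(head_frame, f); head_id <- c(head_id, next_id)
        next_id <- next_id + 1L
      }
    }
  }

  locs$track_id <- assign_id
  len <- table(locs$track_id)
  keep <- as.integer(names(len)[len >= min_length])
  locs <- locs[locs$track_id %in% keep, , drop = FALSE]
  if (nrow(locs) == 0) return(empty[, c("track_id", need)])
  # renumber by first appearance
  locs$track_id <- match(locs$track_id, unique(locs$track_id))
  rownames(locs) <- NULL
  locs[, c("track_id", need)]
}

#' Jump distances of tracks
#'
#' Euclidean displacements between consecutive detections of each track.
#' Jumps spanning one or more missing (gap) frames are removed when
#' `exclude_gap_jumps` is set, and at most `cap` jumps (the first `cap`) are
#' kept per track so that long-lived bound molecules do not dominate the
#' jump-distance distribution.
#'
#' @param tracks Track table as returned by [link_tracks()].
#' @param cap Maximum number of jumps per track (default 10).
#' @param exclude_gap_jumps Drop jumps that bridge missing frames.
#' @return Data frame with columns `track_id`, `from_frame`, `jump_um`.
#' @export
jump_distances <- function(tracks, cap = 10L, exclude_gap_jumps = TRUE) {
  stopifnot(nrow(tracks) >= 1 || is.data.frame(tracks))
  out <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    m <- nrow(tr)
    if (m < 2) {
      return(data.frame(track_id = integer(0), from_frame = integer(0),
                        jump_um = numeric(0)))
    }
    d <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
    gap <- diff(tr$frame) > 1L
    keep <- if (exclude_gap_jumps) !gap else rep(TRUE, m - 1L)
    d <- d[keep]
    ff <- tr$frame[-m][keep]
    if (length(d) > cap) {
      d <- d[seq_len(cap)]
      ff <- ff[seq_len(cap)]
    }
    data.frame(track_id = tr$track_id[1], from_frame = ff, jump_um = d)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write / read track tables
#'
#' Tracks are exchanged as plain TSV with columns
#' `track_id, frame, t_s, x_um, y_um`.
#'
#' @param tracks Track table.
#' @param path File path.
#' @return `read_tracks` returns the track table.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.table(tracks[, c("track_id", "frame", "t_s", "x_um", "y_um")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("integer", "integer", "numeric",
                                   "numeric", "numeric"))
}
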