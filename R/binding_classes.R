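# Survived dark times per track.
#
# A track survives a dark interval of the scheme when detections flank it
# (optionally within `confinement_radius` of each other). Detections need not
# be in adjacent frames: a molecule missed in one exposure still survived the
# surrounding dark times, so every dark interval between the first and last
# detection counts unless the flanking detections moved too far apart.
survived_darks <- function(frames, xs, ys, ft, confinement_radius = NULL,
                           short_min = 0.05, long_min = 1) {
  if (length(frames) < 2) return(c(short = 0L, long = 0L))
  cls <- dark_class(ft$dark_after_s, short_min, long_min)
  dark_idx <- which(cls != "none" & ft$frame >= min(frames) &
                      ft$frame < max(frames))
  if (!length(dark_idx)) return(c(short = 0L, long = 0L))
  ok <- rep(TRUE, length(dark_idx))
  if (!is.null(confinement_radius)) {
    for (j in seq_along(dark_idx)) {
      f <- ft$frame[dark_idx[j]]
      i_before <- max(which(frames <= f))
      i_after <- min(which(frames > f))
      d <- sqrt((xs[i_after] - xs[i_before])^2 + (ys[i_after] - ys[i_before])^2)
      ok[j] <- d <= confinement_radius
    }
  }
  tab <- table(factor(cls[dark_idx][ok], levels = c("short", "long")))
  c(short = unname(tab["short"]), long = unname(tab["long"]))
}

#' Classify ITM tracks into binding classes
#'
#' Tracks from an interlaced time-lapse movie are sorted into disjoint
#' classes by the dark times they survive: `spot` (single detection),
#' `long` (survived at least two long dark times), `short` (survived at
#' least one short dark time but no long dark time), and `grey` (survived
#' exactly one long dark time; excluded from both named classes but counted
#' in the denominator of the fractions).
#'
#' @param tracks Track table (one movie), columns `track_id`, `frame`,
#'   `x_um`, `y_um`.
#' @param scheme The ITM [illumination_scheme()] the movie was recorded with;
#'   must contain both short and long dark times.
#' @param confinement_radius Maximum displacement across a dark time for it
#'   to count as survived (µm); `NULL` trusts the linking radius.
#' @param short_min,long_min Dark-class boundaries (s), see [dark_class()].
#' @return Object of class `binding_class_counts`: counts `N_long`,
#'   `N_short`, `N_spot`, `N_grey` and a per-track class vector.
#' @export
classify_itm <- function(tracks, scheme, confinement_radius = NULL,
                         short_min = 0.05, long_min = 1) {
  ft <- frame_table(scheme)
  cls_present <- unique(dark_class(ft$dark_after_s, short_min, long_min))
  if (!all(c("short", "long") %in% cls_present)) {
    stop("scheme must contain both short and long dark times (ITM pattern)")
  }
  per_track <- vapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (nrow(tr) == 1) return("spot")
    sv <- survived_darks(tr$frame, tr$x_um, tr$y_um, ft, confinement_radius,
                         short_min, long_min)
    if (sv["long"] >= 2) "long"
    else if (sv["long"] == 1) "grey"
    else if (sv["short"] >= 1) "short"
    else "spot"  # multi-frame track spanning no dark time
  }, character(1))
  counts <- table(factor(per_track, levels = c("long", "short", "spot",
                                               "grey")))
  structure(list(N_long = unname(counts["long"]),
                 N_short = unname(counts["short"]),
                 N_spot = unname(counts["spot"]),
                 N_grey = unname(counts["grey"]),
                 classes = per_track),
            class = "binding_class_counts")
}

#' @export
print.binding_class_counts <- function(x, ...) {
  cat(sprintf("ITM classes: long %d, short %d, spot %d, grey %d\n",
              x$N_long, x$N_short, x$N_spot, x$N_grey))
  invisible(x)
}

#' Binding-class fractions
#'
#' Long- and short-bound fractions of one or several movies. The denominator
#' is the total number of scored tracks (long + short + spot + grey); for a
#' list of movie-wise counts the movie-wise fractions are reported together
#' with their mean and s.d.
#'
#' @param counts A `binding_class_counts` object or a list of them (one per
#'   movie).
#' @return For a single movie, a list with `long_fraction` and
#'   `short_fraction`; for a list, additionally a per-movie data frame and
#'   `mean`/`sd` of each fraction.
#' @export
class_fractions <- function(counts) {
  one <- function(ct) {
    denom <- ct$N_long + ct$N_short + ct$N_spot + ct$N_grey
    if (denom == 0) stop("no tracks: fractions undefined")
    c(long_fraction = ct$N_long / denom, short_fraction = ct$N_short / denom)
  }
  if (inherits(counts, "binding_class_counts")) {
    as.list(one(counts))
  } else {
    per <- t(vapply(counts, one, numeric(2)))
    list(per_movie = as.data.frame(per),
         long_fraction = mean(per[, "long_fraction"]),
         short_fraction = mean(per[, "short_fraction"]),
         long_sd = stats::sd(per[, "long_fraction"]),
         short_sd = stats::sd(per[, "short_fraction"]))
  }
}

#' Mobility of classified molecules in TACO movies
#'
#' Filters tracks by the TACO class rule (long: survived at least two long
#' dark times; short: survived at least one short dark time and no long dark
#' time) and computes, per qualifying track, the mean jump distance over its
#' first complete gap-free burst of continuously illuminated frames. Later
#' bursts of the same track are discarded to avoid overrepresentation.
#'
#' @param tracks Track table.
#' @param scheme A [taco_scheme()] (frames labelled `"probe"`/`"burst"`).
#' @param class `"short"` or `"long"`.
#' @param confinement_radius Optional survival confinement (µm).
#' @return Object of class `taco_mobility`: per-track mean jumps, cohort
#'   `mean_um` and `sd_um`, and the class label. Empty result (0 rows) if no
#'   track qualifies.
#' @export
taco_mobility <- function(tracks, scheme, class = c("short", "long"),
                          confinement_radius = NULL) {
  class <- match.arg(class)
  ft <- frame_table(scheme)
  if (!any(ft$label == "burst")) {
    stop("scheme has no continuous burst frames; not a TACO scheme")
  }
  # consecutive runs of burst frames in the scheme
  burst <- ft$frame[ft$label == "burst"]
  run_id <- cumsum(c(1L, diff(burst) != 1L))
  runs <- split(burst, run_id)

  rows <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (nrow(tr) < 2) return(NULL)
    sv <- survived_darks(tr$frame, tr$x_um, tr$y_um, ft, confinement_radius)
    qualifies <- if (class == "long") sv["long"] >= 2
                 else sv["short"] >= 1 && sv["long"] == 0
    if (!qualifies) return(NULL)
    for (rn in runs) {
      if (all(rn %in% tr$frame)) {   # first complete, gap-free burst
        sub <- tr[match(rn, tr$frame), ]
        d <- sqrt(diff(sub$x_um)^2 + diff(sub$y_um)^2)
        return(data.frame(track_id = tr$track_id[1],
                          mean_jump_um = mean(d), n_jumps = length(d)))
      }
    }
    NULL
  })
  per <- do.call(rbind, rows)
  if (is.null(per)) per <- data.frame(track_id = integer(0),
                                      mean_jump_um = numeric(0),
                                      n_jumps = integer(0))
  rownames(per) <- NULL
  structure(list(class = class, per_track = per,
                 mean_um = mean(per$mean_jump_um),
                 sd_um = stats::sd(per$mean_jump_um)),
            class = "taco_mobility")
}

#' @export
print.taco_mobility <- function(x, ...) {
  cat(sprintf("TACO %s-bound mobility: %d tracks, mean jump %.1f +/- %.1f nm\n",
              x$class, nrow(x$per_track), 1000 * x$mean_um, 1000 * x$sd_um))
  invisible(x)
}
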