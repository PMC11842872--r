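#' Illumination schemes
#'
#' An illumination scheme describes the repeating pattern of camera exposures,
#' readout intervals and dark times used to record a single-molecule movie.
#' The scheme fixes the timestamp of every frame and therefore which molecular
#' events are observable: continuous movies resolve fast diffusion, time-lapse
#' movies with long dark times resolve slow dissociation, and interlaced
#' patterns (ITM/TACO) separate binding-time classes.
#'
#' @param name Character label for the scheme.
#' @param cycle Data frame with one row per frame of the repeating unit and
#'   columns `exposure_s`, `readout_s`, `dark_s` (all seconds, non-negative).
#'   An optional `label` column tags frames (e.g. `"probe"` vs `"burst"`).
#' @param repeats Number of times the cycle is repeated.
#' @return An object of class `illumination_scheme`.
#' @examples
#' sch <- continuous_scheme(n_frames = 10)
#' frame_cycle_time(sch)  # 0.0117 s
#' @export
illumination_scheme <- function(name, cycle, repeats = 1L) {
  stopifnot(is.data.frame(cycle), nrow(cycle) >= 1L)
  need <- c("exposure_s", "readout_s", "dark_s")
  if (!all(need %in% names(cycle))) {
    stop("`cycle` must have columns exposure_s, readout_s, dark_s")
  }
  if (any(vapply(cycle[need], function(x) any(x < 0), logical(1)))) {
    stop("all durations must be non-negative")
  }
  if (!any(cycle$exposure_s > 0)) {
    stop("at least one event must have exposure_s > 0")
  }
  repeats <- as.integer(repeats)
  stopifnot(repeats >= 1L)
  if (is.null(cycle$label)) cycle$label <- "frame"
  structure(list(name = name, cycle = cycle[, c(need, "label")],
                 repeats = repeats),
            class = "illumination_scheme")
}

#' @export
print.illumination_scheme <- function(x, ...) {
  cat("Illumination scheme:", x$name, "\n")
  cat(sprintf("  %d-frame cycle x %d repeats (%d frames, %.3f s total)\n",
              nrow(x$cycle), x$repeats, nrow(x$cycle) * x$repeats,
              sum(x$cycle$exposure_s + x$cycle$readout_s + x$cycle$dark_s) *
                x$repeats))
  print(x$cycle, row.names = FALSE)
  invisible(x)
}

#' Frame table of a scheme
#'
#' Expands a scheme into one row per frame with its (exactly reproducible)
#' exposure start time, exposure duration, the dark time following the frame,
#' and the frame label. Frames are 0-based, timestamps strictly increasing.
#'
#' @param scheme An [illumination_scheme()].
#' @return Data frame with columns `frame`, `t_s`, `exposure_s`,
#'   `dark_after_s`, `label`.
#' @export
frame_table <- function(scheme) {
  stopifnot(inherits(scheme, "illumination_scheme"))
  ev <- scheme$cycle[rep(seq_len(nrow(scheme$cycle)), scheme$repeats), ,
                     drop = FALSE]
  dur <- ev$exposure_s + ev$readout_s + ev$dark_s
  n <- nrow(ev)
  t0 <- cumsum(c(0, dur))[seq_len(n)]
  data.frame(frame = seq_len(n) - 1L, t_s = t0, exposure_s = ev$exposure_s,
             dark_after_s = ev$dark_s, label = ev$label,
             row.names = NULL)
}

#' Frame cycle time
#'
#' Exposure plus camera readout of a cycle event; the effective frame rate of
#' a continuous movie.
#'
#' @param scheme An [illumination_scheme()].
#' @param event Row index into the cycle (default first).
#' @return Cycle time in seconds.
#' @export
frame_cycle_time <- function(scheme, event = 1L) {
  stopifnot(inherits(scheme, "illumination_scheme"))
  scheme$cycle$exposure_s[event] + scheme$cycle$readout_s[event]
}

#' Total scheme duration
#' @param scheme An [illumination_scheme()].
#' @return Duration in seconds covered by all repeats.
#' @export
scheme_duration <- function(scheme) {
  stopifnot(inherits(scheme, "illumination_scheme"))
  sum(scheme$cycle$exposure_s + scheme$cycle$readout_s + scheme$cycle$dark_s) *
    scheme$repeats
}

#' Continuous illumination
#'
#' Back-to-back frames with no dark time, the scheme used to measure jump
#' distance distributions and diffusion mixtures. Defaults give the 11.7 ms
#' frame cycle (10 ms exposure + 1.7 ms readout).
#'
#' @param n_frames Number of frames.
#' @param exposure_s,readout_s Exposure and camera readout (s).
#' @return An [illumination_scheme()].
#' @export
continuous_scheme <- function(n_frames = 100L, exposure_s = 0.010,
                              readout_s = 0.0017) {
  illumination_scheme(
    "continuous",
    data.frame(exposure_s = exposure_s, readout_s = readout_s, dark_s = 0),
    repeats = n_frames)
}

#' Time-lapse illumination
#'
#' Long-exposure frames separated by a fixed dark time; long exposures blur
#' out diffusing molecules so that only bound molecules are tracked. Defaults
#' give the 501.7 ms frame cycle; with `dark_s = 4.0136` the frame-to-frame
#' interval is 4.5153 s.
#'
#' @param n_frames Number of frames.
#' @param exposure_s,readout_s,dark_s Durations in seconds.
#' @export
timelapse_scheme <- function(n_frames = 100L, exposure_s = 0.5,
                             readout_s = 0.0017, dark_s = 0) {
  nm <- if (dark_s > 0) sprintf("timelapse_%.4gs", exposure_s + readout_s +
                                  dark_s) else "timelapse_continuous"
  illumination_scheme(
    nm,
    data.frame(exposure_s = exposure_s, readout_s = readout_s, dark_s = dark_s),
    repeats = n_frames)
}

#' Interlaced time-lapse microscopy (ITM)
#'
#' Short frames interlaced with alternating short (0.2 s) and long (4 s) dark
#' times. Molecules surviving at least two long dark times are classified as
#' long bound, molecules surviving a short dark time only as short bound.
#'
#' @param n_cycles Number of (short dark, long dark) cycles.
#' @param exposure_s,readout_s Frame exposure and readout (s).
#' @param short_dark_s,long_dark_s The two alternating dark times (s).
#' @export
itm_scheme <- function(n_cycles = 50L, exposure_s = 0.010, readout_s = 0.0017,
                       short_dark_s = 0.2, long_dark_s = 4) {
  if (short_dark_s >= long_dark_s) {
    stop("short_dark_s must be smaller than long_dark_s")
  }
  illumination_scheme(
    "ITM",
    data.frame(exposure_s = exposure_s, readout_s = readout_s,
               dark_s = c(short_dark_s, long_dark_s),
               label = "probe"),
    repeats = n_cycles)
}

#' Time-lapse alternated with continuous intervals (TACO)
#'
#' Combines ITM-style probe frames (classifying tracks as short or long
#' bound) with bursts of 10 continuously illuminated frames during which the
#' mobility of the classified molecule is measured.
#'
#' The long variant uses two probe frames each followed by a long dark time
#' (track must survive both, > 8 s in total) before the analysis burst; the
#' short variant uses a single probe frame followed by a 0.2 s dark time.
#'
#' @param class `"long"` or `"short"` TACO variant.
#' @param n_cycles Number of full cycles.
#' @param exposure_s,readout_s Frame exposure and readout (s).
#' @param short_dark_s,long_dark_s Classification dark times (s).
#' @param burst_frames Number of continuous frames per analysis burst.
#' @export
taco_scheme <- function(class = c("long", "short"), n_cycles = 20L,
                        exposure_s = 0.010, readout_s = 0.0017,
                        short_dark_s = 0.2, long_dark_s = 4.1883,
                        burst_frames = 10L) {
  class <- match.arg(class)
  fc <- exposure_s + readout_s
  probe_dark <- if (class == "long") long_dark_s else short_dark_s
  n_probe <- if (class == "long") 2L else 1L
  cyc <- data.frame(
    exposure_s = exposure_s, readout_s = readout_s,
    dark_s = c(rep(probe_dark, n_probe), rep(0, burst_frames - 1L),
               long_dark_s),
    label = c(rep("probe", n_probe), rep("burst", burst_frames)))
  # the last burst frame is followed by a long dark time separating cycles
  illumination_scheme(sprintf("TACO_%s", class), cyc, repeats = n_cycles)
  }

#' Classify the dark time following each frame
#'
#' Dark times are grouped into the two ITM classes by duration: `"long"`
#' (>= `long_min`), `"short"` (in `[short_min, long_min)`), else `"none"`.
#'
#' @param dark_s Numeric vector of dark durations (s).
#' @param short_min,long_min Class boundaries (s).
#' @return Character vector of classes.
#' @export
dark_class <- function(dark_s, short_min = 0.05, long_min = 1) {
  out <- rep("none", length(dark_s))
  out[dark_s >= short_min & dark_s < long_min] <- "short"
  out[dark_s >= long_min] <- "long"
  out
}
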