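#' Fluorescence survival dataset of one time-lapse condition
#'
#' Container for the observed survival times of bound molecules recorded
#' under one illumination condition, together with the condition's
#' frame-to-frame cycle time and the per-frame loss probability (tracking
#' error + photobleaching) calibrated at tracking time.
#'
#' @param times Observed survival times (s); positive multiples of `cycle_s`.
#' @param cycle_s Frame-to-frame time of the condition (s).
#' @param p_loss Per-detected-frame loss probability (default 0.0025).
#' @param condition Label.
#' @param min_frames Minimum detections per event used when the dataset was
#'   built (default 3).
#' @return Object of class `survival_dataset`.
#' @export
survival_dataset <- function(times, cycle_s, p_loss = 0.0025,
                             condition = "condition", min_frames = 3L) {
  stopifnot(cycle_s > 0, all(times > 0))
  mult <- times / cycle_s
  if (any(abs(mult - round(mult)) > 1e-6)) {
    stop("survival times must be positive multiples of the cycle time")
  }
  structure(list(times = sort(times), cycle_s = cycle_s, p_loss = p_loss,
                 condition = condition, min_frames = as.integer(min_frames)),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("Survival dataset '%s': %d events, cycle %.4g s, p_loss %.4g\n",
              x$condition, length(x$times), x$cycle_s, x$p_loss))
  invisible(x)
}

#' Survival times from a track table
#'
#' Molecules are counted as bound if they are detected (confined by the
#' tracking radius) for at least `min_frames` frames; the survival time of an
#' event is `(detections - 1) * cycle`.
#'
#' @param tracks Track table of one condition.
#' @param scheme The condition's [illumination_scheme()]; the cycle time is
#'   the frame-to-frame interval (exposure + readout + dark).
#' @param min_frames Minimum detections (default 3).
#' @param p_loss Loss probability to record with the dataset.
#' @param condition Label.
#' @return A [survival_dataset()].
#' @export
survival_distribution <- function(tracks, scheme, min_frames = 3L,
                                  p_loss = 0.0025, condition = scheme$name) {
  cyc <- scheme$cycle[1, ]
  cycle_s <- cyc$exposure_s + cyc$readout_s + cyc$dark_s
  n_det <- table(tracks$track_id)
  n_det <- as.integer(n_det[n_det >= min_frames])
  survival_dataset(times = (n_det - 1) * cycle_s, cycle_s = cycle_s,
                   p_loss = p_loss, condition = condition,
                   min_frames = min_frames)
}

#' Grid of candidate dissociation rates
#'
#' Log-spaced rates covering slow specific binding to fast unspecific
#' binding; defaults to 200 rates on `[1e-3, 1e1]` 1/s (50 per decade).
#'
#' @param k_min,k_max Range (1/s).
#' @param per_decade Grid points per decade.
#' @return Numeric vector of rates.
#' @export
rate_grid <- function(k_min = 1e-3, k_max = 1e1, per_decade = 50) {
  stopifnot(k_min > 0, k_max > k_min)
  10^seq(log10(k_min), log10(k_max), by = 1 / per_decade)
}

# Empirical survival function of a dataset evaluated at log-spaced multiples
# of the cycle time. S(t) = P(T >= t | T >= t_min), so S at the first
# (conditioning) time is 1.
log_binned_survival <- function(ds, n_points = 50L) {
  tmin <- min(ds$times); tmax <- max(ds$times)
  mult <- unique(round(10^seq(log10(tmin / ds$cycle_s),
                              log10(tmax / ds$cycle_s),
                              length.out = n_points)))
  t_eval <- mult * ds$cycle_s
  t_eval <- t_eval[t_eval >= tmin & t_eval <= tmax]
  n <- length(ds$times)
  S <- vapply(t_eval, function(t) sum(ds$times >= t - 1e-9) / n, numeric(1))
  list(t = t_eval, S = S)
}

#' Invert survival distributions into a dissociation-rate spectrum
#'
#' Joint inversion of the fluorescence survival-time distributions of
#' several time-lapse conditions into event amplitudes on a fixed grid of
#' dissociation rates. The model for condition `c` with cycle time
#' \eqn{\Delta_c} is
#' \deqn{S_c(t) = \sum_i A^e_i \, e^{-k_i t} \, (1 - p_{loss})^{t/\Delta_c}}
#' so conditions with different dark times decouple photobleaching/tracking
#' loss (per detected frame) from dissociation (per unit time). Amplitudes
#' are obtained by nonnegative least squares on the stacked log-binned
#' empirical survival functions; because each empirical survival function is
#' conditioned on reaching its first observable time, a per-condition scale
#' factor is iterated alongside the NNLS solve. Conditions are weighted
#' equally.
#'
#' Rates whose decay is essentially complete before the first observable
#' frame of every condition are unidentifiable (their design columns are
#' near zero), so the NNLS solution is selected by a tiny damping term
#' (`damping`, default 1e-4): this is numerical stabilization of the
#' rank-deficient inversion, not spectral smoothing — identifiable
#' amplitudes are unaffected at this magnitude.
#'
#' @param datasets List of [survival_dataset()] objects (>= 2 conditions with
#'   distinct dark times recommended; a single condition warns, since
#'   bleaching and dissociation are then unidentifiable).
#' @param grid Rate grid from [rate_grid()].
#' @param n_points Log-spaced evaluation points per condition.
#' @param max_iter,tol Scale-iteration controls.
#' @param damping Minimum-norm selection weight for unidentifiable
#'   amplitudes.
#' @return Object of class `rate_spectrum` with `rates`, normalized event
#'   amplitudes `event`, state amplitudes `state` (see
#'   [to_state_spectrum()]), and the fit residual.
#' @export
invert_spectrum <- function(datasets, grid = rate_grid(), n_points = 50L,
                            max_iter = 50L, tol = 1e-10, damping = 1e-4) {
  if (inherits(datasets, "survival_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1,
            all(vapply(datasets, inherits, logical(1), "survival_dataset")))
  if (length(unique(vapply(datasets, `[[`, numeric(1), "cycle_s"))) < 2) {
    warning("single time-lapse condition: photobleaching and dissociation ",
            "are not identifiable")
  }
  if (any(grid <= 0)) stop("rate grid must be strictly positive")

  emp <- lapply(datasets, log_binned_survival, n_points = n_points)
  X_blocks <- vector("list", length(datasets))
  w <- numeric(0); cond_id <- integer(0)
  for (c in seq_along(datasets)) {
    ds <- datasets[[c]]
    t <- emp[[c]]$t
    decay <- outer(t, grid, function(t, k) exp(-k * t)) *
      (1 - ds$p_loss)^(t / ds$cycle_s)
    X_blocks[[c]] <- decay
    w <- c(w, rep(1 / sqrt(length(t)), length(t)))  # equal condition weight
    cond_id <- c(cond_id, rep(c, length(t)))
  }
  X <- do.call(rbind, X_blocks)
  S_emp <- unlist(lapply(emp, `[[`, "S"))
  t1_idx <- vapply(seq_along(datasets), function(c) min(which(cond_id == c)),
                   integer(1))

  # iterate the per-condition conditioning scale s_c = model value at the
  # first observable time, solving NNLS for the amplitudes at each pass
  A <- rep(1 / length(grid), length(grid))
  res <- Inf
  Xd <- rbind(X * w, diag(damping, length(grid)))
  pad <- numeric(length(grid))
  for (it in seq_len(max_iter)) {
    s_c <- as.numeric(X[t1_idx, , drop = FALSE] %*% A)
    if (any(s_c <= 0)) s_c[s_c <= 0] <- 1e-12
    y <- S_emp * s_c[cond_id]
    sol <- pracma::lsqnonneg(Xd, c(y * w, pad))
    A_new <- sol$x
    if (sum(A_new) <= 0) stop("spectrum inversion failed: all-zero amplitudes")
    delta <- sum((A_new - A)^2)
    A <- A_new
    res <- sum(((X %*% A - y) * w)^2)   # undamped weighted residual
    if (delta < tol) break
  }

  event <- A / sum(A)
  spec <- structure(list(rates = grid, event = event, state = NULL,
                         event_sd = NULL, state_sd = NULL,
                         residual = res, n_events = vapply(
                           datasets, function(d) length(d$times), numeric(1))),
                    class = "rate_spectrum")
  spec$state <- to_state_spectrum(spec)$state
  spec
}

#' @export
print.rate_spectrum <- function(x, ...) {
  cat(sprintf("Dissociation-rate spectrum on %d grid rates [%.3g, %.3g] 1/s\n",
              length(x$rates), min(x$rates), max(x$rates)))
  nz <- which(x$event > 1e-6)
  cat(sprintf("  %d non-zero event amplitudes; residual %.4g\n",
              length(nz), x$residual))
  invisible(x)
}

#' Convert an event spectrum to a state spectrum
#'
#' Event amplitudes count binding events per unit time; state amplitudes
#' count molecules bound at a snapshot. The conversion divides each event
#' amplitude by its dissociation rate and renormalizes:
#' \eqn{A^s_i = (A^e_i / k_i) / \sum_j (A^e_j / k_j)}.
#'
#' @param spec A `rate_spectrum` with event amplitudes.
#' @return The spectrum with `state` filled in.
#' @export
to_state_spectrum <- function(spec) {
  stopifnot(inherits(spec, "rate_spectrum"))
  if (any(spec$rates <= 0)) stop("invalid grid: zero rate")
  s <- spec$event / spec$rates
  spec$state <- s / sum(s)
  spec
}

#' Convert a state spectrum back to an event spectrum
#'
#' Inverse of [to_state_spectrum()]: multiply state amplitudes by their rate
#' and renormalize.
#'
#' @param spec A `rate_spectrum` with state amplitudes.
#' @return The spectrum with `event` recomputed from `state`.
#' @export
to_event_spectrum <- function(spec) {
  stopifnot(inherits(spec, "rate_spectrum"), !is.null(spec$state))
  e <- spec$state * spec$rates
  spec$event <- e / sum(e)
  spec
}

#' Residence-time summary of a rate spectrum
#'
#' Splits the spectrum at a threshold dissociation rate (default 0.1 1/s,
#' separating long/specific from short/unspecific binding): the specific
#' dissociation rate `k_off_s` is the amplitude-weighted mean of all grid
#' rates below the threshold and the specific residence time is its inverse
#' (`tau_s = 1/k_off_s`); analogously `k_off_u`, `tau_u` above the
#' threshold. Summed event and state masses on each side are reported.
#'
#' @param spec A `rate_spectrum`.
#' @param threshold Split rate (1/s), default 0.1.
#' @param weights Which amplitudes weight the rate average: `"state"`
#'   (default), `"event"`, or `"none"` (unweighted mean of supported rates).
#' @return Object of class `residence_summary`. Sides without spectral mass
#'   are reported as `NA` and flagged in `empty_side`.
#' @export
summarize_residence <- function(spec, threshold = 0.1,
                                weights = c("state", "event", "none")) {
  stopifnot(inherits(spec, "rate_spectrum"))
  weights <- match.arg(weights)
  if (is.null(spec$state)) spec <- to_state_spectrum(spec)
  wvec <- switch(weights,
                 state = spec$state,
                 event = spec$event,
                 none = as.numeric(spec$event > 0))
  lo <- spec$rates < threshold
  avg <- function(side) {
    if (sum(wvec[side]) <= 0) return(NA_real_)
    sum(wvec[side] * spec$rates[side]) / sum(wvec[side])
  }
  k_s <- avg(lo); k_u <- avg(!lo)
  structure(list(threshold = threshold, weights = weights,
                 k_off_s = k_s, k_off_u = k_u,
                 tau_s = 1 / k_s, tau_u = 1 / k_u,
                 A_event_s = sum(spec$event[lo]),
                 A_event_u = sum(spec$event[!lo]),
                 A_state_s = sum(spec$state[lo]),
                 A_state_u = sum(spec$state[!lo]),
                 empty_side = c(below = sum(wvec[lo]) <= 0,
                                above = sum(wvec[!lo]) <= 0)),
            class = "residence_summary")
}

#' @export
print.residence_summary <- function(x, ...) {
  cat(sprintf("Residence summary (threshold %.3g 1/s, %s-weighted):\n",
              x$threshold, x$weights))
  cat(sprintf("  specific:   k_off = %.4g 1/s, tau = %.4g s, state mass %.3f\n",
              x$k_off_s, x$tau_s, x$A_state_s))
  cat(sprintf("  unspecific: k_off = %.4g 1/s, tau = %.4g s, state mass %.3f\n",
              x$k_off_u, x$tau_u, x$A_state_u))
  invisible(x)
}

#' Resampling errors of a rate spectrum
#'
#' Standard deviation of every event and state amplitude over repeated
#' inversions of random subsets of the survival times (defaults: 500
#' resamplings of 80% of the events in each condition).
#'
#' @param datasets List of [survival_dataset()] objects.
#' @param grid Rate grid.
#' @param n_resamples Number of resampling rounds (default 500).
#' @param frac Fraction of events per subset (default 0.8).
#' @param seed Integer seed.
#' @param ... Passed on to [invert_spectrum()].
#' @return List with `event_sd`, `state_sd` and the resampled amplitude
#'   matrices.
#' @export
resample_spectrum <- function(datasets, grid = rate_grid(),
                              n_resamples = 500L, frac = 0.8, seed = 1L, ...) {
  if (inherits(datasets, "survival_dataset")) datasets <- list(datasets)
  set.seed(seed)
  ne <- length(grid)
  ev <- matrix(NA_real_, n_resamples, ne)
  st <- matrix(NA_real_, n_resamples, ne)
  for (b in seq_len(n_resamples)) {
    sub <- lapply(datasets, function(ds) {
      m <- max(1L, round(frac * length(ds$times)))
      survival_dataset(ds$times[sample.int(length(ds$times), m)],
                       ds$cycle_s, ds$p_loss, ds$condition, ds$min_frames)
    })
    spec <- try(suppressWarnings(invert_spectrum(sub, grid, ...)),
                silent = TRUE)
    if (inherits(spec, "try-error")) next
    ev[b, ] <- spec$event
    st[b, ] <- spec$state
  }
  keep <- stats::complete.cases(ev)
  list(event_sd = apply(ev[keep, , drop = FALSE], 2, stats::sd),
       state_sd = apply(st[keep, , drop = FALSE], 2, stats::sd),
       event = ev[keep, , drop = FALSE], state = st[keep, , drop = FALSE])
}
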