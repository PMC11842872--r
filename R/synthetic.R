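#' Ground-truth parameter set for synthetic movies
#'
#' Collects the parameters of the generative model that emulates the imaging
#' experiments: a mixture of Brownian diffusion components (the slowest
#' component is the apparent motion of chromatin-bound molecules; localization
#' error is folded into its coefficient), a three-state binding model
#' (free <-> short-bound, free <-> long-bound) with exponential waiting times,
#' a combined per-detected-frame Bernoulli loss (photobleaching plus tracking
#' loss), and a circular nuclear boundary with optional radially structured
#' binding-site density.
#'
#' @param diffusion_components Data frame with columns `fraction` and
#'   `D_um2_s`, slowest component first; fractions must sum to 1. The slow
#'   component's fraction is the stationary bound fraction implied by the
#'   binding rates when a movie is simulated.
#' @param k_on_u,k_on_s Pseudo-first-order association rates (1/s) into the
#'   unspecific (short) and specific (long) bound states.
#' @param k_off_u,k_off_s Dissociation rates (1/s) out of the two states.
#' @param loc_error_um Isotropic localization error s.d. (µm) added to every
#'   detection.
#' @param per_frame_loss Probability that a detection is lost per detected
#'   frame (photobleach + mislink combined), in `[0, 1)`.
#' @param nucleus_radius_um Radius of the (circular) nucleus (µm).
#' @param radial_bias Optional function mapping CBD in `[0, 1]` to relative
#'   binding density (used by [radial_place()]).
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(diffusion_components =
                           data.frame(fraction = c(0.15, 0.35, 0.50),
                                      D_um2_s = c(0.01, 0.3, 2.5)),
                         k_on_u = 0.02, k_on_s = 0.005,
                         k_off_u = 1, k_off_s = 0.01,
                         loc_error_um = 0.03, per_frame_loss = 0.0025,
                         nucleus_radius_um = 5, radial_bias = NULL) {
  stopifnot(is.data.frame(diffusion_components),
            all(c("fraction", "D_um2_s") %in% names(diffusion_components)))
  if (abs(sum(diffusion_components$fraction) - 1) > 1e-8) {
    stop("diffusion component fractions must sum to 1")
  }
  rates <- c(k_on_u = k_on_u, k_on_s = k_on_s,
             k_off_u = k_off_u, k_off_s = k_off_s)
  if (any(rates <= 0)) stop("all rates must be > 0")
  if (per_frame_loss < 0 || per_frame_loss >= 1) {
    stop("per_frame_loss must be in [0, 1)")
  }
  if (any(diffusion_components$D_um2_s <= 0)) stop("all D must be > 0")
  structure(list(diffusion_components = diffusion_components,
                 k_on_u = k_on_u, k_on_s = k_on_s,
                 k_off_u = k_off_u, k_off_s = k_off_s,
                 loc_error_um = loc_error_um,
                 per_frame_loss = per_frame_loss,
                 nucleus_radius_um = nucleus_radius_um,
                 radial_bias = radial_bias),
            class = "ground_truth")
}

#' Stationary state probabilities of the binding model
#'
#' Probabilities of the free, short-bound and long-bound states of the
#' three-state chain at equilibrium.
#'
#' @param truth A [ground_truth()].
#' @return Named numeric vector `c(free, short, long)` summing to 1.
#' @export
stationary_fractions <- function(truth) {
  w <- c(free = 1,
         short = truth$k_on_u / truth$k_off_u,
         long = truth$k_on_s / truth$k_off_s)
  w / sum(w)
}

# Sample one continuous-time trajectory of the 3-state chain on [0, t_end].
# Returns step-function data: switch times and the state entered at each.
sim_state_path <- function(truth, t_end) {
  p0 <- stationary_fractions(truth)
  state <- sample.int(3L, 1L, prob = p0)  # 1 free, 2 short, 3 long
  times <- 0; states <- state; t <- 0
  while (t < t_end) {
    if (state == 1L) {
      rate <- truth$k_on_u + truth$k_on_s
      t <- t + stats::rexp(1, rate)
      state <- if (stats::runif(1) < truth$k_on_u / rate) 2L else 3L
    } else if (state == 2L) {
      t <- t + stats::rexp(1, truth$k_off_u)
      state <- 1L
    } else {
      t <- t + stats::rexp(1, truth$k_off_s)
      state <- 1L
    }
    times <- c(times, t); states <- c(states, state)
  }
  list(times = times, states = states)
}

state_at <- function(path, t) {
  path$states[findInterval(t, path$times)]
}

# integral of the state-dependent diffusion coefficient over [a, b]:
# the variance of the displacement over an interval spanning state switches
# is additive over the piecewise-Brownian segments
integrate_D <- function(path, a, b, D_states) {
  idx <- which(path$times > a & path$times < b)
  ts <- c(a, path$times[idx], b)
  st <- path$states[findInterval(ts[-length(ts)], path$times)]
  sum(D_states[st] * diff(ts))
}

#' Simulate a single-molecule movie under an illumination scheme
#'
#' Molecules switch between free, short-bound and long-bound states with
#' exponential waiting times, diffuse with the state's diffusion coefficient
#' (free molecules use a mobile component assigned per molecule from the
#' mixture; bound molecules use the slow component), are confined to the
#' nuclear disk by reflection, and are detected during every exposure frame
#' subject to localization noise and an independent per-frame loss.
#'
#' @param truth A [ground_truth()].
#' @param scheme An [illumination_scheme()]; the movie covers all its frames.
#' @param n_molecules Number of molecules.
#' @param seed Integer seed; all randomness derives from it.
#' @return Object of class `simulated_movie`: a data frame of detections with
#'   columns `molecule`, `frame`, `t_s`, `x_um`, `y_um`, `state`
#'   (`"free"`, `"short"`, `"long"`; ground-truth label at the frame time),
#'   with the scheme and seed stored as attributes.
#' @export
simulate_movie <- function(truth, scheme, n_molecules, seed) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(scheme, "illumination_scheme"))
  ft <- frame_table(scheme)
  if (nrow(ft) < 2) stop("scheme must cover at least 2 frames")
  set.seed(seed)
  rates <- c(truth$k_on_u + truth$k_on_s, truth$k_off_u, truth$k_off_s)
  if (any(rates * max(ft$exposure_s) > 1)) {
    warning("binding rates imply > 1 expected transition per exposure; ",
            "state labels are discretized at frame times")
  }
  t_end <- max(ft$t_s) + ft$exposure_s[nrow(ft)]
  R <- truth$nucleus_radius_um
  comp <- truth$diffusion_components
  D_bound <- comp$D_um2_s[1]
  mobile <- comp[-1, , drop = FALSE]
  state_names <- c("free", "short", "long")

  out <- vector("list", n_molecules)
  for (m in seq_len(n_molecules)) {
    path <- sim_state_path(truth, t_end)
    D_free <- if (nrow(mobile)) {
      mobile$D_um2_s[sample.int(nrow(mobile), 1L, prob = mobile$fraction)]
    } else D_bound
    # initial position uniform in the disk
    repeat {
      p <- stats::runif(2, -R, R)
      if (sum(p^2) <= R^2) break
    }
    st <- state_at(path, ft$t_s)
    n <- nrow(ft)
    xs <- numeric(n); ys <- numeric(n)
    xs[1] <- p[1]; ys[1] <- p[2]
    D_states <- c(D_free, D_bound, D_bound)
    sd_step <- vapply(seq_len(n - 1), function(k)
      sqrt(2 * integrate_D(path, ft$t_s[k], ft$t_s[k + 1], D_states)),
      numeric(1))
    dx <- stats::rnorm(n - 1, 0, sd_step)
    dy <- stats::rnorm(n - 1, 0, sd_step)
    for (k in 2:n) {
      q <- c(xs[k - 1] + dx[k - 1], ys[k - 1] + dy[k - 1])
      r <- sqrt(sum(q^2))
      if (r > R) q <- q * (2 * R - r) / r  # radial reflection at the envelope
      xs[k] <- q[1]; ys[k] <- q[2]
    }
    detected <- stats::runif(n) >= truth$per_frame_loss
    if (!any(detected)) next
    out[[m]] <- data.frame(
      molecule = m, frame = ft$frame[detected], t_s = ft$t_s[detected],
      x_um = xs[detected] + stats::rnorm(sum(detected), 0, truth$loc_error_um),
      y_um = ys[detected] + stats::rnorm(sum(detected), 0, truth$loc_error_um),
      state = state_names[st[detected]])
  }
  det <- do.call(rbind, out)
  rownames(det) <- NULL
  structure(det, class = c("simulated_movie", "data.frame"),
            scheme = scheme, seed = seed, truth = truth)
}

#' Ground-truth tracks of a simulated movie
#'
#' Uses the molecule identity as the track id, bypassing the tracker; useful
#' for testing classification and kinetics without linking errors.
#'
#' @param movie A [simulate_movie()] result.
#' @return Track table with columns `track_id`, `frame`, `t_s`, `x_um`,
#'   `y_um`, `state`.
#' @export
as_tracks <- function(movie) {
  stopifnot(inherits(movie, "simulated_movie"))
  out <- as.data.frame(movie)
  names(out)[names(out) == "molecule"] <- "track_id"
  out
}

#' Sample jump distances from a Brownian mixture
#'
#' Draws single-frame jump distances directly from the closed-form mixture
#' used by [fit_mixture()]: each jump picks a component by its fraction and
#' has squared displacement Exp(mean `4 D dt`) (2D Brownian step).
#'
#' @param components Data frame with `fraction`, `D_um2_s`.
#' @param n Number of jumps.
#' @param dt Frame interval (s).
#' @param seed Integer seed.
#' @return Numeric vector of jump distances (µm).
#' @export
simulate_jumps <- function(components, n, dt, seed) {
  stopifnot(abs(sum(components$fraction) - 1) < 1e-8)
  set.seed(seed)
  comp <- sample.int(nrow(components), n, replace = TRUE,
                     prob = components$fraction)
  sqrt(stats::rexp(n, rate = 1 / (4 * components$D_um2_s[comp] * dt)))
}

#' Simulate observed fluorescence survival times for one time-lapse condition
#'
#' Binding events draw a true dwell time from an exponential mixture of
#' dissociation rates; a molecule bound for `d` seconds is detectable in
#' `floor(d / cycle) + 1` consecutive frames, each detection additionally
#' survives photobleaching/tracking loss with probability `1 - p_loss`, and
#' events observed for fewer than `min_frames` frames are discarded (they are
#' not distinguishable from diffusing molecules).
#'
#' @param rates Dissociation rates (1/s) of the mixture.
#' @param weights Event weights (will be normalized).
#' @param n_events Number of binding events to generate.
#' @param cycle_s Frame-to-frame time of the condition (s), i.e. frame cycle
#'   plus dark time.
#' @param p_loss Per-detected-frame loss probability.
#' @param min_frames Minimum detections for an event to be scored (default 3).
#' @param seed Integer seed.
#' @param condition Label for the dataset.
#' @return A [survival_dataset()].
#' @export
simulate_survival_times <- function(rates, weights, n_events, cycle_s,
                                    p_loss = 0.0025, min_frames = 3L, seed = 1L,
                                    condition = sprintf("tl_%.4gs", cycle_s)) {
  stopifnot(length(rates) == length(weights), all(rates > 0))
  set.seed(seed)
  w <- weights / sum(weights)
  k <- sample(rates, n_events, replace = TRUE, prob = w)
  dwell <- stats::rexp(n_events, rate = k)
  n_det <- floor(dwell / cycle_s) + 1
  if (p_loss > 0) {
    # number of consecutive detections until the first loss (>= 1)
    lifespan <- stats::rgeom(n_events, p_loss) + 1
    n_det <- pmin(n_det, lifespan)
  }
  keep <- n_det >= min_frames
  survival_dataset(times = (n_det[keep] - 1) * cycle_s, cycle_s = cycle_s,
                   p_loss = p_loss, condition = condition,
                   min_frames = min_frames)
}

#' Place binding events with a radial density bias inside the unit nucleus
#'
#' Events are placed at center-border distance (CBD) `u` with density
#' proportional to `bias(u) * u` (the factor `u` is the ring-circumference
#' area element of the disk), with uniform angle.
#'
#' @param truth A [ground_truth()] whose `radial_bias` is used, or `NULL` for
#'   a uniform density.
#' @param n Number of events.
#' @param seed Integer seed.
#' @param bias Optional function overriding `truth$radial_bias`.
#' @return Data frame with columns `x`, `y` (units of the nucleus radius) and
#'   `cbd`.
#' @export
radial_place <- function(truth = NULL, n, seed, bias = NULL) {
  if (is.null(bias)) {
    bias <- if (!is.null(truth)) truth$radial_bias else NULL
  }
  if (is.null(bias)) bias <- function(u) rep(1, length(u))
  set.seed(seed)
  grid <- seq(0, 1, length.out = 2048)
  dens <- bias(grid) * grid
  if (any(!is.finite(dens)) || any(dens < 0)) {
    stop("radial_bias must be finite and non-negative on [0, 1]")
  }
  cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]
  # invert the CDF on the grid (strictly increasing where density > 0)
  u <- stats::approx(x = cdf, y = grid, xout = stats::runif(n), rule = 2,
                     ties = "ordered")$y
  theta <- stats::runif(n, 0, 2 * pi)
  R <- if (!is.null(truth)) truth$nucleus_radius_um else 1
  data.frame(x = R * u * cos(theta), y = R * u * sin(theta), cbd = u)
}
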