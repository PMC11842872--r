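#' Bin jump distances into a cumulative distribution
#'
#' Builds the empirical cumulative distribution of jump distances on a fixed
#' grid of bin edges (default 1 nm bins, 747 bins). Jumps beyond the last
#' edge contribute to the normalization but not to the fitted range, so the
#' last CDF value may be below 1 for fast-diffusing samples.
#'
#' @param jumps Jump distances (µm).
#' @param bin_width Bin width (µm), default 0.001 (1 nm).
#' @param n_bins Number of bins, default 747.
#' @return List with `r` (bin edges, µm) and `cdf` (empirical CDF values).
#' @export
jump_cdf <- function(jumps, bin_width = 0.001, n_bins = 747L) {
  stopifnot(length(jumps) > 0, all(jumps >= 0))
  r <- seq_len(n_bins) * bin_width
  s <- sort(jumps)
  list(r = r, cdf = findInterval(r, s) / length(s))
}

mixture_cdf <- function(r, A, D, dt) {
  out <- numeric(length(r))
  for (i in seq_along(A)) {
    out <- out + A[i] * (1 - exp(-r^2 / (4 * D[i] * dt)))
  }
  out
}

# map unconstrained parameters to (A, D); amplitudes via stick-breaking
# logits so that sum(A) = 1 by construction, D via log
par_to_AD <- function(par, k) {
  if (k == 2) {
    a1 <- stats::plogis(par[1])
    A <- c(a1, 1 - a1)
    D <- exp(par[2:3])
  } else {
    a1 <- stats::plogis(par[1])
    a2 <- (1 - a1) * stats::plogis(par[2])
    A <- c(a1, a2, 1 - a1 - a2)
    D <- exp(par[3:5])
  }
  list(A = A, D = D)
}

#' Fit a Brownian mixture to a cumulative jump-distance distribution
#'
#' Least-squares fit of
#' \deqn{CDF(r) = \sum_i A_i (1 - e^{-r^2 / (4 D_i \Delta t)})}
#' to the binned empirical CDF, with the sum-to-one constraint on the
#' amplitudes enforced by the parameterization. The slowest component's
#' amplitude \eqn{A_1} is the overall bound fraction of the tracked
#' molecules; localization error is not modelled separately but absorbed
#' into \eqn{D_1}. The fit is restarted from several deterministic
#' initializations and the best residual sum of squares is kept.
#'
#' @param jumps Jump distances (µm).
#' @param dt Frame interval (s).
#' @param n_components 2 or 3.
#' @param bin_width,n_bins Binning of the empirical CDF (see [jump_cdf()]).
#' @param n_starts Number of deterministic multistart initializations (>= 5
#'   recommended).
#' @return Object of class `diffusion_fit` with elements `A` (ascending-D
#'   order, sums to 1), `D` (µm²/s, ascending), `RSS`, `n_components`,
#'   `n_bins`, `dt`, and the fitted curve.
#' @export
fit_mixture <- function(jumps, dt, n_components = 3L, bin_width = 0.001,
                        n_bins = 747L, n_starts = 5L) {
  stopifnot(dt > 0, n_components %in% c(2L, 3L))
  if (length(unique(jumps)) < 2) {
    stop("degenerate data: all jump distances identical")
  }
  h <- jump_cdf(jumps, bin_width, n_bins)
  k <- as.integer(n_components)

  obj <- function(par) {
    ad <- par_to_AD(par, k)
    sum((h$cdf - mixture_cdf(h$r, ad$A, ad$D, dt))^2)
  }

  # deterministic multistart: spread diffusion coefficients over decades
  base_D <- list(c(0.005, 0.5), c(0.02, 2), c(0.05, 5), c(0.002, 0.2),
                 c(0.01, 1),
                 c(0.005, 0.1, 1), c(0.01, 0.3, 2.5), c(0.02, 0.5, 5),
                 c(0.002, 0.05, 0.8), c(0.05, 1, 8))
  starts <- Filter(function(d) length(d) == k, base_D)
  starts <- starts[seq_len(min(length(starts), max(n_starts, 1L)))]

  best <- NULL
  for (D0 in starts) {
    par0 <- if (k == 2) c(0, log(D0)) else c(stats::qlogis(1 / 3), 0, log(D0))
    fit <- try(stats::optim(par0, obj, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("mixture fit failed from all starts")

  ad <- par_to_AD(best$par, k)
  ord <- order(ad$D)
  A <- ad$A[ord]; D <- ad$D[ord]
  structure(list(n_components = k, A = A, D = D, RSS = best$value,
                 n_bins = as.integer(n_bins), bin_width = bin_width, dt = dt,
                 r = h$r, cdf = h$cdf,
                 fitted = mixture_cdf(h$r, A, D, dt)),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("%d-component Brownian mixture fit (%d bins, dt = %.4g s)\n",
              x$n_components, x$n_bins, x$dt))
  for (i in seq_len(x$n_components)) {
    cat(sprintf("  A%d = %.3f   D%d = %.4g um^2/s\n", i, x$A[i], i, x$D[i]))
  }
  cat(sprintf("  RSS = %.4g; bound fraction f_b = A1 = %.3f\n", x$RSS, x$A[1]))
  invisible(x)
}

#' Bound fraction from a diffusion fit
#'
#' The amplitude of the slowest diffusion component, representing immobile,
#' chromatin-bound molecules.
#'
#' @param fit A [fit_mixture()] result.
#' @return The bound fraction `f_b = A1`.
#' @export
bound_fraction <- function(fit) {
  stopifnot(inherits(fit, "diffusion_fit"))
  fit$A[1]
}

#' Compare 2- and 3-component diffusion models by AIC difference
#'
#' \deqn{\Delta AIC = (2 k_{2} + n \ln RSS_{2}) - (2 k_{3} + n \ln RSS_{3})}
#' with parameter counts \eqn{k_2 = 3} and \eqn{k_3 = 5} (free parameters
#' after the sum-to-one amplitude constraint) and `n` the number of CDF bins.
#' A positive value prefers the three-component model.
#'
#' @param fit2,fit3 [fit_mixture()] results computed on the same binned data.
#' @param n Bin count (defaults to the fits' shared bin count).
#' @return Object of class `model_comparison` with `delta_AIC`,
#'   `preferred` (2 or 3) and the ingredients.
#' @export
compare_models <- function(fit2, fit3, n = NULL) {
  stopifnot(inherits(fit2, "diffusion_fit"), inherits(fit3, "diffusion_fit"),
            fit2$n_components == 2L, fit3$n_components == 3L)
  if (is.null(n)) {
    if (fit2$n_bins != fit3$n_bins) stop("fits use different binnings")
    n <- fit2$n_bins
  }
  if (fit2$RSS <= 0 || fit3$RSS <= 0) stop("RSS must be positive")
  k2 <- 2L * 2L - 1L  # A1 + (D1, D2)
  k3 <- 2L * 3L - 1L  # A1, A2 + (D1, D2, D3)
  delta <- (2 * k2 + n * log(fit2$RSS)) - (2 * k3 + n * log(fit3$RSS))
  structure(list(k_2rate = k2, k_3rate = k3, n = n,
                 RSS_2rate = fit2$RSS, RSS_3rate = fit3$RSS,
                 delta_AIC = delta, preferred = if (delta > 0) 3L else 2L),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Delta AIC = %.2f -> %d-component model preferred\n",
              x$delta_AIC, x$preferred))
  invisible(x)
}

#' Resampling errors of diffusion-fit parameters
#'
#' Standard deviation of each amplitude and diffusion coefficient over refits
#' on random subsets of the jump distances (defaults: 500 resamplings of 80%
#' of the jumps).
#'
#' @param jumps Jump distances (µm).
#' @param dt Frame interval (s).
#' @param n_components 2 or 3.
#' @param n_resamples Number of resampling rounds (default 500).
#' @param frac Fraction of jumps per subset (default 0.8).
#' @param seed Integer seed.
#' @param ... Passed on to [fit_mixture()].
#' @return List with `A_sd`, `D_sd` (per-parameter s.d.) and the matrix of
#'   resampled estimates.
#' @export
resample_errors <- function(jumps, dt, n_components = 3L, n_resamples = 500L,
                            frac = 0.8, seed = 1L, ...) {
  stopifnot(n_resamples >= 2)
  set.seed(seed)
  m <- max(1L, round(frac * length(jumps)))
  k <- as.integer(n_components)
  est <- matrix(NA_real_, n_resamples, 2L * k)
  for (b in seq_len(n_resamples)) {
    sub <- jumps[sample.int(length(jumps), m)]
    fit <- try(fit_mixture(sub, dt, k, ...), silent = TRUE)
    if (inherits(fit, "try-error")) next
    est[b, ] <- c(fit$A, fit$D)
  }
  est <- est[stats::complete.cases(est), , drop = FALSE]
  sds <- apply(est, 2, stats::sd)
  list(A_sd = sds[seq_len(k)], D_sd = sds[k + seq_len(k)], estimates = est)
}
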