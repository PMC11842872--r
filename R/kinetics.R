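#' Equilibrium two-class binding model
#'
#' Chromatin-binding proteins such as cohesin and CTCF bind unspecific
#' (short-lived) and specific (long-lived) sites. At equilibrium the law of
#' mass action relates, for each class `i`, the measured free and bound
#' fractions to the kinetic rates via
#' \eqn{k_{off,i} / k^*_{on,i} = p_f / p_{b,i}}, where the pseudo-first-order
#' association rate \eqn{k^*_{on,i} = k_{on,i} [D_i]} absorbs the (never
#' materialized) free-site concentration. All functions below work purely
#' with measured fractions and rates.
#'
#' @name kinetic_model
NULL

#' Pseudo-first-order association rate from measured fractions
#'
#' \eqn{k^*_{on} = k_{off} \; p_b / p_f}.
#'
#' @param k_off Dissociation rate (1/s).
#' @param p_b Bound fraction of the class.
#' @param p_f Free fraction.
#' @return Association pseudo-rate (1/s).
#' @examples
#' pseudo_on_rate(0.01, 0.1, 0.5)  # 0.002
#' @export
pseudo_on_rate <- function(k_off, p_b, p_f) {
  if (any(p_f <= 0)) stop("p_f must be > 0")
  k_off * p_b / p_f
}

#' Target-search time under facilitated diffusion
#'
#' A searching molecule makes \eqn{N_{trials} = 1 / A^e_s} unspecific
#' encounters before hitting a specific site (with \eqn{A^e_s} the event
#' fraction of specific binding), so the mean search time is
#' \deqn{\tau_{search} = N_{trials} / k^*_{on,u} + (N_{trials} - 1) / k_{off,u}.}
#'
#' @param A_event_s Event-spectrum fraction of specific (long) binding,
#'   in `(0, 1]`.
#' @param k_on_u Unspecific association pseudo-rate (1/s), see
#'   [pseudo_on_rate()].
#' @param k_off_u Unspecific dissociation rate (1/s).
#' @return List with `N_trials` and `tau_search` (s). `A_event_s = 0` gives
#'   an infinite search time (flagged by `Inf`).
#' @examples
#' search_time_facilitated(0.5, 0.1, 1)$tau_search  # 21
#' @export
search_time_facilitated <- function(A_event_s, k_on_u, k_off_u) {
  if (A_event_s < 0 || A_event_s > 1) stop("A_event_s must be in [0, 1]")
  if (A_event_s == 0) {
    return(list(N_trials = Inf, tau_search = Inf))
  }
  N <- 1 / A_event_s
  list(N_trials = N, tau_search = N / k_on_u + (N - 1) / k_off_u)
}

#' Direct search time from the specific-binding equilibrium
#'
#' When the association pseudo-rate of the specific class is computed
#' directly from the measured fractions, the search time is its inverse:
#' \eqn{\tau_{search} = 1 / k^*_{on,s} = p_f / (k_{off,s} \; p_{b,s})}.
#'
#' @param k_off_s Specific dissociation rate (1/s).
#' @param p_b_s Specific (long) bound fraction.
#' @param p_f Free fraction.
#' @return Search time (s).
#' @examples
#' search_time_direct(0.01, 0.1, 0.5)  # 500
#' @export
search_time_direct <- function(k_off_s, p_b_s, p_f) {
  1 / pseudo_on_rate(k_off_s, p_b_s, p_f)
}

#' Relative effective search time
#'
#' Accounts for changing molecule numbers and nuclear volume between
#' developmental stages: \eqn{\tau_{eff} = \tau_{search} V_{nuc} / N_{mol}},
#' normalized to a reference stage so that only relative molecule counts and
#' volumes are needed.
#'
#' @param tau_search Search time (s).
#' @param v_nuc Nuclear volume (µm³ or relative units).
#' @param n_mol Relative molecule count.
#' @param tau_ref,v_ref,n_ref Same quantities for the reference stage.
#' @return Effective search time relative to the reference stage.
#' @export
effective_search_time <- function(tau_search, v_nuc, n_mol,
                                  tau_ref = tau_search, v_ref = v_nuc,
                                  n_ref = n_mol) {
  stopifnot(v_nuc > 0, n_mol > 0, v_ref > 0, n_ref > 0)
  (tau_search * v_nuc / n_mol) / (tau_ref * v_ref / n_ref)
}

#' Nuclear volume from a cross-sectional area
#'
#' Assumes a spherical nucleus whose largest cross-section has the given
#' area: \eqn{r = \sqrt{area/\pi}}, \eqn{V = \frac{4}{3}\pi r^3}.
#'
#' @param area_um2 Cross-sectional area (µm²).
#' @return Volume (µm³).
#' @examples
#' nuclear_volume_from_cross_section(pi)  # 4*pi/3
#' @export
nuclear_volume_from_cross_section <- function(area_um2) {
  stopifnot(all(area_um2 > 0))
  r <- sqrt(area_um2 / pi)
  (4 / 3) * pi * r^3
}

#' Predicted long-bound fraction from kinetic rates
#'
#' Mass-action prediction of the overall fraction of long-bound molecules
#' from the two classes' rates:
#' \deqn{p_{b,s} = \frac{k^*_{on,s}/k_{off,s}}
#'   {k^*_{on,s}/k_{off,s} + k^*_{on,u}/k_{off,u} + 1}.}
#'
#' @param k_on_s,k_off_s Specific association pseudo-rate and dissociation
#'   rate (1/s).
#' @param k_on_u,k_off_u Unspecific rates (1/s). `k_on_u = 0` reduces the
#'   model to a one-class Langmuir isotherm.
#' @return Predicted long-bound fraction.
#' @examples
#' predict_bound_fraction(1, 1, 1, 1)  # 1/3
#' @export
predict_bound_fraction <- function(k_on_s, k_off_s, k_on_u, k_off_u) {
  if (k_off_s <= 0 || k_off_u <= 0 || k_on_s < 0 || k_on_u < 0) {
    stop("rates must be positive (association rates may be zero)")
  }
  rs <- unname(k_on_s / k_off_s)
  ru <- unname(k_on_u / k_off_u)
  rs / (rs + ru + 1)
}

#' All three state fractions from kinetic rates
#'
#' Convenience companion to [predict_bound_fraction()]: free, unspecific-
#' and specific-bound fractions of the two-class equilibrium.
#'
#' @inheritParams predict_bound_fraction
#' @return Named vector `c(p_f, p_b_u, p_b_s)` summing to 1.
#' @export
predict_fractions <- function(k_on_s, k_off_s, k_on_u, k_off_u) {
  rs <- unname(k_on_s / k_off_s)
  ru <- unname(k_on_u / k_off_u)
  tot <- 1 + rs + ru
  c(p_f = 1 / tot, p_b_u = ru / tot, p_b_s = rs / tot)
}

#' First-order Gaussian error propagation
#'
#' Delta-method propagation of independent Gaussian uncertainties through an
#' arbitrary scalar function, using central-difference numerical partial
#' derivatives.
#'
#' @param f Function of a numeric vector.
#' @param values Parameter values.
#' @param sds Standard deviations (same length as `values`).
#' @param rel_h Relative step for the numerical derivatives.
#' @return List with `value` and `sd`.
#' @examples
#' propagate_gaussian(function(x) x[1] + x[2], c(1, 1), c(1, 1))$sd  # sqrt(2)
#' @export
propagate_gaussian <- function(f, values, sds, rel_h = 1e-6) {
  stopifnot(length(values) == length(sds), all(sds >= 0))
  g <- vapply(seq_along(values), function(i) {
    h <- max(rel_h, rel_h * abs(values[i]))
    up <- values; up[i] <- up[i] + h
    dn <- values; dn[i] <- dn[i] - h
    (f(up) - f(dn)) / (2 * h)
  }, numeric(1))
  list(value = f(values), sd = sqrt(sum((g * sds)^2)))
}
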