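# Reduced 3D bead-spring backend: overdamped Langevin dynamics of a chain
# with harmonic bonds and Lennard-Jones volume interactions. This is a
# desk-scale alternative to the effective-contour contact model for small
# systems; it is not meant to reproduce production-scale molecular dynamics.

lj_forces <- function(pos, eps, sigma, cutoff) {
  n <- nrow(pos)
  f <- matrix(0, n, 3)
  if (eps <= 0) return(f)
  # O(n^2) pair loop, vectorized per particle; adequate for n <= ~500
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    dr <- pos[j, , drop = FALSE] -
      matrix(pos[i, ], length(j), 3, byrow = TRUE)
    r2 <- rowSums(dr^2)
    sel <- r2 < cutoff^2 & r2 > 1e-12
    if (!any(sel)) next
    jj <- j[sel]; dr <- dr[sel, , drop = FALSE]; r2 <- r2[sel]
    sr6 <- (sigma^2 / r2)^3
    # f(r)/r for U = 4 eps (sr^12 - sr^6)
    fr <- 24 * eps * (2 * sr6^2 - sr6) / r2
    fv <- dr * fr
    f[jj, ] <- f[jj, ] + fv
    f[i, ] <- f[i, ] - colSums(fv)
  }
  f
}

bond_forces <- function(pos, bonds, k, b) {
  f <- matrix(0, nrow(pos), 3)
  if (nrow(bonds) == 0) return(f)
  dr <- pos[bonds[, 2], , drop = FALSE] - pos[bonds[, 1], , drop = FALSE]
  r <- sqrt(rowSums(dr^2))
  r[r < 1e-12] <- 1e-12
  mag <- -k * (r - b) / r          # restoring force along the bond
  fv <- dr * mag
  for (d in 1:3) {
    f[, d] <- f[, d] + tapply_add(-fv[, d], bonds[, 1], nrow(pos)) +
      tapply_add(fv[, d], bonds[, 2], nrow(pos))
  }
  f
}

tapply_add <- function(x, idx, n) {
  out <- numeric(n)
  s <- tapply(x, idx, sum)
  out[as.integer(names(s))] <- s
  out
}

#' Parameters of the reduced Langevin polymer backend
#'
#' Reduced-unit parameters of the bead-spring chain: Lennard-Jones well
#' depth, length and cutoff (theta-solvent values must be supplied by the
#' caller), harmonic bond constant `k` (default 40, stiff enough to prevent
#' strand passing) and equilibrium bond length `b`. One bead of the 1 kb
#' chain corresponds to about 33.5 nm (see [bead_size_nm()]); the simulation
#' itself runs in reduced units.
#'
#' @param eps,sigma,cutoff Lennard-Jones parameters (reduced units).
#' @param k Bond spring constant (default 40).
#' @param b Equilibrium bond length (default 1).
#' @return Object of class `langevin_params`.
#' @export
langevin_params <- function(eps = 1, sigma = 1, cutoff = 2.5, k = 40, b = 1) {
  stopifnot(k > 0, sigma > 0, cutoff > 0, b > 0)
  structure(list(eps = eps, sigma = sigma, cutoff = cutoff, k = k, b = b),
            class = "langevin_params")
}

#' Overdamped Langevin dynamics of a bead-spring chain
#'
#' Euler-Maruyama integration of `dx = F dt + sqrt(2 dt) dW` (reduced units,
#' kT = friction = 1) for a linear chain with harmonic backbone bonds,
#' optional extra harmonic bonds (extruder bridges), and Lennard-Jones
#' volume interactions. Aborts with a diagnostic when the integration
#' becomes unstable (non-finite coordinates or runaway bond lengths).
#'
#' @param n_beads Chain length (kept small; the backend is desk-scale).
#' @param params A [langevin_params()].
#' @param extra_bonds Two-column matrix of additional bonded pairs.
#' @param n_steps Integration steps.
#' @param dt Time step (reduced units; default 1e-3 for k = 40).
#' @param sample_every Steps between stored configurations.
#' @param seed Integer seed.
#' @param max_step Cap on the per-step deterministic displacement (units of
#'   `b`); limits the impulse when an extruder bond is first imposed between
#'   distant legs. The cap is rarely active at equilibrium.
#' @param init Optional n x 3 start configuration (default: straight line at
#'   bond length b).
#' @return List with `samples` (list of n x 3 matrices) and the final
#'   configuration.
#' @export
langevin_chain <- function(n_beads, params = langevin_params(),
                           extra_bonds = NULL, n_steps = 2000L, dt = 1e-3,
                           sample_every = 100L, seed = 1L, max_step = 0.2,
                           init = NULL) {
  stopifnot(inherits(params, "langevin_params"), n_beads >= 2)
  set.seed(seed)
  pos <- if (is.null(init)) {
    cbind(seq_len(n_beads) * params$b, 0, 0)
  } else as.matrix(init)
  bonds <- cbind(seq_len(n_beads - 1L), 2:n_beads)
  if (!is.null(extra_bonds) && nrow(extra_bonds) > 0) {
    bonds <- rbind(bonds, as.matrix(extra_bonds))
  }
  samples <- list()
  noise_sd <- sqrt(2 * dt)
  for (step in seq_len(n_steps)) {
    f <- bond_forces(pos, bonds, params$k, params$b) +
      lj_forces(pos, params$eps, params$sigma, params$cutoff)
    disp <- f * dt
    mag <- sqrt(rowSums(disp^2))
    cap <- max_step * params$b
    over <- mag > cap
    if (any(over)) disp[over, ] <- disp[over, , drop = FALSE] * cap / mag[over]
    pos <- pos + disp +
      matrix(stats::rnorm(3 * n_beads, 0, noise_sd), n_beads, 3)
    if (any(!is.finite(pos)) ||
        max(abs(pos)) > 1e3 * params$b * n_beads) {
      stop("Langevin integration unstable at step ", step,
           ": reduce dt or soften potentials")
    }
    if (step %% sample_every == 0L) {
      samples[[length(samples) + 1L]] <- pos
    }
  }
  list(samples = samples, final = pos)
}

#' Contact map from the Langevin backend
#'
#' Imposes each sampled extruder configuration of a lattice trajectory as
#' extra bonds on the bead-spring chain, equilibrates briefly, and scores
#' contacts as bead pairs within `capture_radius`. Contact maps are averaged
#' over lattice samples and Langevin configurations.
#'
#' @param traj A [run_extrusion()] trajectory with a small chain
#'   (`chain_length` <= 2000; in practice a few hundred beads).
#' @param params A [langevin_params()].
#' @param capture_radius Contact distance in units of the bond length.
#' @param n_steps,dt,sample_every Integration controls per lattice sample.
#' @param seed Integer seed.
#' @return A [contact_map()].
#' @export
langevin_contacts <- function(traj, params = langevin_params(),
                              capture_radius = 2, n_steps = 2000L, dt = 1e-3,
                              sample_every = 200L, seed = 1L) {
  stopifnot(inherits(traj, "lattice_trajectory"))
  n <- traj$params$chain_length
  if (n > 2000) stop("Langevin backend is desk-scale: chain_length <= 2000")
  if (length(traj$samples) == 0) stop("empty trajectory")
  acc <- matrix(0, n, n)
  count <- 0L
  cap2 <- (capture_radius * params$b)^2
  for (si in seq_along(traj$samples)) {
    s <- traj$samples[[si]]
    eb <- if (nrow(s) > 0) cbind(s$left, s$right) else NULL
    run <- langevin_chain(n, params, extra_bonds = eb, n_steps = n_steps,
                          dt = dt, sample_every = sample_every,
                          seed = seed + si)
    for (pos in run$samples) {
      d2 <- as.matrix(stats::dist(pos))^2
      acc <- acc + (d2 <= cap2)
      count <- count + 1L
    }
  }
  contact_map(acc / count, traj$params$resolution_kb)
}
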