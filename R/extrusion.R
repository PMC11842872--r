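#' Parameters of the 1D loop-extrusion lattice model
#'
#' A chromosome is a chain of beads (`resolution_kb` kb each). Loop
#' extruders (cohesins) are loaded stochastically onto adjacent bead pairs,
#' advance each leg outward by one bead per update, unload with a constant
#' probability per update, block each other (legs cannot pass), and stall
#' permanently at impermeable CTCF sites and chain ends. With one bead per
#' leg per update the extrusion speed (loop growth rate) is emergent:
#' `2 * resolution_kb / update_interval_s` kb/s, i.e. 0.5 kb/s at 1 kb beads
#' and 4 s updates.
#'
#' The macroscopic association rate `assoc_rate_per_mb_min` (extruder
#' loadings per Mb of chain per minute) is converted to a per-candidate-pair
#' loading probability per update:
#' `p_load = rate * chain_Mb * (update_interval_s / 60) / n_candidate_pairs`,
#' where candidate pairs exclude chain ends and CTCF beads, so the
#' configured rate is honoured at any resolution. The residence time maps to
#' `p_unload = update_interval_s / residence_s`.
#'
#' @param chain_length Number of beads (>= 4).
#' @param resolution_kb kb per bead (1 or 10 in typical use).
#' @param update_interval_s Seconds per update (default 4; the time mapping
#'   of the lattice model).
#' @param assoc_rate_per_mb_min Loading rate per Mb per minute (alternative
#'   to `p_load`).
#' @param residence_s Mean extruder residence time (s) (alternative to
#'   `p_unload`).
#' @param p_load,p_unload Direct probabilities per update (override the
#'   macroscopic parameters).
#' @param ctcf_sites Integer bead indices of impermeable CTCF sites.
#' @return Object of class `extrusion_params`.
#' @export
extrusion_params <- function(chain_length, resolution_kb = 1,
                             update_interval_s = 4,
                             assoc_rate_per_mb_min = NULL, residence_s = NULL,
                             p_load = NULL, p_unload = NULL,
                             ctcf_sites = integer(0)) {
  chain_length <- as.integer(chain_length)
  stopifnot(chain_length >= 4L, resolution_kb > 0, update_interval_s > 0)
  ctcf <- logical(chain_length)
  ctcf_sites <- as.integer(ctcf_sites)
  stopifnot(all(ctcf_sites >= 1L & ctcf_sites <= chain_length))
  ctcf[ctcf_sites] <- TRUE

  # candidate loading pairs (i, i+1): no chain-end bead, no CTCF bead
  cand <- 2:(chain_length - 2L)
  cand <- cand[!ctcf[cand] & !ctcf[cand + 1L]]

  if (is.null(p_unload)) {
    if (is.null(residence_s)) stop("give residence_s or p_unload")
    p_unload <- update_interval_s / residence_s
  }
  if (is.null(p_load)) {
    if (is.null(assoc_rate_per_mb_min)) stop("give assoc_rate_per_mb_min or p_load")
    chain_mb <- chain_length * resolution_kb / 1000
    p_load <- assoc_rate_per_mb_min * chain_mb * (update_interval_s / 60) /
      length(cand)
  }
  if (p_load < 0 || p_load > 1 || p_unload < 0 || p_unload > 1) {
    stop("p_load and p_unload must be probabilities in [0, 1]")
  }
  structure(list(chain_length = chain_length, resolution_kb = resolution_kb,
                 update_interval_s = update_interval_s,
                 p_load = p_load, p_unload = p_unload,
                 ctcf = ctcf, candidates = cand,
                 residence_s = update_interval_s / max(p_unload, 1e-300),
                 speed_kb_s = 2 * resolution_kb / update_interval_s),
            class = "extrusion_params")
}

#' @export
print.extrusion_params <- function(x, ...) {
  cat(sprintf(paste0("Loop-extrusion lattice: %d beads x %g kb, update %g s\n",
                     "  p_load %.4g/pair/update, p_unload %.4g/update ",
                     "(residence %.4g s)\n  %d CTCF sites; extrusion speed ",
                     "%g kb/s\n"),
              x$chain_length, x$resolution_kb, x$update_interval_s,
              x$p_load, x$p_unload, x$residence_s, sum(x$ctcf), x$speed_kb_s))
  invisible(x)
}

#' Empty extruder state
#'
#' @param params An [extrusion_params()].
#' @return Object of class `extruder_state`.
#' @export
new_extruder_state <- function(params) {
  structure(list(left = integer(0), right = integer(0),
                 stall_left = logical(0), stall_right = logical(0),
                 load_time = numeric(0), id = integer(0),
                 time = 0, next_id = 1L,
                 unloaded = data.frame(id = integer(0), lifetime_s = numeric(0),
                                       loop_kb = numeric(0))),
            class = "extruder_state")
}

#' One update of the loop-extrusion engine
#'
#' Event order within an update: (1) each extruder unloads with `p_unload`;
#' (2) each surviving extruder advances each non-stalled leg outward by one
#' bead, stalling at occupied beads (temporarily) and at CTCF sites or chain
#' ends (permanently); (3) loading is attempted at every unoccupied
#' candidate pair with `p_load`. Extruders are processed in id order, so the
#' update is fully deterministic given the random stream.
#'
#' @param state An `extruder_state`.
#' @param params An [extrusion_params()].
#' @return Updated state (time advanced by one update interval). Lifetimes
#'   and loop sizes of unloaded extruders accumulate in `state$unloaded`.
#' @export
extrusion_step <- function(state, params) {
  L <- params$chain_length
  ctcf <- params$ctcf
  t_next <- state$time + params$update_interval_s

  # 1) unloading
  n <- length(state$left)
  if (n > 0 && params$p_unload > 0) {
    gone <- stats::runif(n) < params$p_unload
    if (any(gone)) {
      state$unloaded <- rbind(
        state$unloaded,
        data.frame(id = state$id[gone],
                   lifetime_s = t_next - state$load_time[gone],
                   loop_kb = (state$right[gone] - state$left[gone]) *
                     params$resolution_kb))
      keep <- !gone
      state$left <- state$left[keep]; state$right <- state$right[keep]
      state$stall_left <- state$stall_left[keep]
      state$stall_right <- state$stall_right[keep]
      state$load_time <- state$load_time[keep]; state$id <- state$id[keep]
    }
  }

  # 2) stepping (sequential in id order; occupancy updated as legs move)
  n <- length(state$left)
  if (n > 0) {
    occ <- logical(L)
    occ[state$left] <- TRUE; occ[state$right] <- TRUE
    for (i in seq_len(n)) {
      if (!state$stall_left[i]) {
        tgt <- state$left[i] - 1L
        if (tgt <= 1L || ctcf[tgt]) {
          # chain end or impermeable CTCF site: permanent stall
          state$stall_left[i] <- TRUE
        } else if (!occ[tgt]) {
          occ[state$left[i]] <- FALSE; state$left[i] <- tgt; occ[tgt] <- TRUE
        }                                   # occupied: blocked, retry later
      }
      if (!state$stall_right[i]) {
        tgt <- state$right[i] + 1L
        if (tgt >= L || ctcf[tgt]) {
          state$stall_right[i] <- TRUE
        } else if (!occ[tgt]) {
          occ[state$right[i]] <- FALSE; state$right[i] <- tgt; occ[tgt] <- TRUE
        }
      }
    }
  } else {
    occ <- logical(L)
  }

  # 3) loading onto free candidate pairs
  if (params$p_load > 0 && length(params$candidates)) {
    cand <- params$candidates
    free <- !occ[cand] & !occ[cand + 1L]
    tries <- cand[free][stats::runif(sum(free)) < params$p_load]
    for (i0 in tries) {
      if (occ[i0] || occ[i0 + 1L]) next     # adjacent loading this update
      state$left <- c(state$left, i0)
      state$right <- c(state$right, i0 + 1L)
      state$stall_left <- c(state$stall_left, FALSE)
      state$stall_right <- c(state$stall_right, FALSE)
      state$load_time <- c(state$load_time, t_next)
      state$id <- c(state$id, state$next_id)
      state$next_id <- state$next_id + 1L
      occ[i0] <- TRUE; occ[i0 + 1L] <- TRUE
    }
  }

  state$time <- t_next
  state
}

#' Check structural invariants of an extruder state
#'
#' Verifies `left < right` for every extruder, that no bead carries two
#' legs, and that loop intervals are nested or disjoint (never crossing).
#'
#' @param state An `extruder_state`.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_extruder_state <- function(state) {
  n <- length(state$left)
  if (n == 0) return(invisible(TRUE))
  if (any(state$left >= state$right)) stop("invariant violated: left >= right")
  beads <- c(state$left, state$right)
  if (anyDuplicated(beads)) stop("invariant violated: shared bead")
  if (n > 1) {
    ord <- order(state$left)
    l <- state$left[ord]; r <- state$right[ord]
    for (i in seq_len(n - 1)) {
      # the next loop must start after this one ends (disjoint) or lie
      # strictly inside it (nested)
      bad <- l[i + 1] > l[i] & l[i + 1] < r[i] & r[i + 1] > r[i]
      if (any(bad)) stop("invariant violated: crossing loops")
    }
  }
  invisible(TRUE)
}

#' Run the loop-extrusion engine
#'
#' Repeated [extrusion_step()]s with seeded randomness. Configurations are
#' sampled every `sample_every_s` seconds after a stationarity burn-in
#' (default three residence times).
#'
#' @param params An [extrusion_params()].
#' @param duration_s Simulated time after burn-in (s).
#' @param sample_every_s Sampling interval (s).
#' @param seed Integer seed.
#' @param burn_in_s Burn-in (s); default `3 * residence_s`.
#' @param validate Check invariants after every update (slower).
#' @return Object of class `lattice_trajectory`: `samples` (list of data
#'   frames with `left`, `right`, `stalled_left`, `stalled_right`),
#'   `sample_times`, per-sample extruder counts, the unload log
#'   (`lifetime_s`, `loop_kb`) and the parameters.
#' @export
run_extrusion <- function(params, duration_s, sample_every_s,
                          seed = 1L, burn_in_s = 3 * params$residence_s,
                          validate = FALSE) {
  stopifnot(duration_s >= sample_every_s)
  set.seed(seed)
  state <- new_extruder_state(params)
  dt <- params$update_interval_s
  n_burn <- ceiling(burn_in_s / dt)
  n_run <- ceiling(duration_s / dt)
  every <- max(1L, round(sample_every_s / dt))

  for (j in seq_len(n_burn)) {
    state <- extrusion_step(state, params)
    if (validate) validate_extruder_state(state)
  }
  state$unloaded <- state$unloaded[0, ]  # only post-burn-in lifetimes

  samples <- list(); times <- numeric(0)
  for (j in seq_len(n_run)) {
    state <- extrusion_step(state, params)
    if (validate) validate_extruder_state(state)
    if (j %% every == 0L) {
      samples[[length(samples) + 1L]] <-
        data.frame(left = state$left, right = state$right,
                   stalled_left = state$stall_left,
                   stalled_right = state$stall_right)
      times <- c(times, state$time)
    }
  }
  structure(list(samples = samples, sample_times = times,
                 n_extruders = vapply(samples, nrow, integer(1)),
                 unloaded = state$unloaded, params = params),
            class = "lattice_trajectory")
}

#' @export
print.lattice_trajectory <- function(x, ...) {
  cat(sprintf("Lattice trajectory: %d samples, mean %.2f extruders, %d unload events\n",
              length(x$samples), mean(x$n_extruders), nrow(x$unloaded)))
  invisible(x)
}

#' Extruder processivity
#'
#' Expected loop length extruded before unloading: speed times residence
#' time (e.g. 0.5 kb/s x 50 s = 25 kb).
#'
#' @param speed_kb_s Extrusion speed (kb/s).
#' @param residence_s Residence time (s).
#' @return Processivity (kb).
#' @export
processivity <- function(speed_kb_s, residence_s) {
  stopifnot(speed_kb_s >= 0, residence_s >= 0)
  speed_kb_s * residence_s
}

#' Mean extruder density on the chain
#'
#' Time-averaged number of bound extruders per Mb of simulated chromatin.
#'
#' @param traj A [run_extrusion()] trajectory.
#' @return Density (extruders / Mb).
#' @export
mean_density <- function(traj) {
  stopifnot(inherits(traj, "lattice_trajectory"))
  chain_mb <- traj$params$chain_length * traj$params$resolution_kb / 1000
  mean(traj$n_extruders) / chain_mb
}

#' Measure the emergent extrusion speed
#'
#' Places a single extruder mid-chain with loading and unloading switched
#' off, runs unobstructed updates and returns the loop growth in kb divided
#' by the elapsed time (both legs advance, one bead each, per update).
#'
#' @param resolution_kb kb per bead.
#' @param update_interval_s Seconds per update.
#' @param n_updates Number of updates to measure over.
#' @return Speed in kb/s.
#' @export
measure_extrusion_speed <- function(resolution_kb = 1, update_interval_s = 4,
                                    n_updates = 10L) {
  L <- as.integer(4L + 2L * (n_updates + 2L))
  params <- extrusion_params(chain_length = L, resolution_kb = resolution_kb,
                             update_interval_s = update_interval_s,
                             p_load = 0, p_unload = 0)
  state <- new_extruder_state(params)
  mid <- L %/% 2L
  state$left <- mid; state$right <- mid + 1L
  state$stall_left <- FALSE; state$stall_right <- FALSE
  state$load_time <- 0; state$id <- 1L
  size0 <- (state$right - state$left) * resolution_kb
  for (j in seq_len(n_updates)) state <- extrusion_step(state, params)
  size1 <- (state$right - state$left) * resolution_kb
  (size1 - size0) / state$time
}

#' Bead size of the chromatin chain model
#'
#' Physical extent of one lattice bead, from the random-walk folding of the
#' nucleosome chain: `step_nm * sqrt(n_nucleosomes)` with ~5 nucleosomes
#' (15 nm nucleosome + linker) per kb, i.e. 15 * sqrt(5) ~ 33.5 nm for a
#' 1 kb bead.
#'
#' @param resolution_kb kb per bead.
#' @param nucleosomes_per_kb Nucleosome count per kb (default 5).
#' @param step_nm Nucleosome-plus-linker step (nm, default 15).
#' @return Bead size in nm.
#' @export
bead_size_nm <- function(resolution_kb = 1, nucleosomes_per_kb = 5,
                         step_nm = 15) {
  step_nm * sqrt(nucleosomes_per_kb * resolution_kb)
}
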