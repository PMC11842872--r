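test_that("parameter mapping honours the macroscopic rates", {
  p <- extrusion_params(chain_length = 1000, resolution_kb = 1,
                        assoc_rate_per_mb_min = 3, residence_s = 50)
  # loading flux over the whole chain: rate * Mb / 60 per second
  flux <- p$p_load * length(p$candidates) / p$update_interval_s
  expect_equal(flux, 3 * 1 / 60, tolerance = 1e-12)
  expect_equal(p$p_unload, 4 / 50)
  expect_equal(p$residence_s, 50)
  expect_equal(p$speed_kb_s, 0.5)
  expect_error(extrusion_params(100, residence_s = 1), "give assoc")
  expect_error(extrusion_params(100, p_load = 2, p_unload = 0.5),
               "probabilities")
})

test_that("an unobstructed extruder grows its loop by two beads per update", {
  p <- extrusion_params(chain_length = 30, p_load = 0, p_unload = 0)
  st <- new_extruder_state(p)
  st$left <- 15L; st$right <- 16L
  st$stall_left <- FALSE; st$stall_right <- FALSE
  st$load_time <- 0; st$id <- 1L
  st <- extrusion_step(st, p)
  expect_equal(c(st$left, st$right), c(14L, 17L))
  st <- extrusion_step(st, p)
  expect_equal(c(st$left, st$right), c(13L, 18L))
})

test_that("p_unload = 1 removes every extruder one update after loading", {
  p <- extrusion_params(chain_length = 20, p_load = 0.5, p_unload = 1)
  st <- new_extruder_state(p)
  set.seed(71)
  for (i in 1:20) st <- extrusion_step(st, p)
  expect_gt(nrow(st$unloaded), 5)
  expect_true(all(st$unloaded$lifetime_s == p$update_interval_s))
})

test_that("converging extruders block inner legs and keep extruding outward", {
  # hand-enumerated 20-bead oracle: loops [8,9] and [11,12] loaded together;
  # update 1 -> [7,10], [10?]: the left loop reaches 10 first, the right
  # loop's left leg is blocked at 11 and its right leg moves on
  p <- extrusion_params(chain_length = 20, p_load = 0, p_unload = 0)
  st <- new_extruder_state(p)
  st$left <- c(8L, 11L); st$right <- c(9L, 12L)
  st$stall_left <- c(FALSE, FALSE); st$stall_right <- c(FALSE, FALSE)
  st$load_time <- c(0, 0); st$id <- 1:2
  st <- extrusion_step(st, p)
  expect_equal(st$left, c(7L, 11L))   # extruder 2's left leg blocked by 10
  expect_equal(st$right, c(10L, 13L))
  st <- extrusion_step(st, p)
  expect_equal(st$left, c(6L, 11L))   # inner legs now permanently adjacent
  expect_equal(st$right, c(10L, 14L)) # extruder 1's right leg blocked by 11
  validate_extruder_state(st)
  # outer legs keep extruding to the chain-end stall
  for (i in 1:10) st <- extrusion_step(st, p)
  expect_equal(st$left, c(2L, 11L))
  expect_equal(st$right, c(10L, 19L))
  expect_true(st$stall_left[1] && st$stall_right[2])
  validate_extruder_state(st)
})

test_that("legs stall permanently at impermeable CTCF sites", {
  p <- extrusion_params(chain_length = 40, p_load = 0, p_unload = 0,
                        ctcf_sites = c(10L, 25L))
  st <- new_extruder_state(p)
  st$left <- 15L; st$right <- 16L
  st$stall_left <- FALSE; st$stall_right <- FALSE
  st$load_time <- 0; st$id <- 1L
  for (i in 1:20) st <- extrusion_step(st, p)
  # legs never pass (or occupy) the sites they approached
  expect_equal(st$left, 11L)
  expect_equal(st$right, 24L)
  expect_true(st$stall_left && st$stall_right)
})

test_that("loading respects occupancy, CTCF sites and chain ends", {
  p <- extrusion_params(chain_length = 10, p_load = 1, p_unload = 0,
                        ctcf_sites = 5L)
  # candidates exclude ends (beads 1, 10 and pair 9-10) and the site bead
  expect_false(any(p$candidates %in% c(1L, 4L, 5L, 9L)))
  st <- new_extruder_state(p)
  set.seed(72)
  st <- extrusion_step(st, p)
  validate_extruder_state(st)
  occ <- c(st$left, st$right)
  expect_false(any(occ == 5L))
  expect_false(any(occ %in% c(1L, 10L)))
})

test_that("realized lifetimes are geometric with mean dt/p_unload", {
  p <- extrusion_params(chain_length = 200, p_load = 0.002, p_unload = 0.1)
  tr <- run_extrusion(p, duration_s = 3e4, sample_every_s = 400, seed = 73)
  life <- tr$unloaded$lifetime_s / p$update_interval_s
  expect_gt(length(life), 500)
  expect_equal(mean(life), 1 / p$p_unload, tolerance = 0.1)
  # chi-squared goodness of fit against the geometric pmf
  kmax <- 40
  obs <- tabulate(pmin(life, kmax), nbins = kmax)
  pk <- dgeom(0:(kmax - 2), p$p_unload)
  pk <- c(pk, 1 - sum(pk))            # pooled tail
  expect_gt(suppressWarnings(
    chisq.test(obs, p = pk, rescale.p = TRUE))$p.value, 0.001)
})

test_that("p_load = 0 yields an empty trajectory", {
  p <- extrusion_params(chain_length = 50, p_load = 0, p_unload = 0.1)
  tr <- run_extrusion(p, duration_s = 100, sample_every_s = 20, seed = 74)
  expect_true(all(tr$n_extruders == 0))
})

test_that("low-density occupancy follows Little's law", {
  p <- extrusion_params(chain_length = 300, p_load = 5e-4, p_unload = 0.1)
  tr <- run_extrusion(p, duration_s = 6e4, sample_every_s = 100, seed = 75)
  lam <- p$p_load * length(p$candidates) / p$update_interval_s
  expect_equal(mean(tr$n_extruders), lam * p$residence_s, tolerance = 0.1)
  # a single permanent extruder on a 1 Mb chain is 1 per Mb
  p1 <- extrusion_params(chain_length = 1000, resolution_kb = 1,
                         p_load = 0, p_unload = 0)
  tr1 <- run_extrusion(p1, duration_s = 40, sample_every_s = 4, seed = 1,
                       burn_in_s = 0)
  tr1$samples <- lapply(tr1$samples, function(s)
    data.frame(left = 500L, right = 501L, stalled_left = FALSE,
               stalled_right = FALSE))
  tr1$n_extruders <- rep(1L, length(tr1$samples))
  expect_equal(mean_density(tr1), 1)
})

test_that("structural invariants hold along a busy trajectory", {
  p <- extrusion_params(chain_length = 120, p_load = 0.01, p_unload = 0.05,
                        ctcf_sites = c(30L, 60L, 90L))
  expect_silent(run_extrusion(p, duration_s = 8000, sample_every_s = 400,
                              seed = 76, validate = TRUE))
})

test_that("processivity is speed times residence", {
  expect_equal(processivity(0.5, 50), 25)
  expect_equal(processivity(0.5, 100), 50)
  expect_equal(processivity(0.5, 0), 0)
})

test_that("the bead size mapping gives 33.5 nm at 1 kb", {
  expect_equal(bead_size_nm(), 15 * sqrt(5))
  expect_equal(bead_size_nm(), 33.5, tolerance = 0.002)
  expect_equal(bead_size_nm(4), 2 * bead_size_nm(1))
})
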