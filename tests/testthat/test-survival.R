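test_that("survival times follow the (detections - 1) x cycle rule", {
  sch <- timelapse_scheme(n_frames = 20, exposure_s = 0.5, readout_s = 0.0017,
                          dark_s = 0)
  tracks <- rbind(
    stationary_track(1L, 0:2, 1, 1, sch),   # 3 detections -> 1.0034 s
    stationary_track(2L, 0:1, 2, 2, sch),   # 2 detections -> excluded
    stationary_track(3L, 0:9, 3, 3, sch))
  ds <- survival_distribution(tracks, sch)
  expect_equal(ds$times, c(2 * 0.5017, 9 * 0.5017))
  expect_equal(ds$times[1], 1.0034)
  expect_equal(ds$cycle_s, 0.5017)
})

test_that("rate grid spans 1e-3 to 1e1 with 50 points per decade", {
  g <- rate_grid()
  expect_equal(range(g), c(1e-3, 1e1))
  expect_equal(length(g), 201L)
  expect_true(all(diff(log10(g)) > 0))
})

test_that("a noiseless single exponential concentrates at the true rate", {
  # deterministic event counts reproduce the exact discretized survival law
  exact_dataset <- function(k, cycle_s, N = 5e4) {
    m <- 2:ceiling(-log(1e-5) / (k * cycle_s))
    n_m <- round(N * (exp(-k * m * cycle_s) - exp(-k * (m + 1) * cycle_s)))
    survival_dataset(rep(m * cycle_s, n_m), cycle_s, p_loss = 0)
  }
  d1 <- exact_dataset(0.01, 0.5)
  d2 <- exact_dataset(0.01, 4.5)
  spec <- invert_spectrum(list(d1, d2))
  k_hat <- sum(spec$rates * spec$event)
  expect_equal(k_hat, 0.01, tolerance = 0.1)
  # mass concentrated near 0.01: nothing appreciable beyond a half decade
  far <- abs(log10(spec$rates / 0.01)) > 0.5
  expect_lt(sum(spec$event[far]), 0.05)
})

test_that("two-exponential truth with per-frame loss is recovered", {
  rates <- c(0.01, 1); w <- c(0.3, 0.7)
  d1 <- simulate_survival_times(rates, w, 1e4, cycle_s = 0.5017,
                                p_loss = 0.0025, seed = 53)
  d2 <- simulate_survival_times(rates, w, 1e4, cycle_s = 4.5153,
                                p_loss = 0.0025, seed = 54)
  spec <- invert_spectrum(list(d1, d2))
  lo <- spec$rates < 0.1
  expect_lt(abs(sum(spec$event[lo]) - 0.3), 0.05)
  rs <- summarize_residence(spec)
  expect_lt(abs(rs$tau_s - 100) / 100, 0.2)
  expect_lt(abs(rs$tau_u - 1) / 1, 0.3)
  expect_true(rs$tau_s > rs$tau_u)
})

test_that("a single condition warns about identifiability", {
  d1 <- simulate_survival_times(0.1, 1, 500, cycle_s = 0.5, p_loss = 0.0025,
                                seed = 55)
  expect_warning(invert_spectrum(list(d1)), "identifiable")
})

test_that("state/event spectrum conversion is exact algebra", {
  spec <- structure(list(rates = c(0.01, 1), event = c(0.5, 0.5),
                         state = NULL), class = "rate_spectrum")
  spec <- to_state_spectrum(spec)
  expect_equal(spec$state, c(50 / 50.5, 0.5 / 50.5))
  expect_equal(spec$state, c(0.990099, 0.009901), tolerance = 1e-6)
  # single-rate spectrum: state == event == 1
  s1 <- structure(list(rates = 2, event = 1, state = NULL),
                  class = "rate_spectrum")
  expect_equal(to_state_spectrum(s1)$state, 1)
  # round trip state -> event -> state is the identity
  back <- to_state_spectrum(to_event_spectrum(spec))
  expect_equal(back$state, spec$state, tolerance = 1e-12)
  expect_equal(back$event, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("residence summary averages rates on each side of the threshold", {
  spec <- structure(list(rates = c(0.01, 0.02, 0.5, 2),
                         event = c(0.2, 0.2, 0.3, 0.3), state = NULL),
                    class = "rate_spectrum")
  spec <- to_state_spectrum(spec)
  rs <- summarize_residence(spec)
  s <- spec$state
  k_s <- sum(s[1:2] * c(0.01, 0.02)) / sum(s[1:2])
  expect_equal(rs$k_off_s, k_s)
  expect_equal(rs$tau_s, 1 / k_s)
  expect_equal(rs$A_event_s, 0.4)
  # all mass on one side: the other side is flagged
  one <- structure(list(rates = c(0.01, 0.02), event = c(0.5, 0.5),
                        state = NULL), class = "rate_spectrum")
  rs1 <- summarize_residence(to_state_spectrum(one))
  expect_true(is.na(rs1$tau_u))
  expect_true(rs1$empty_side["above"])
  # state weights (2/3, 1/3) on rates (0.01, 0.02): k_s = 0.01333, tau = 75
  expect_equal(rs1$tau_s, 75)
})

test_that("all mass at k = 0.01 gives tau_s = 100 s", {
  spec <- structure(list(rates = c(0.01, 1), event = c(1, 0), state = NULL),
                    class = "rate_spectrum")
  expect_equal(summarize_residence(to_state_spectrum(spec))$tau_s, 100)
})

test_that("inversion residual is monotone in grid density on nested grids", {
  d1 <- simulate_survival_times(c(0.02, 0.8), c(0.5, 0.5), 4e3,
                                cycle_s = 0.5, p_loss = 0, seed = 56)
  d2 <- simulate_survival_times(c(0.02, 0.8), c(0.5, 0.5), 4e3,
                                cycle_s = 4.5, p_loss = 0, seed = 57)
  coarse <- invert_spectrum(list(d1, d2), grid = rate_grid(per_decade = 25))
  fine <- invert_spectrum(list(d1, d2), grid = rate_grid(per_decade = 50))
  # slack covers the iterated conditioning scale, not the NNLS itself
  expect_lte(fine$residual, coarse$residual * 1.001 + 1e-12)
})

test_that("spectrum resampling errors shrink with event count", {
  rates <- c(0.01, 1); w <- c(0.3, 0.7)
  small <- lapply(c(0.5017, 4.5153), function(cy)
    simulate_survival_times(rates, w, 800, cycle_s = cy, seed = 60 + cy))
  big <- lapply(c(0.5017, 4.5153), function(cy)
    simulate_survival_times(rates, w, 8000, cycle_s = cy, seed = 70 + cy))
  g <- rate_grid(per_decade = 15)
  # uncertainty of the long-bound residence time shrinks with event count
  tau_sd <- function(ds, seed) {
    r <- resample_spectrum(ds, g, n_resamples = 20, seed = seed)
    taus <- apply(r$state, 1, function(st) {
      sp <- structure(list(rates = g, event = st * g / sum(st * g),
                           state = st), class = "rate_spectrum")
      summarize_residence(sp)$tau_s
    })
    stats::sd(taus)
  }
  expect_lt(tau_sd(big, 2), tau_sd(small, 1))
  # identical subsets (frac = 1) give zero spread
  r0 <- resample_spectrum(big, g, n_resamples = 3, frac = 1, seed = 3)
  expect_equal(max(r0$event_sd), 0)
})
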