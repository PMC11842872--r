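itm <- itm_scheme(n_cycles = 10)
itm_ft <- frame_table(itm)

test_that("ITM classification assigns the canonical track archetypes", {
  # frame f is followed by dark 0.2 s (even f) or 4 s (odd f)
  spot <- stationary_track(1L, 0L, 0, 0, itm)
  short <- stationary_track(2L, 0:1, 2, 2, itm)      # spans one short dark
  grey <- stationary_track(3L, 1:2, 4, 4, itm)       # spans one long dark
  long <- stationary_track(4L, 1:5, 6, 6, itm)       # spans two long darks
  ct <- classify_itm(rbind(spot, short, grey, long), itm,
                     confinement_radius = 0.5)
  expect_equal(unname(ct$classes[c("1", "2", "3", "4")]),
               c("spot", "short", "grey", "long"))
  expect_equal(c(ct$N_long, ct$N_short, ct$N_spot, ct$N_grey),
               c(1L, 1L, 1L, 1L))
})

test_that("every track lands in exactly one class and ids are irrelevant", {
  tracks <- rbind(stationary_track(7L, 0:3, 1, 1, itm),
                  stationary_track(3L, 0L, 5, 5, itm),
                  stationary_track(11L, 0:1, 9, 9, itm))
  ct <- classify_itm(tracks, itm)
  expect_equal(ct$N_long + ct$N_short + ct$N_spot + ct$N_grey, 3L)
  relabeled <- tracks
  relabeled$track_id <- match(relabeled$track_id, unique(relabeled$track_id))
  ct2 <- classify_itm(relabeled, itm)
  expect_equal(sort(unname(ct$classes)), sort(unname(ct2$classes)))
})

test_that("a wandering molecule does not survive dark times", {
  # detections flank the darks but move far apart: not confined
  tr <- data.frame(track_id = 1L, frame = 1:5,
                   t_s = itm_ft$t_s[2:6],
                   x_um = c(0, 3, 6, 9, 12), y_um = 0)
  ct <- classify_itm(tr, itm, confinement_radius = 0.5)
  expect_equal(unname(ct$classes), "spot")
})

test_that("class fractions follow the event-count arithmetic", {
  ct <- structure(list(N_long = 5L, N_short = 15L, N_spot = 80L, N_grey = 0L),
                  class = "binding_class_counts")
  fr <- class_fractions(ct)
  expect_equal(fr$long_fraction, 0.05)
  expect_equal(fr$short_fraction, 0.15)
  ct0 <- structure(list(N_long = 0L, N_short = 2L, N_spot = 8L, N_grey = 0L),
                   class = "binding_class_counts")
  expect_equal(class_fractions(ct0)$long_fraction, 0)
  ct_empty <- structure(list(N_long = 0L, N_short = 0L, N_spot = 0L,
                             N_grey = 0L), class = "binding_class_counts")
  expect_error(class_fractions(ct_empty), "undefined")
  # movie-wise aggregation: mean +/- sd across movies
  agg <- class_fractions(list(ct, ct0))
  expect_equal(agg$long_fraction, 0.025)
  expect_equal(agg$long_sd, stats::sd(c(0.05, 0)))
})

test_that("a continuous scheme is rejected as an ITM input", {
  tr <- stationary_track(1L, 0:3, 1, 1, continuous_scheme(10))
  expect_error(classify_itm(tr, continuous_scheme(10)), "dark")
})

test_that("recovered long fraction matches the simulated occupancy", {
  # ~13% long-bound occupancy; everything else diffuses fast
  truth <- ground_truth(
    diffusion_components = data.frame(fraction = c(0.13, 0.87),
                                      D_um2_s = c(5e-4, 2.5)),
    k_on_u = 1e-9, k_on_s = 0.13 / 0.87 * 0.002, k_off_u = 1, k_off_s = 0.002,
    loc_error_um = 0.02, per_frame_loss = 0, nucleus_radius_um = 6)
  p_long <- unname(stationary_fractions(truth)["long"])
  expect_equal(p_long, 0.13, tolerance = 0.001)
  sch <- itm_scheme(n_cycles = 6)
  movies <- lapply(1:4, function(s) {
    mv <- simulate_movie(truth, sch, n_molecules = 120, seed = 300 + s)
    classify_itm(as_tracks(mv), sch, confinement_radius = 0.6)
  })
  agg <- class_fractions(movies)
  n_tot <- sum(vapply(movies, function(ct)
    ct$N_long + ct$N_short + ct$N_spot + ct$N_grey, integer(1)))
  se <- sqrt(0.13 * 0.87 / n_tot)
  expect_lt(abs(agg$long_fraction - 0.13), 4 * se + 0.02)
})

test_that("TACO mobility matches Rayleigh-mean oracles", {
  # stationary molecule, localization noise sigma: mean jump = sigma*sqrt(pi)
  sigma <- 0.03
  sch <- taco_scheme("long", n_cycles = 8)
  ft <- frame_table(sch)
  set.seed(31)
  n <- nrow(ft)
  tracks <- do.call(rbind, lapply(1:300, function(id) {
    data.frame(track_id = id, frame = ft$frame, t_s = ft$t_s,
               x_um = 5 + rnorm(n, 0, sigma), y_um = 5 + rnorm(n, 0, sigma))
  }))
  tm <- taco_mobility(tracks, sch, "long")
  expect_equal(tm$mean_um, sigma * sqrt(pi), tolerance = 0.05)
  # freely diffusing molecule: mean jump = sqrt(pi * D * dt)
  D <- 0.5; dtc <- 0.0117
  burst <- ft$frame[ft$label == "burst"][1:10]
  set.seed(32)
  free <- do.call(rbind, lapply(1:400, function(id) {
    steps <- matrix(rnorm(20, 0, sqrt(2 * D * dtc)), ncol = 2)
    pos <- apply(steps, 2, cumsum)
    # keep probe detections co-located so the track classifies as long
    probe <- ft[ft$label == "probe", ]
    rbind(data.frame(track_id = id, frame = probe$frame, t_s = probe$t_s,
                     x_um = 0, y_um = 0),
          data.frame(track_id = id, frame = burst,
                     t_s = ft$t_s[match(burst, ft$frame)],
                     x_um = pos[, 1], y_um = pos[, 2]))
  }))
  tmf <- taco_mobility(free, sch, "long")
  expect_equal(tmf$mean_um, sqrt(pi * D * dtc), tolerance = 0.05)
})

test_that("long-bound molecules are less mobile than short-bound ones", {
  sch_l <- taco_scheme("long", n_cycles = 8)
  sch_s <- taco_scheme("short", n_cycles = 8)
  lb <- long_binder_truth(loc_error_um = 0.02)
  lb$diffusion_components$D_um2_s[1] <- 0.005   # slow bound motion
  sb <- short_binder_truth(loc_error_um = 0.02)
  sb$diffusion_components$D_um2_s[1] <- 0.08    # more mobile short binders
  ml <- simulate_movie(lb, sch_l, n_molecules = 120, seed = 41)
  ms <- simulate_movie(sb, sch_s, n_molecules = 250, seed = 42)
  tl <- taco_mobility(as_tracks(ml), sch_l, "long",
                      confinement_radius = 0.8)
  ts <- taco_mobility(as_tracks(ms), sch_s, "short",
                      confinement_radius = 0.8)
  expect_gt(nrow(tl$per_track), 20)
  expect_gt(nrow(ts$per_track), 20)
  expect_lt(tl$mean_um, ts$mean_um)
})
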