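# minimal trajectory with fixed loop configurations
manual_traj <- function(n_beads, loops_list, resolution_kb = 1) {
  params <- extrusion_params(chain_length = n_beads,
                             resolution_kb = resolution_kb,
                             p_load = 0, p_unload = 0)
  samples <- lapply(loops_list, function(lp) {
    if (is.null(lp)) {
      data.frame(left = integer(0), right = integer(0),
                 stalled_left = logical(0), stalled_right = logical(0))
    } else {
      data.frame(left = lp[, 1], right = lp[, 2],
                 stalled_left = FALSE, stalled_right = FALSE)
    }
  })
  structure(list(samples = samples,
                 sample_times = seq_along(samples) * 4,
                 n_extruders = vapply(samples, nrow, integer(1)),
                 unloaded = data.frame(), params = params),
            class = "lattice_trajectory")
}

test_that("with no extruders P(s) is the bare power law", {
  tr <- manual_traj(100, list(NULL))
  cm <- contacts_from_loops(tr)
  pc <- ps_curve(cm, smooth = 1L)
  expect_equal(pc$p, pc$s_kb^-1.5, tolerance = 1e-12)
  inner <- pc$slope[!is.na(pc$slope)]
  expect_equal(inner, rep(-1.5, length(inner)), tolerance = 1e-9)
})

test_that("effective separations equal the brute-force shortest-path oracle", {
  loops <- rbind(c(10L, 30L), c(15L, 25L), c(40L, 45L))  # nested + disjoint
  tr <- manual_traj(50, list(loops))
  cm <- contacts_from_loops(tr, exponent = -1.5)
  d_oracle <- chromakin:::dense_shortest_paths(
    50, data.frame(left = loops[, 1], right = loops[, 2]))
  expect_equal(cm$mat, pmax(d_oracle, 1)^-1.5, tolerance = 1e-12)
  # the loop anchors are in contact: d_eff = 1
  expect_equal(d_oracle[10, 30], 1)
  expect_equal(cm$mat[10, 30], 1)
})

test_that("adding a loop never increases any effective separation", {
  base <- chromakin:::dense_shortest_paths(
    60, data.frame(left = 20L, right = 35L))
  more <- chromakin:::dense_shortest_paths(
    60, data.frame(left = c(20L, 25L), right = c(35L, 30L)))
  expect_true(all(more <= base + 1e-12))
})

test_that("a single static loop produces a corner peak", {
  tr <- manual_traj(50, list(rbind(c(20L, 35L))))
  cm <- contacts_from_loops(tr)
  # contact at the anchors far exceeds the background at that distance
  expect_equal(cm$mat[20, 35], 1)
  expect_gt(cm$mat[20, 35] / 15^-1.5, 50)
})

test_that("P(s) slope machinery handles flat and noisy power-law maps", {
  n <- 200
  flat <- contact_map(matrix(1, n, n), resolution_kb = 1)
  pf <- ps_curve(flat)
  expect_equal(max(abs(pf$slope), na.rm = TRUE), 0)
  # pure power law with multiplicative noise: slope recovered within 0.05
  d <- pmax(abs(outer(1:n, 1:n, "-")), 1)
  set.seed(81)
  noisy <- d^-1.2 * exp(matrix(rnorm(n * n, 0, 0.05), n, n))
  noisy <- (noisy + t(noisy)) / 2
  pc <- ps_curve(contact_map(noisy, 1), bins_per_decade = 10)
  expect_equal(ps_slope_fit(pc, 5, 150), -1.2, tolerance = 0.04)
})

test_that("slope ratios are elementwise with masking", {
  tr <- manual_traj(100, list(NULL))
  pc <- ps_curve(contacts_from_loops(tr))
  sr <- slope_ratio(pc, pc)
  expect_equal(sr$ratio[!is.na(sr$ratio)],
               rep(1, sum(!is.na(sr$ratio))))
  flat <- ps_curve(contact_map(matrix(1, 50, 50), 1))
  sr0 <- slope_ratio(pc[pc$s_kb <= 49, ], flat)
  expect_true(all(is.na(sr0$ratio)))
})

test_that("O/E and pile-up reduce to identities on structureless maps", {
  n <- 60
  d <- abs(outer(1:n, 1:n, "-"))
  m <- contact_map(pmax(d, 1)^-1.5, 1)
  oe <- oe_map(m)
  expect_equal(max(abs(oe$mat - 1)), 0, tolerance = 1e-12)
  pu <- pileup(m, site_beads = c(20L, 40L), window_kb = 10)
  expect_equal(max(abs(pu - 1)), 0, tolerance = 1e-12)
  expect_equal(insulation_score(pu), 1, tolerance = 1e-12)
  # a single interior site is its own window
  pu1 <- pileup(m, site_beads = 30L, window_kb = 5)
  expect_equal(unclass(pu1)[1:11, 1:11], oe$mat[25:35, 25:35],
               ignore_attr = TRUE)
  # sites at the edge are skipped with a message
  expect_message(pileup(m, site_beads = c(2L, 30L), window_kb = 10),
                 "skipped")
})

test_that("impermeable sites insulate in simulated pile-ups", {
  sites <- c(40L, 80L, 120L, 160L)
  p <- extrusion_params(chain_length = 200, resolution_kb = 10,
                        assoc_rate_per_mb_min = 15, residence_s = 100,
                        ctcf_sites = sites)
  tr <- run_extrusion(p, duration_s = 400, sample_every_s = 40, seed = 82)
  pu <- pileup(contacts_from_loops(tr), sites, window_kb = 100)
  expect_lt(insulation_score(pu), 0.9)
})

test_that("BED intervals map to midpoints at lattice resolution", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chrS\t0\t1000\tsite1\t0\t+",
               "chrS\t12000\t14000\tsite2\t0\t-",
               "chrS\t99000\t99500\tsite3\t0\t+"), bed)
  beads <- bed_to_beads(bed, resolution_kb = 1, chain_length = 50)
  expect_equal(beads, c(1L, 14L))   # midpoints 500 and 13000; 99250 clipped
  beads10 <- bed_to_beads(bed, resolution_kb = 10)
  expect_equal(beads10, c(1L, 2L, 10L))
  unlink(bed)
})

test_that("contact maps round-trip through the text format", {
  tr <- manual_traj(30, list(rbind(c(10L, 20L))))
  cm <- contacts_from_loops(tr)
  f <- tempfile(fileext = ".tsv")
  write_contact_map(cm, f)
  back <- read_contact_map(f)
  expect_equal(back$mat, cm$mat, tolerance = 1e-12)
  expect_equal(back$resolution_kb, 1)
  unlink(f)
})

test_that("Langevin backend: bonded beads equilibrate at the bond length", {
  lp <- langevin_params(eps = 0, k = 40, b = 1)
  run <- langevin_chain(2, lp, n_steps = 4000, dt = 1e-3, sample_every = 10,
                        seed = 83)
  seps <- vapply(run$samples[100:400],
                 function(m) sqrt(sum((m[2, ] - m[1, ])^2)), numeric(1))
  # radial entropy shifts <r> slightly above b: b + 2kT/(k b) at stiff k
  expect_equal(mean(seps), 1 + 2 / 40, tolerance = 0.05)
})

test_that("Langevin backend: an extruder bond holds distant legs together", {
  lp <- langevin_params(eps = 0.3, sigma = 1, cutoff = 2.5, k = 40, b = 1)
  run <- langevin_chain(30, lp, extra_bonds = cbind(5L, 25L),
                        n_steps = 6000, dt = 5e-4, sample_every = 50,
                        seed = 84)
  d <- vapply(run$samples[60:120],
              function(m) sqrt(sum((m[25, ] - m[5, ])^2)), numeric(1))
  expect_lt(mean(d), 2)
})

test_that("Langevin instability is detected and reported", {
  # a time step far beyond the harmonic stability limit, with the
  # displacement cap disabled, must abort rather than return garbage
  lp <- langevin_params(eps = 0, k = 40, b = 1)
  expect_error(langevin_chain(10, lp, n_steps = 200, dt = 10, seed = 85,
                              max_step = Inf),
               "unstable")
})
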