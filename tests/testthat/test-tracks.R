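test_that("zero dose produces no events and negative dose errors", {
  geom <- make_test_geometry(100)
  ev <- generate_tracks(geom, irradiation_config(dose_gy = 0))
  expect_equal(nrow(ev$deposits), 0)
  expect_equal(nrow(ev$radicals), 0)
  expect_equal(ev$delivered_dose_gy, 0)
  expect_error(irradiation_config(dose_gy = -1), "dose")
  expect_error(generate_tracks(assemble_geometry(build_helix_segment(5)),
                               irradiation_config()),
               "container")
})

test_that("delivered dose tracks the target within the one-deposit granularity", {
  geom <- make_test_geometry(10000, histone_spacing = 200)
  # ~2000 Gy in this fibre volume is ~10^4 eV, i.e. a few hundred deposits,
  # so the truncate-or-keep rule holds the overshoot well under 2 percent
  for (s in 1:5) {
    ev <- generate_tracks(geom, irradiation_config(dose_gy = 2000, seed = s))
    expect_lt(abs(ev$delivered_dose_gy - 2000) / 2000, 0.02)
  }
})

test_that("dose conversion follows the eV-to-Gy water mass formula", {
  cm <- container_model() # 528 um^3 nucleus
  dep <- data.frame(energy = 3.295e6)
  expect_equal(dose_from_deposits(dep, cm), 1.0, tolerance = 1e-3)
  expect_equal(dose_from_deposits(dep[0, , drop = FALSE], cm), 0)
  dep2 <- data.frame(energy = c(1e5, 2.5e4))
  expect_equal(dose_from_deposits(transform(dep2, energy = 2 * energy), cm),
               2 * dose_from_deposits(dep2, cm))
})

test_that("deposit counts are Poisson in the linear density", {
  geom <- make_test_geometry(4000)
  cont <- geom$container
  cfg1 <- irradiation_config(mean_linear_density = 15)
  cfg2 <- irradiation_config(mean_linear_density = 30)
  n1 <- n2 <- 0
  reps <- 300
  set.seed(42)
  for (i in seq_len(reps)) {
    d1 <- strandbreakr:::sample_track_deposits(0, 0, cfg1, cont)
    d2 <- strandbreakr:::sample_track_deposits(0, 0, cfg2, cont)
    n1 <- n1 + if (is.null(d1)) 0 else nrow(d1)
    n2 <- n2 + if (is.null(d2)) 0 else nrow(d2)
  }
  # ratio of Poisson totals: 3 sigma band around 2
  se <- 2 * sqrt(1 / n1 + n2 / n1^2)
  expect_lt(abs(n2 / n1 - 2), 3 * se)
})

test_that("radical yield matches the configured G-value within sampling error", {
  geom <- make_test_geometry(10000)
  ev <- generate_tracks(geom, irradiation_config(dose_gy = 3000, seed = 7,
                                                 g_oh_per_100ev = 2.5))
  expected <- sum(ev$deposits$energy) * 2.5 / 100
  expect_lt(abs(nrow(ev$radicals) - expected), 3 * sqrt(expected))
})

test_that("determinism: identical config and seed give identical event lists", {
  geom <- make_test_geometry(3000)
  cfg <- irradiation_config(dose_gy = 1000, seed = 9)
  ev1 <- generate_tracks(geom, cfg)
  ev2 <- generate_tracks(geom, cfg)
  expect_identical(ev1$deposits, ev2$deposits)
  expect_identical(ev1$radicals, ev2$radicals)
})

test_that("radical culling matches a brute-force distance filter", {
  geom <- make_test_geometry(60, histone_spacing = NULL)
  s <- geom$sites

  # radical sitting on a phosphate centre survives
  ph <- s[s$kind == "phosphate", ][1, ]
  r1 <- data.frame(id = 1L, x = ph$x, y = ph$y, z = ph$z, t0 = 0,
                   status = "alive")
  expect_equal(cull_radicals_at_creation(r1, geom)$status, "alive")

  # radical 10 nm away from everything is killed
  r2 <- data.frame(id = 1L, x = 0, y = 0, z = max(s$z) + 10.5, t0 = 0,
                   status = "alive")
  expect_equal(cull_radicals_at_creation(r2, geom)$status, "killed")

  set.seed(5)
  n <- 1000
  spawns <- data.frame(id = seq_len(n),
                       x = runif(n, -15, 15), y = runif(n, -15, 15),
                       z = runif(n, -15, max(s$z) + 15),
                       t0 = 0, status = "alive")
  culled <- cull_radicals_at_creation(spawns, geom, d_kill_nm = 9)
  for (i in seq_len(n)) {
    dmin <- min(sqrt((s$x - spawns$x[i])^2 + (s$y - spawns$y[i])^2 +
                       (s$z - spawns$z[i])^2))
    expect_identical(culled$status[i] == "alive", dmin <= 9)
  }
  expect_error(cull_radicals_at_creation(spawns, geom, d_kill_nm = 0),
               "positive")
})

test_that("fibre containers hit the requested bp density", {
  cm <- fibre_container(10000, bp_density_nm3 = 0.012)
  v <- ellipsoid_volume(cm$nucleus_axes_um[1], cm$nucleus_axes_um[2],
                        cm$nucleus_axes_um[3])
  expect_equal(bp_density(10000, v), 0.012, tolerance = 0.02)
})
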