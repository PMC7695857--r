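test_that("the rate table schema has exactly 53 validated entries", {
  nm <- repair_rate_names()
  expect_length(nm, 53)
  expect_false(any(duplicated(nm)))
  rt <- default_rate_table()
  expect_s3_class(rt, "repair_rate_table")
  expect_error(validate_rate_table(rt[-1]), "missing")
  bad <- c(unclass(rt), extra_constant = 1)
  expect_error(validate_rate_table(bad), "unknown")
  neg <- rt; neg[1] <- -1
  expect_error(validate_rate_table(neg), ">= 0")
})

test_that("null inputs give identically zero trajectories and foci", {
  traj <- simulate_repair(repair_inputs(0, 0), t_end_h = 5)
  expect_true(all(abs(as.matrix(traj[, !names(traj) %in% "time_h"])) < 1e-12))
  foci <- gamma_h2ax_curve(traj, scaled = FALSE)
  expect_true(all(as.matrix(foci[, -1]) == 0))
})

test_that("with all rate constants zero the DSB count is conserved", {
  rt <- default_rate_table(); rt[] <- 0
  traj <- simulate_repair(repair_inputs(12, 3), validate_rate_table(rt),
                          t_end_h = 10)
  expect_equal(traj$n0, rep(15, nrow(traj)), tolerance = 1e-10)
})

test_that("a single reduced pathway matches first-order exponential decay", {
  k <- 0.7
  rt <- default_rate_table(); rt[] <- 0; rt["k_nhej_fin"] <- k
  red <- list(nhej = list(species = character(), forward = character(),
                          reverse = character(), final = "k_nhej_fin"))
  traj <- simulate_repair(repair_inputs(10, 0), validate_rate_table(rt),
                          t_end_h = 6, dt_out_h = 0.25, pathways = red,
                          atol = 1e-12, rtol = 1e-10)
  expected <- 10 * exp(-k * traj$time_h)
  expect_lt(max(abs(traj$n0 - expected) / expected), 1e-6)
})

test_that("the full network keeps states non-negative and N0 non-increasing", {
  traj <- simulate_repair(repair_inputs(30, 8))
  states <- as.matrix(traj[, !grepl("^(time_h|v_)", names(traj))])
  expect_gt(min(states), -1e-9)
  expect_true(all(diff(traj$n0) <= 1e-9))
  expect_equal(max(traj$time_h), 25)
  # fluxes are reported for every pathway
  expect_true(all(c("v_nhej", "v_hr", "v_ssa", "v_micro_ssa",
                    "v_alt_nhej") %in% names(traj)))
})

test_that("the solution is stable under halving the solver tolerances", {
  inp <- repair_inputs(25, 5)
  t1 <- simulate_repair(inp, atol = 1e-9, rtol = 1e-8)
  t2 <- simulate_repair(inp, atol = 5e-10, rtol = 4e-9)
  denom <- pmax(abs(t1$n0), 1e-6)
  expect_lt(max(abs(t1$n0 - t2$n0) / denom), 1e-3)
})

test_that("time-rescaled rates reproduce the dimensionless-form equivalence", {
  # multiplying all kinetic constants by s and shrinking time by s leaves
  # the trajectory invariant
  s <- 3.7
  inp <- repair_inputs(20, 4)
  rt <- default_rate_table()
  kin <- setdiff(repair_rate_names(),
                 c("k_h2ax_vmax", "k_h2ax_km", "k_h2ax_phos",
                   "k_h2ax_deph", "alpha_dsb_per_gy"))
  rt2 <- rt; rt2[kin] <- rt[kin] * s
  a <- simulate_repair(inp, rt, t_end_h = 10, dt_out_h = 0.5)
  b <- simulate_repair(inp, validate_rate_table(rt2), t_end_h = 10 / s,
                       dt_out_h = 0.5 / s)
  expect_equal(b$n0, a$n0, tolerance = 1e-6)
})

test_that("the gamma-H2AX curve rises, decays, and plateaus with irreparable damage", {
  inp <- repair_inputs(20, 3) # irreparable fraction 3/23
  # integrate well past the usual 25 h window so the reparable signal and
  # ATM activity have fully decayed and only the irreparable plateau remains
  traj <- simulate_repair(inp, t_end_h = 100)
  rt <- default_rate_table()

  # Michaelis-Menten kernel: half of Vmax at the Michaelis constant
  expect_equal(strandbreakr:::mm_transform(rt[["k_h2ax_km"]],
                                           rt[["k_h2ax_vmax"]],
                                           rt[["k_h2ax_km"]]),
               rt[["k_h2ax_vmax"]] / 2)

  raw <- gamma_h2ax_curve(traj, scaled = FALSE)
  late <- tail(raw$gh2ax, 1)
  f <- inp$irreparable_fraction
  plateau <- strandbreakr:::mm_transform(f * traj$n0[1],
                                         rt[["k_h2ax_vmax"]],
                                         rt[["k_h2ax_km"]])
  expect_equal(late, plateau, tolerance = 0.05)
  expect_gt(late, 0)
  # with no irreparable component the curve relaxes far below its peak
  raw0 <- gamma_h2ax_curve(traj, irreparable_fraction = 0, scaled = FALSE)
  expect_lt(tail(raw0$gh2ax, 1), 0.1 * max(raw0$gh2ax))
  # scaled mode normalises to the maximum
  sc <- gamma_h2ax_curve(traj)
  expect_equal(max(sc$gh2ax), 1)
  expect_error(gamma_h2ax_curve(traj, species_map = list(
    ku = "nope", dnapkcs = "nope", rpa = "nope", rad51 = "nope",
    atm = "nope")), "missing")
})

test_that("degree of protection follows the log-survival formula", {
  expect_equal(degree_of_protection(0.1, 0.1), 0)
  expect_equal(degree_of_protection(0.1, 0.4), 0.602, tolerance = 1e-3)
  expect_equal(degree_of_protection(0.2, 1), 1)
  expect_error(degree_of_protection(1, 0.5), "between")
  expect_error(degree_of_protection(0.5, 0), "0, 1")
})

test_that("the reciprocal DP fit recovers exact and noisy parameters", {
  x <- c(0.125, 0.25, 0.5, 1)
  dp <- 1 / (2 / x + 1.25)
  f <- fit_max_protection(x, dp)
  expect_equal(f$k, 2, tolerance = 1e-10)
  expect_equal(f$y_inf, 1.25, tolerance = 1e-10)
  expect_equal(f$max_dp, 0.8, tolerance = 1e-10)
  expect_equal(f$status, "ok")

  expect_error(fit_max_protection(c(0.5, 0.5), c(0.2, 0.3)), "distinct")

  # parameter recovery from noisy synthetic data within 3 standard errors;
  # Gaussian noise sits on the reciprocal (regression) scale where the
  # least-squares standard errors are exact
  set.seed(12)
  x8 <- seq(0.1, 1.5, length.out = 8)
  inv_true <- 2 / x8 + 1.25
  ok <- 0
  for (r in 1:20) {
    dp_noisy <- 1 / (inv_true + rnorm(8, 0, 0.02))
    fr <- fit_max_protection(x8, dp_noisy)
    if (abs(fr$k - 2) <= 3 * fr$se_k &&
        abs(fr$y_inf - 1.25) <= 3 * fr$se_y_inf) ok <- ok + 1
  }
  expect_gte(ok, 17) # ~99.7% nominal coverage, allow a couple of misses
})

test_that("rate tables round-trip through JSON", {
  rt <- default_rate_table()
  path <- withr::local_tempfile(fileext = ".json")
  write_rate_table(rt, path)
  back <- read_rate_table(path)
  expect_equal(unclass(back), unclass(rt))
})
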