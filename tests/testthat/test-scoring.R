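test_that("the direct-break probability is the documented linear ramp", {
  expect_equal(direct_break_probability(4), 0)
  expect_equal(direct_break_probability(40), 1)
  expect_equal(direct_break_probability(21.25), 0.5)
  expect_equal(direct_break_probability(5), 0)
  expect_equal(direct_break_probability(37.5), 1)
  expect_error(direct_break_probability(-1), "non-negative")
  # monotone over random energies
  e <- sort(runif(100, 0, 50))
  expect_true(all(diff(direct_break_probability(e)) >= 0))
})

test_that("energy accumulation assigns deposits to the nearest unit within R_dir", {
  geom <- make_test_geometry(1, histone_spacing = NULL)
  ph <- geom$sites[geom$sites$kind == "phosphate" &
                     geom$sites$strand == 0, ]
  # radially 0.4 nm away from the phosphate: beyond the 0.35 nm radius...
  dir <- c(ph$x, ph$y, 0) / sqrt(ph$x^2 + ph$y^2)
  far <- data.frame(x = ph$x + 0.4 * dir[1], y = ph$y + 0.4 * dir[2],
                    z = ph$z, energy = 30)
  tab <- accumulate_direct_energy(far, geom)
  expect_equal(nrow(tab), 0)
  # ...but 0.1 nm away it is scored, entirely on that unit
  near <- data.frame(x = ph$x + 0.1 * dir[1], y = ph$y + 0.1 * dir[2],
                     z = ph$z, energy = 30)
  tab <- accumulate_direct_energy(near, geom)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$energy, 30)
  expect_equal(tab$strand, ph$strand)
})

test_that("a 500-deposit cloud matches the brute-force nearest-within-radius scan", {
  geom <- make_test_geometry(120, histone_spacing = NULL)
  set.seed(17)
  dep <- data.frame(x = runif(500, -2, 2), y = runif(500, -2, 2),
                    z = runif(500, -1, 120 * 0.34 + 1),
                    energy = rexp(500, 1 / 40))
  got <- accumulate_direct_energy(dep, geom)

  # oracle: per-deposit exhaustive nearest backbone site, pooled by unit
  want <- new.env()
  for (i in seq_len(nrow(dep))) {
    nb <- brute_nearest_backbone(c(dep$x[i], dep$y[i], dep$z[i]), geom$sites)
    if (nb$distance <= 0.35) {
      key <- paste(nb$site$segment_id, nb$site$bp_index, nb$site$strand)
      want[[key]] <- (if (is.null(want[[key]])) 0 else want[[key]]) +
        dep$energy[i]
    }
  }
  expect_equal(nrow(got), length(ls(want)))
  for (j in seq_len(nrow(got))) {
    key <- paste(got$segment_id[j], got$bp_index[j], got$strand[j])
    expect_equal(got$energy[j], want[[key]], tolerance = 1e-12)
  }
})

test_that("direct Bernoulli scoring follows the ramp probabilities", {
  units <- data.frame(segment_id = 1L, bp_index = 0:9999,
                      strand = 0L, energy = 50)
  withr::with_seed(1, {
    all_hit <- score_direct_breaks(units)
  })
  expect_equal(nrow(all_hit), 10000) # p = 1 everywhere
  expect_true(all(all_hit$source == "direct"))

  units$energy <- 21.25
  withr::with_seed(2, {
    half <- score_direct_breaks(units)
  })
  # binomial 3 sigma around p = 0.5 at n = 10^4
  expect_lt(abs(nrow(half) / 10000 - 0.5), 3 * sqrt(0.25 / 10000))

  expect_equal(nrow(score_direct_breaks(units[0, , drop = FALSE])), 0)
})

test_that("indirect scoring hits the configured probability and is monotone in P_OH", {
  enc <- data.frame(radical_id = 1:10000, segment_id = 1L,
                    bp_index = 1:10000, strand = 0L, kind = "phosphate",
                    time_ns = 1)
  none <- score_indirect_breaks(enc, scoring_params(p_oh_break = 0), seed = 3)
  expect_equal(nrow(none), 0)
  all_b <- score_indirect_breaks(enc, scoring_params(p_oh_break = 1), seed = 3)
  expect_equal(nrow(all_b), 10000)

  got <- score_indirect_breaks(enc, scoring_params(), seed = 3)
  p <- 0.405
  expect_lt(abs(nrow(got) / 10000 - p), 3 * sqrt(p * (1 - p) / 10000))

  # paired-seed monotonicity: successes at lower p are a subset
  lo <- score_indirect_breaks(enc, scoring_params(p_oh_break = 0.2), seed = 3)
  key_lo <- paste(lo$bp_index, lo$strand)
  key_hi <- paste(got$bp_index, got$strand)
  expect_true(all(key_lo %in% key_hi))
})

test_that("duplicate encounters collapse and direct wins over indirect", {
  enc <- data.frame(radical_id = 1:4, segment_id = 1L,
                    bp_index = c(5L, 5L, 9L, 9L), strand = c(0L, 0L, 1L, 1L),
                    kind = "phosphate", time_ns = 1)
  ind <- score_indirect_breaks(enc, scoring_params(p_oh_break = 1), seed = 1)
  expect_equal(nrow(ind), 2) # collapsed per nucleotide

  dir <- make_breaks(5, 0, "direct")
  comb <- combine_breaks(dir, ind)
  expect_equal(nrow(comb), 2)
  expect_equal(comb$source[comb$bp_index == 5], "direct")
  expect_equal(comb$source[comb$bp_index == 9], "indirect")
})
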