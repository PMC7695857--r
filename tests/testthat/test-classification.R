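test_that("cluster segmentation splits on strictly more than 100 unbroken bp", {
  two <- segment_clusters(make_breaks(c(0, 102), c(0, 0)))
  expect_length(two, 2)
  one <- segment_clusters(make_breaks(c(0, 101), c(0, 0)))
  expect_length(one, 1)
  expect_length(segment_clusters(make_breaks(integer(), integer())), 0)

  # clusters never span segments even at bp distance 0
  b <- rbind(make_breaks(5, 0, segment = 1L), make_breaks(5, 0, segment = 2L))
  expect_length(segment_clusters(b), 2)

  # every break lands in exactly one cluster and spans are disjoint
  set.seed(30)
  b <- make_breaks(sort(sample.int(5000, 60)), sample(0:1, 60, TRUE))
  cl <- segment_clusters(b)
  expect_equal(sum(vapply(cl, function(x) nrow(x$breaks), integer(1))),
               nrow(unique(b)))
  spans <- t(vapply(cl, function(x) range(x$breaks$bp_index), numeric(2)))
  expect_true(all(spans[-1, 1] > spans[-nrow(spans), 2]))
})

test_that("DSB pairing respects the distance window and maximum cardinality", {
  expect_equal(nrow(pair_dsbs(as_cluster(make_breaks(c(100, 105), c(0, 1))))), 1)
  expect_equal(nrow(pair_dsbs(as_cluster(make_breaks(c(100, 115), c(0, 1))))), 0)
  expect_equal(nrow(pair_dsbs(as_cluster(make_breaks(c(100, 110), c(0, 1))))), 1)

  # the spec-breaking counterexample for naive smallest-gap-first greedy:
  # strand 0 at {0, 10}, strand 1 at {10, 20} admits two DSBs
  tricky <- as_cluster(make_breaks(c(0, 10, 10, 20), c(0, 0, 1, 1)))
  expect_equal(nrow(pair_dsbs(tricky)), 2)

  set.seed(99)
  for (i in 1:200) {
    b <- random_cluster()
    expect_equal(nrow(pair_dsbs(as_cluster(b))), brute_max_matching(b),
                 info = paste("cluster", i))
  }
})

test_that("complexity classes pick the most complex applicable label", {
  # DSB plus one extra same-strand break 3 bp away
  dsbp <- as_cluster(make_breaks(c(100, 103, 105), c(0, 0, 1)))
  expect_equal(complexity_class(dsbp), "DSBp")
  # two DSBs
  dsbpp <- as_cluster(make_breaks(c(100, 101, 150, 152), c(0, 1, 0, 1)))
  expect_equal(complexity_class(dsbpp), "DSBpp")
  # a single break
  expect_equal(complexity_class(as_cluster(make_breaks(7, 0))), "SSB_cluster")
  # lone DSB
  expect_equal(complexity_class(as_cluster(make_breaks(c(100, 104), c(0, 1)))),
               "DSB")
  # extra break farther than d_DSB from both paired breaks: still plain DSB
  far <- as_cluster(make_breaks(c(100, 104, 150), c(0, 1, 0)))
  expect_equal(complexity_class(far), "DSB")
})

test_that("source classes implement the indirect-removal test", {
  dd <- as_cluster(make_breaks(c(100, 104), c(0, 1), c("direct", "direct")))
  expect_equal(source_class(dd), "DSBdir")
  ii <- as_cluster(make_breaks(c(100, 104), c(0, 1),
                               c("indirect", "indirect")))
  expect_equal(source_class(ii), "DSBind")
  # direct+indirect pair with nothing else: removal leaves no DSB
  hyb <- as_cluster(make_breaks(c(100, 104), c(0, 1),
                                c("direct", "indirect")))
  expect_equal(source_class(hyb), "DSBhyb")
  # an all-direct DSB survives removal of a nearby indirect SSB
  mix <- as_cluster(make_breaks(c(100, 104, 108), c(0, 1, 0),
                                c("direct", "direct", "indirect")))
  expect_equal(source_class(mix), "DSBmix")
  expect_error(source_class(as_cluster(make_breaks(5, 0))), "DSB")

  # partition property: every DSB cluster gets exactly one class, and
  # all-direct relabelling forces DSBdir
  set.seed(41)
  for (i in 1:100) {
    b <- random_cluster()
    cl <- as_cluster(b)
    if (nrow(pair_dsbs(cl)) == 0) next
    expect_true(source_class(cl) %in%
                  c("DSBdir", "DSBind", "DSBhyb", "DSBmix"))
    b2 <- b; b2$source <- "direct"
    expect_equal(source_class(as_cluster(b2)), "DSBdir")
  }
})

test_that("the distant-DSB filter keeps only well-separated DSBs", {
  expect_equal(distant_dsb_filter(c(0, 20000)), 2)
  expect_equal(distant_dsb_filter(c(0, 5000, 20000)), 2)
  expect_equal(distant_dsb_filter(numeric()), 0)
  expect_equal(distant_dsb_filter(1234), 1)
  expect_equal(distant_dsb_filter(c(0, 10000)), 2) # "at least" is inclusive
})

test_that("yield summaries follow the complex-DSB bookkeeping", {
  # three DSBp clusters and two DSBpp clusters -> N_cDSB = 3 + 2*2 = 7
  mk_dsbp <- function(off) make_breaks(off + c(0, 3, 5), c(0, 0, 1))
  mk_dsbpp <- function(off) make_breaks(off + c(0, 1, 50, 52),
                                        c(0, 1, 0, 1))
  b <- rbind(mk_dsbp(0), mk_dsbp(500), mk_dsbp(1000),
             mk_dsbpp(2000), mk_dsbpp(3000))
  sm <- classify_breaks(b, dose_gy = 1, genome_gbp = 1)
  expect_equal(sm$n_dsbp, 3)
  expect_equal(sm$n_dsbpp, 2)
  expect_equal(sm$n_cdsb, 7)
  expect_equal(sm$n_ncdsb, 0)
  expect_equal(sm$n_dsbdir + sm$n_dsbind + sm$n_dsbhyb + sm$n_dsbmix,
               sm$n_dsb)

  # 100 unpaired breaks at 1 Gy over 0.01 Gbp -> 10^4 per Gy per Gbp
  ssb <- make_breaks(seq(0, by = 200, length.out = 100), 0)
  sm2 <- classify_breaks(ssb, dose_gy = 1, genome_gbp = 0.01)
  expect_equal(sm2$ssb_per_gy_gbp, 1e4)
  expect_true(is.na(sm2$ssb_dsb_ratio))
  expect_true(is.na(sm2$scavengeable_fraction))
  expect_error(classify_breaks(ssb, dose_gy = 0, genome_gbp = 1), "positive")
})

test_that("the scavengeable fraction weighs indirect and hybrid DSBs only", {
  x <- list(n_dsbdir = 5, n_dsbmix = 1, n_dsbind = 3, n_dsbhyb = 1)
  expect_equal(scavengeable_fraction(x), 0.4)
  expect_equal(scavengeable_fraction(list(n_dsbdir = 7, n_dsbmix = 0,
                                          n_dsbind = 0, n_dsbhyb = 0)), 0)
  expect_equal(scavengeable_fraction(list(n_dsbdir = 0, n_dsbmix = 0,
                                          n_dsbind = 4, n_dsbhyb = 0)), 1)
  expect_true(is.na(scavengeable_fraction(list(n_dsbdir = 0, n_dsbmix = 0,
                                               n_dsbind = 0, n_dsbhyb = 0))))
})

test_that("denser break patterns do not inflate the SSB/DSB ratio", {
  # paired-seed stochastic trend: concentrating the same number of breaks
  # into tighter windows can only help DSB formation
  set.seed(77)
  ratios <- sapply(c(2000L, 200L), function(window) {
    rs <- replicate(30, {
      b <- unique(make_breaks(sample.int(window, 30, TRUE),
                              sample(0:1, 30, TRUE)))
      sm <- classify_breaks(b, dose_gy = 1, genome_gbp = 1)
      c(sm$n_ssb, sm$n_dsb)
    })
    sum(rs[1, ]) / sum(rs[2, ])
  })
  expect_gte(ratios[1], ratios[2])
})
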