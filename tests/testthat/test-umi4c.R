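test_that("distance filter is inclusive at 500 bp and 1 Mb", {
  # fragments of 1000 bp; bait placed so midpoints land exactly on bounds
  n <- 2101
  prof <- make_profile(rep(5L, n), frag = 1000L, bait_pos = 1050500.5)
  # construct explicit cases instead: midpoint distances from bait
  mid <- (prof$start + prof$end) / 2
  d <- abs(mid - attr(prof, "bait_pos"))
  kept <- distance_filter(prof)
  mid_kept <- (kept$start + kept$end) / 2
  d_kept <- abs(mid_kept - attr(kept, "bait_pos"))
  expect_true(all(d_kept >= 500 & d_kept <= 1e6))
  # brute-force equality of the retained set
  expect_equal(mid_kept, mid[d >= 500 & d <= 1e6])

  # exact-boundary fragments: midpoints at 400, 500 and 1e6 from the bait
  p2 <- contact_profile(
    data.frame(chrom = "chrS",
               start = c(0, 2100, 1001500), end = c(2000, 4100, 1003500)),
    c(1L, 2L, 3L), bait_pos = 1400, condition = "x"
  )
  # midpoints 1000, 3100, 1002500 -> distances 400, 1700, 1001100
  f2 <- distance_filter(p2)
  expect_equal(f2$umi_count, 2L)
  p3 <- contact_profile(
    data.frame(chrom = "chrS", start = c(0, 10000), end = c(1000, 11000)),
    c(4L, 5L), bait_pos = 1000500, condition = "x"
  )
  # distances: |500 - 1000500| = 1e6 (inclusive), |10500 - 1000500| = 990000
  expect_equal(distance_filter(p3)$umi_count, c(4L, 5L))
  p4 <- contact_profile(
    data.frame(chrom = "chrS", start = 0, end = 1000),
    6L, bait_pos = 1000501, condition = "x"
  )
  expect_equal(nrow(distance_filter(p4)), 0)  # 1e6 + 1 bp: excluded
  expect_error(distance_filter(p2, min_bp = 10, max_bp = 5), "config")
})

test_that("smoothing reproduces hand-computed truncated moving averages", {
  prof <- make_profile(c(0L, 0L, 9L, 0L, 0L))
  expect_equal(smooth_profile(prof, 1L), c(0, 0, 1, 0, 0))
  expect_equal(smooth_profile(prof, 3L), c(0, 1 / 3, 1 / 3, 1 / 3, 0))
  flat <- make_profile(rep(4L, 10))
  expect_equal(smooth_profile(flat, 5L), rep(0.1, 10))
  expect_error(smooth_profile(prof, 2L), "odd")
})

test_that("domainogram differences vanish for identical profiles and locate a boost", {
  set.seed(1)
  counts <- rpois(20, 50)
  a <- make_profile(counts, condition = "t0")
  b <- make_profile(counts, condition = "t168")
  dg0 <- domainogram(a, b, scales = c(1L, 3L, 5L))
  expect_equal(dim(dg0), c(3L, 20L))
  expect_true(all(dg0 == 0))

  boosted <- counts
  boosted[12] <- boosted[12] + 300L
  b2 <- make_profile(boosted, condition = "t168")
  dg <- domainogram(a, b2, scales = c(1L, 3L, 5L))
  # scale 1 equals the raw normalised difference
  expect_equal(dg[1, ],
               boosted / sum(boosted) - counts / sum(counts))
  expect_equal(which.max(dg[1, ]), 12L)
  # the peak attenuates with scale
  expect_gt(dg[1, 12], dg[2, 12])
  expect_gt(dg[2, 12], dg[3, 12])
  expect_error(domainogram(a, make_profile(counts[1:10])), "grid")
  expect_error(domainogram(a, b, scales = 2L), "odd|config")
})

test_that("contact test matches the closed-form Pearson chi-square", {
  # equal proportions: chi2 = 0, p = 1
  a <- make_profile(c(50L, 950L))
  b <- make_profile(c(50L, 950L), condition = "t168")
  res <- contact_test(a, b, 1L)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  expect_equal(res$p_adj, res$p)

  a2 <- make_profile(c(10L, 990L))
  b2 <- make_profile(c(60L, 940L), condition = "t168")
  res2 <- contact_test(a2, b2, 1L)
  oracle <- chi2_oracle(10, 990, 60, 940)
  expect_equal(res2$chi2, oracle$stat, tolerance = 1e-12)
  expect_equal(res2$p, oracle$p, tolerance = 1e-12)
  # symmetric under swapping the conditions
  res2r <- contact_test(b2, a2, 1L)
  expect_equal(res2r$chi2, res2$chi2)
  expect_equal(res2r$p, res2$p)

  # degenerate margins are refused with a message
  z <- make_profile(c(0L, 100L))
  expect_error(contact_test(z, make_profile(c(0L, 50L)), 1L), "margin")

  # multiple windows get BH adjustment across windows
  set.seed(9)
  pa <- make_profile(rpois(30, 40))
  pb <- make_profile(rpois(30, 40), condition = "t168")
  multi <- contact_test(pa, pb, list(1:3, 10:12, 20:22))
  expect_equal(multi$p_adj, p.adjust(multi$p, "BH"))
})

test_that("null contact tests reject near the nominal rate", {
  set.seed(4)
  n_sims <- 150
  rej <- 0L
  for (s in seq_len(n_sims)) {
    sp <- simulate_contact_pair(n_fragments = 101L, mean_depth = 500,
                                loop_offset = NULL, seed = s)
    pa <- distance_filter(sp$a); pb <- distance_filter(sp$b)
    w <- sample(nrow(pa), 1)
    if (contact_test(pa, pb, w)$p < 0.05) rej <- rej + 1L
  }
  rate <- rej / n_sims
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_sims))
})
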