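test_that("delta_beta is the difference of endpoint replicate means", {
  E <- rbind(c(0.90, 0.9, 0.9, 0.9, 0.9, 0.9, 0.20),
             c(0.55, 0.55, 0.55, 0.55, 0.55, 0.55, 0.55))
  bm <- make_bm(E, reps = 2, probe_ids = c("cgA", "cgB"))
  expect_equal(delta_beta(bm, "cgA"), -0.70)
  expect_equal(delta_beta(bm, "cgB"), 0)
  expect_error(delta_beta(bm, "cgA", t_to = 96), "96")
  expect_error(delta_beta(bm, "nope"), "nope")
})

test_that("the magnitude filter is inclusive at the 0.66 boundary", {
  # 1 - (1 - 0.66) recovers the 0.66 double exactly (Sterbenz), so the
  # computed |delta beta| equals the threshold bit-for-bit
  at <- 1 - 0.66
  E <- rbind(c(1, 1, 1, 1, 1, 1, at),        # exactly at the threshold
             c(1, 1, 1, 1, 1, 1, at + 0.01), # just below
             c(0.5, rep(0.5, 5), 0.5))       # null
  bm <- make_bm(E, reps = 3, probe_ids = c("at", "below", "null"))
  res <- call_dmcs(bm)
  expect_true(res$passes[res$probe_id == "at"])
  expect_false(res$passes[res$probe_id == "below"])
  expect_false(res$passes[res$probe_id == "null"])
  expect_equal(abs(res$delta_beta[res$probe_id == "at"]), 0.66)
  # an unattainable magnitude bound admits nothing
  expect_equal(sum(call_dmcs(bm, delta_threshold = 1.01)$passes), 0)
})

test_that("degenerate probes follow the p-value conventions", {
  E <- rbind(rep(0.5, 7),                  # no change, no variance -> p = 1
             c(0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.1)) # shift, no variance
  bm <- make_bm(E, reps = 3, probe_ids = c("flat", "shift"))
  expect_equal(test_probe(bm, "flat", method = "welch_t"), 1)
  expect_equal(test_probe(bm, "flat", method = "anova_f"), 1)
  p_shift <- test_probe(bm, "shift", method = "welch_t")
  expect_gt(p_shift, 0)
  expect_lt(p_shift, 1e-100)
})

test_that("Welch p-values match stats::t.test to 1e-10 on random fixtures", {
  set.seed(101)
  for (i in 1:100) {
    reps <- sample(2:5, 1)
    g0 <- runif(reps, 0.2, 0.9)
    g1 <- runif(reps, 0.05, 0.8)
    E <- matrix(0.5, 1, 7)
    bm0 <- make_bm(E, reps = reps)
    bm0$beta[1, bm0$samples$condition == "transdiff" &
               bm0$samples$timepoint_h == 0] <- g0
    bm0$beta[1, bm0$samples$condition == "transdiff" &
               bm0$samples$timepoint_h == 168] <- g1
    expect_equal(test_probe(bm0, "cg001", method = "welch_t"),
                 t.test(g0, g1)$p.value, tolerance = 1e-10)
  }
})

test_that("one-way F p-values match stats::oneway.test on random fixtures", {
  set.seed(202)
  for (i in 1:50) {
    reps <- 3
    vals <- matrix(runif(7 * reps, 0.1, 0.9), nrow = 1)
    bm <- make_bm(matrix(0.5, 1, 7), reps = reps)
    td <- bm$samples$condition == "transdiff"
    bm$beta[1, td] <- vals
    grp <- factor(bm$samples$timepoint_h[td])
    expect_equal(test_probe(bm, "cg001", method = "anova_f"),
                 oneway.test(as.numeric(vals) ~ grp,
                             var.equal = TRUE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("noiseless planted mixtures are recovered exactly with directions", {
  st <- generate_dataset(sim_config(
    n_probes = 110L, n_planted_hypo = 10L, n_planted_hyper = 4L,
    beta_noise_sd = 0, n_genes = 30L, n_interactions = 10L,
    n_fragments = 1000L, umi4c_flank_frags = 50L, seed = 77
  ))
  res <- call_dmcs(st$beta)
  called <- res$probe_id[res$passes]
  expect_setequal(called, st$truth$dmc$probe_id)
  dir_called <- setNames(res$direction[res$passes], res$probe_id[res$passes])
  expect_equal(unname(dir_called[st$truth$dmc$probe_id]),
               st$truth$dmc$direction)
})

test_that("pass sets are monotone in both thresholds and order-invariant", {
  st <- generate_dataset(sim_config(
    n_probes = 400L, n_planted_hypo = 20L, n_planted_hyper = 2L,
    n_genes = 50L, n_interactions = 20L, n_fragments = 1000L,
    umi4c_flank_frags = 50L, seed = 13
  ))
  bm <- st$beta
  pass_at <- function(p_thr, d_thr) {
    r <- call_dmcs(bm, p_threshold = p_thr, delta_threshold = d_thr)
    r$probe_id[r$passes]
  }
  expect_true(all(pass_at(0.01, 0.66) %in% pass_at(0.05, 0.66)))
  expect_true(all(pass_at(0.05, 0.70) %in% pass_at(0.05, 0.66)))
  # shuffling probes and samples leaves per-probe results unchanged
  perm_r <- sample(nrow(bm$beta)); perm_c <- sample(ncol(bm$beta))
  bm2 <- beta_matrix(bm$beta[perm_r, perm_c], bm$samples[perm_c, ])
  r1 <- call_dmcs(bm)
  r2 <- call_dmcs(bm2)
  r2 <- r2[match(r1$probe_id, r2$probe_id), ]
  expect_equal(r1$delta_beta, r2$delta_beta)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$passes, r2$passes)
})

test_that("BH-adjusted filtering is at least as strict as unadjusted", {
  st <- generate_dataset(sim_config(
    n_probes = 400L, n_planted_hypo = 20L, n_planted_hyper = 0L,
    n_genes = 50L, n_interactions = 20L, n_fragments = 1000L,
    umi4c_flank_frags = 50L, seed = 14
  ))
  raw <- call_dmcs(st$beta, adjust = "none")
  bh <- call_dmcs(st$beta, adjust = "bh")
  expect_true(all(bh$q_value >= bh$p_value))
  expect_true(all(bh$probe_id[bh$passes] %in% raw$probe_id[raw$passes]))
})

test_that("endpoint methylation of planted DMCs is macrophage-like", {
  E <- rbind(c(0.9, 0.85, 0.7, 0.5, 0.3, 0.2, 0.15),
             c(0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.80))
  # probe 1 converges on the positive control; probe 2 stays at the negative
  bm <- make_bm(E, reps = 2, neg = c(0.9, 0.8), pos = c(0.15, 0.1),
                probe_ids = c("conv", "stay"))
  cc <- control_concordance(bm, c("conv", "stay"))
  expect_true(cc$macrophage_like[cc$probe_id == "conv"])
  expect_false(cc$macrophage_like[cc$probe_id == "stay"])
  expect_equal(cc$dist_to_positive[cc$probe_id == "conv"], 0)

  # planted-truth recovery across seeds on generated studies
  fr <- vapply(1:5, function(s) {
    st <- generate_dataset(sim_config(
      n_probes = 300L, n_planted_hypo = 30L, n_planted_hyper = 2L,
      n_genes = 60L, n_interactions = 20L, n_fragments = 1000L,
      umi4c_flank_frags = 50L, seed = s
    ))
    cc <- control_concordance(st$beta, st$truth$dmc$probe_id)
    attr(cc, "fraction_macrophage_like")
  }, numeric(1))
  expect_gte(mean(fr), 0.95)

  no_ctrl <- bm
  no_ctrl$samples$condition[no_ctrl$samples$condition == "positive_control"] <-
    "negative_control"
  expect_error(control_concordance(no_ctrl, "conv"), "positive_control")
})
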