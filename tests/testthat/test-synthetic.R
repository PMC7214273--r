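small_cfg <- function(...) {
  sim_config(n_probes = 300L, n_planted_hypo = 30L, n_planted_hyper = 3L,
             n_genes = 80L, n_interactions = 40L, n_fragments = 2000L,
             umi4c_flank_frags = 100L, ...)
}

test_that("generation is bit-identical under a fixed seed", {
  a <- generate_dataset(small_cfg(seed = 5))
  b <- generate_dataset(small_cfg(seed = 5))
  expect_identical(a$beta$beta, b$beta$beta)
  expect_identical(a$expr, b$expr)
  expect_identical(as.data.frame(a$manifest), as.data.frame(b$manifest))
  expect_identical(as.data.frame(a$interactions), as.data.frame(b$interactions))
  expect_identical(a$contacts$a$umi_count, b$contacts$a$umi_count)
  expect_identical(truth_report(a$truth), truth_report(b$truth))
  c_ <- generate_dataset(small_cfg(seed = 6))
  expect_false(identical(a$beta$beta, c_$beta$beta))
})

test_that("noiseless planted probes clear the endpoint beta-change bound", {
  st <- generate_dataset(small_cfg(beta_noise_sd = 0, seed = 2))
  hypo <- st$truth$dmc$probe_id[st$truth$dmc$direction == "hypo"]
  hyper <- st$truth$dmc$probe_id[st$truth$dmc$direction == "hyper"]
  d_hypo <- vapply(hypo, function(p) delta_beta(st$beta, p), numeric(1))
  d_hyper <- vapply(hyper, function(p) delta_beta(st$beta, p), numeric(1))
  expect_true(all(d_hypo <= -0.45))  # plateau-bound consequence
  expect_true(all(d_hypo <= -0.66))  # design: expected change clears the filter
  expect_true(all(d_hyper >= 0.66))
  # null probes are exactly constant without noise
  nulls <- setdiff(rownames(st$beta$beta), c(hypo, hyper))
  d_null <- vapply(nulls, function(p) delta_beta(st$beta, p), numeric(1))
  expect_true(all(d_null == 0))
})

test_that("null delta-beta distribution is centred with sd ~ noise * sqrt(2)", {
  sd0 <- 0.03
  st <- generate_dataset(sim_config(
    n_probes = 2000L, n_planted_hypo = 0L, n_planted_hyper = 0L,
    replicates_per_timepoint = 1L, beta_noise_sd = sd0, seed = 31
  ))
  sm <- st$beta$samples
  c0 <- which(sm$condition == "transdiff" & sm$timepoint_h == 0)
  c1 <- which(sm$condition == "transdiff" & sm$timepoint_h == 168)
  d <- st$beta$beta[, c1] - st$beta$beta[, c0]
  target_sd <- sd0 * sqrt(2)
  n <- length(d)
  expect_lt(abs(mean(d)), 3 * target_sd / sqrt(n))
  expect_lt(abs(sd(d) - target_sd), 3 * target_sd / sqrt(2 * n))
})

test_that("planted expression links have the planted correlation signs", {
  st <- generate_dataset(small_cfg(seed = 9, expr_noise_sd = 0.05))
  links <- rbind(st$truth$local_links[, c("probe_id", "gene", "sign")],
                 setNames(st$truth$distal_links[, c("probe_id", "gene", "sign")],
                          c("probe_id", "gene", "sign")))
  for (i in seq_len(nrow(links))) {
    x <- meth3dlink:::.probe_timecourse(st$beta, links$probe_id[i])
    y <- st$expr[links$gene[i], ]
    r <- cor(as.numeric(x), as.numeric(y))
    if (links$sign[i] %in% c("activation", "enhancer")) {
      expect_lt(r, 0)
    } else {
      expect_gt(r, 0)
    }
  }
})

test_that("truth report rows recount the planted configuration", {
  cfg <- small_cfg(seed = 4)
  st <- generate_dataset(cfg)
  tr <- truth_report(st$truth)
  expect_equal(sum(tr$kind == "dmc"),
               cfg$n_planted_hypo + cfg$n_planted_hyper)
  expect_equal(sum(tr$kind == "local_link"),
               cfg$n_local_activation + cfg$n_local_repression)
  expect_equal(sum(tr$kind == "distal_link"),
               cfg$n_distal_enhancer + cfg$n_distal_silencer)
  expect_equal(sum(tr$kind == "ctcf"),
               min(4L, cfg$n_distal_enhancer + cfg$n_distal_silencer))
  expect_equal(sum(tr$kind == "loop"), 1L)

  empty <- generate_dataset(sim_config(
    n_probes = 50L, n_planted_hypo = 0L, n_planted_hyper = 0L,
    n_genes = 10L, n_interactions = 5L, n_fragments = 500L,
    umi4c_flank_frags = 50L, seed = 1
  ))
  expect_equal(nrow(truth_report(empty$truth)), 0L)
})

test_that("planted distal probes sit inside their recorded other-ends", {
  st <- generate_dataset(small_cfg(seed = 12))
  dl <- st$truth$distal_links
  for (i in seq_len(nrow(dl))) {
    j <- match(dl$interaction_id[i], st$interactions$id)
    pos <- st$manifest$pos[match(dl$probe_id[i], st$manifest$probe_id)]
    expect_true(st$interactions$otherEnd_start[j] <= pos - 1 &&
                  pos - 1 < st$interactions$otherEnd_end[j])
    expect_true(dl$gene[i] %in% bait_genes(st$interactions,
                                           dl$interaction_id[i]))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_probes = 10, n_planted_hypo = 20),
               "n_planted")
  expect_error(sim_config(beta_noise_sd = -1), "noise")
  expect_error(sim_config(n_probes = 100, n_planted_hypo = 10,
                          n_local_activation = 20, n_local_repression = 0,
                          n_distal_enhancer = 0, n_distal_silencer = 0),
               "links")
})

test_that("study fixtures written to disk reload into equal objects", {
  st <- generate_dataset(small_cfg(seed = 8))
  d <- withr::local_tempdir()
  paths <- write_study(st, d)
  bm <- read_beta_matrix(paths[["beta.tsv"]], paths[["samples.tsv"]])
  expect_equal(bm$beta, st$beta$beta, tolerance = 1e-12)
  man <- read_manifest(paths[["manifest.tsv"]])
  expect_equal(as.data.frame(man), as.data.frame(st$manifest))
  ints <- read_interactions(paths[["interactions.ibed"]])
  expect_equal(as.data.frame(ints), as.data.frame(st$interactions))
  cfg <- read_sim_config(paths[["config.yaml"]])
  expect_equal(cfg, st$config)
})
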