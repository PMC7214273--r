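test_that("TF site containment honours the half-open boundary convention", {
  man <- make_manifest(c("cgL", "cgOut"), pos = c(100, 99))
  track <- meth3dlink:::.gr0("chrS", 99, 110, name = "SPI1")
  ov <- overlap_tf_sites(c("cgL", "cgOut"), man, track)
  expect_equal(ov$map$cgL, "SPI1")   # pos 100 -> 0-based 99, inside [99,110)
  expect_length(ov$map$cgOut, 0)     # pos 99 -> 0-based 98, outside
  expect_equal(ov$tfs, "SPI1")
  expect_equal(ov$n_tfs, 1L)
})

test_that("TF overlap equals the naive all-pairs containment oracle", {
  set.seed(77)
  for (rep in 1:3) {
    n_cpg <- 500; n_iv <- 2000
    man <- make_manifest(sprintf("cg%04d", seq_len(n_cpg)),
                         pos = sample.int(1e5, n_cpg))
    iv <- data.frame(chrom = "chrS",
                     start = sample.int(1e5, n_iv),
                     name = sprintf("TF%02d", sample.int(40, n_iv,
                                                         replace = TRUE)),
                     stringsAsFactors = FALSE)
    iv$end <- iv$start + sample(10:500, n_iv, replace = TRUE)
    track <- meth3dlink:::.gr0(iv$chrom, iv$start, iv$end, name = iv$name)
    ov <- overlap_tf_sites(man$probe_id, man, track)
    # oracle must be computed on the track's sorted order used by the map
    naive <- naive_overlap_oracle(man$chrom, man$pos, iv)
    for (i in seq_len(n_cpg)) {
      expect_identical(ov$map[[man$probe_id[i]]],
                       sort(unique(iv$name[naive[[i]]])))
    }
  }
})

test_that("hypergeometric upper tail matches combinatorial identities", {
  expect_equal(hypergeom_upper_tail(0, 5, 4, 10), 1)
  expect_equal(hypergeom_upper_tail(4, 5, 4, 10), 5 / 210)
  expect_equal(hypergeom_upper_tail(3, 3, 3, 3), 1)
  expect_error(hypergeom_upper_tail(5, 4, 10, 10), "bounds")
  expect_error(hypergeom_upper_tail(1, 11, 2, 10), "bounds")
})

test_that("hypergeometric tail equals exact enumeration across small universes", {
  for (N in c(5, 10, 17, 25)) {
    for (K in 0:N) {
      for (n in seq(0, N, by = 3)) {
        for (k in seq(0, min(K, n), by = 2)) {
          expect_equal(hypergeom_upper_tail(k, K, n, N),
                       if (k == 0) 1 else hyper_oracle(k, K, n, N),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("category enrichment ranks a planted category first with valid q", {
  set.seed(88)
  universe <- sprintf("TF%03d", 1:100)
  selected <- universe[1:10]
  cmap <- rbind(
    data.frame(tf = universe[1:10], category = "planted",
               stringsAsFactors = FALSE)[1:8, , drop = FALSE],
    data.frame(tf = universe[11:12], category = "planted",
               stringsAsFactors = FALSE),
    data.frame(tf = sample(universe, 30), category = "background",
               stringsAsFactors = FALSE)
  )
  res <- enrich_categories(selected, universe, cmap)
  expect_equal(res$category[1], "planted")
  expect_equal(res$k[1], 8L)
  expect_equal(res$K[1], 10L)
  # q-values: monotone in p-rank, bounded by 1, never below raw p
  expect_true(all(diff(res$q) >= -1e-12))
  expect_true(all(res$q >= res$p_hyper))
  expect_true(all(res$q <= 1))
})

test_that("selecting the whole universe leaves nothing overrepresented", {
  universe <- sprintf("TF%02d", 1:20)
  cmap <- data.frame(tf = universe,
                     category = rep(c("a", "b"), 10),
                     stringsAsFactors = FALSE)
  res <- enrich_categories(universe, universe, cmap)
  expect_true(all(res$p_hyper == 1))
  expect_error(enrich_categories(c(universe, "ROGUE"), universe, cmap),
               "ROGUE")
})
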