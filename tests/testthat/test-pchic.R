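test_that("probes map into other-end fragments under the shared convention", {
  man <- make_manifest(c("cgIn", "cgOut"), pos = c(5000, 9000))
  ints <- make_interactions(bait_start = 100000, bait_name = "G1",
                            oe_start = 4000)
  mp <- map_cpgs_to_other_ends(c("cgIn", "cgOut"), ints, man)
  expect_equal(mp$probe_id, "cgIn")   # 5000 in [4000, 6000)
  expect_equal(attr(mp, "distal_probes"), "cgIn")
})

test_that("other-end mapping equals the naive all-pairs oracle and is monotone", {
  set.seed(99)
  n_p <- 300; n_i <- 150
  man <- make_manifest(sprintf("cg%04d", seq_len(n_p)),
                       pos = sample.int(5e5, n_p))
  oe <- sample.int(5e5, n_i)
  ints <- interaction_set(data.frame(
    bait_chr = "chrS", bait_start = 9e5, bait_end = 9e5 + 2000,
    bait_name = sprintf("G%d", seq_len(n_i)),
    otherEnd_chr = "chrS", otherEnd_start = oe,
    otherEnd_end = oe + sample(500:5000, n_i, replace = TRUE),
    otherEnd_name = ".", N_reads = 5L, score = 6,
    stringsAsFactors = FALSE
  ))
  mp <- map_cpgs_to_other_ends(man$probe_id, ints, man)
  iv <- data.frame(chrom = ints$otherEnd_chr, start = ints$otherEnd_start,
                   end = ints$otherEnd_end, stringsAsFactors = FALSE)
  naive <- naive_overlap_oracle(man$chrom, man$pos, iv)
  expected <- do.call(rbind, lapply(seq_len(n_p), function(i) {
    if (length(naive[[i]]) == 0) return(NULL)
    data.frame(probe_id = man$probe_id[i],
               interaction_id = ints$id[naive[[i]]],
               stringsAsFactors = FALSE)
  }))
  expected <- expected[order(expected$probe_id, expected$interaction_id), ]
  rownames(expected) <- NULL
  expect_equal(mp$probe_id, expected$probe_id)
  expect_equal(mp$interaction_id, expected$interaction_id)
  # adding interactions never unmaps a probe
  mp_half <- map_cpgs_to_other_ends(man$probe_id, ints[1:75, ], man)
  expect_true(all(attr(mp_half, "distal_probes") %in%
                    attr(mp, "distal_probes")))
})

test_that("planted distal loops classify as enhancer or silencer", {
  st <- generate_dataset(sim_config(
    n_probes = 400L, n_planted_hypo = 50L, n_planted_hyper = 0L,
    n_genes = 100L, n_interactions = 50L, n_fragments = 2000L,
    umi4c_flank_frags = 50L, expr_noise_sd = 0.1, seed = 33
  ))
  dmcs <- call_dmcs(st$beta)
  mp <- map_cpgs_to_other_ends(dmcs$probe_id[dmcs$passes],
                               st$interactions, st$manifest)
  links <- build_distal_links(mp, dmcs, st$interactions, st$beta, st$expr,
                              st$manifest)
  truth <- st$truth$distal_links
  found <- merge(links, truth,
                 by.x = c("probe_id", "target_gene"),
                 by.y = c("probe_id", "gene"))
  expect_gte(nrow(found), 0.8 * nrow(truth))
  expect_gte(mean(found$reg_class == found$sign), 0.9)
  # enhancer + silencer gene counts partition the correlated target genes
  s <- summary(links)
  expect_equal(s$n_enhancer_genes + s$n_silencer_genes, s$n_target_genes)
})

test_that("multiplicity classes count distinct classified target genes", {
  expect_equal(
    multiplicity_classes(make_distal_links("p1", "CCR1", "enhancer")),
    c(unique = 1L, dual = 0L, complex = 0L)
  )
  expect_equal(
    multiplicity_classes(make_distal_links(rep("p1", 2), c("A", "B"),
                                           rep("enhancer", 2))),
    c(unique = 0L, dual = 1L, complex = 0L)
  )
  # planted 21 unique / 7 dual / 6 complex probes
  probes <- c(sprintf("u%02d", 1:21),
              rep(sprintf("d%02d", 1:7), each = 2),
              rep(sprintf("c%02d", 1:6), each = 3))
  genes <- c(sprintf("gu%02d", 1:21),
             sprintf("gd%02d", seq_len(14)),
             sprintf("gc%02d", seq_len(18)))
  links <- make_distal_links(probes, genes,
                             rep("enhancer", length(probes)))
  mult <- multiplicity_classes(links)
  expect_equal(mult, c(unique = 21L, dual = 7L, complex = 6L))
  # the classes partition the classified probes
  expect_equal(sum(mult), length(unique(probes)))
  # uncorrelated links do not contribute
  links$reg_class[links$probe_id == "u01"] <- "uncorrelated"
  expect_equal(multiplicity_classes(links)[["unique"]], 20L)
})

test_that("CTCF overlap works from a motif track and from an IUPAC scan", {
  man <- make_manifest(c("cgA", "cgB"), pos = c(150, 400))
  sites <- meth3dlink:::.gr0("chrS", 140, 160, name = "CTCF")
  expect_equal(ctcf_overlap(c("cgA", "cgB"), man, motif_sites = sites),
               "cgA")
  expect_length(ctcf_overlap(c("cgA", "cgB"), man,
                             motif_sites = GenomicRanges::GRanges()), 0)
  expect_error(ctcf_overlap("cgA", man), "config error")

  # two planted consensus occurrences in a 200 bp sequence, one per strand
  set.seed(12)
  core <- "CCGCGNGGNGGCAG"
  planted_fwd <- "CCGCGTGGAGGCAG"
  planted_rev <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString("CCGCGAGGTGGCAG")))
  bg <- paste(sample(c("A", "T"), 200, replace = TRUE), collapse = "")
  seqc <- paste0(substr(bg, 1, 50), planted_fwd,
                 substr(bg, 51, 120), planted_rev,
                 substr(bg, 121, 200))
  hits <- scan_motif(seqc, core)
  oracle <- iupac_scan_oracle(seqc, core)
  expect_length(hits, 2)
  expect_setequal(GenomicRanges::start(hits),
                  c(oracle$fwd_starts, oracle$rev_starts_forward_coords))
  # probes inside either occurrence are picked up by the scan path
  man2 <- make_manifest(c("in1", "in2", "out"),
                        pos = c(55, 135, 190))
  got <- ctcf_overlap(c("in1", "in2", "out"), man2, sequence = seqc,
                      pattern = core)
  expect_setequal(got, c("in1", "in2"))
})
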