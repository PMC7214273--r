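# Fixture builders: all synthetic, constructed in code at test time.

# Beta matrix from a probes x 7 matrix of per-timepoint expected values,
# replicated `reps` times per timepoint without noise; controls mirror the
# endpoint expectations unless overridden.
make_bm <- function(E, reps = 2, neg = NULL, pos = NULL,
                    probe_ids = NULL) {
  E <- as.matrix(E)
  n <- nrow(E)
  if (is.null(probe_ids)) {
    probe_ids <- if (!is.null(rownames(E))) rownames(E) else
      sprintf("cg%03d", seq_len(n))
  }
  if (is.null(neg)) neg <- E[, 1]
  if (is.null(pos)) pos <- E[, ncol(E)]
  td <- do.call(cbind, lapply(seq_len(ncol(E)), function(j) {
    matrix(rep(E[, j], reps), ncol = reps)
  }))
  mat <- cbind(td, matrix(rep(neg, reps), ncol = reps),
               matrix(rep(pos, reps), ncol = reps))
  ids <- c(as.vector(vapply(TP_H, function(t) {
    sprintf("td_t%03d_r%d", t, seq_len(reps))
  }, character(reps))),
  sprintf("neg_r%d", seq_len(reps)), sprintf("pos_r%d", seq_len(reps)))
  dimnames(mat) <- list(probe_ids, ids)
  samples <- data.frame(
    sample_id = ids,
    timepoint_h = c(rep(TP_H, each = reps), rep(NA_integer_, 2 * reps)),
    replicate = c(rep(seq_len(reps), length(TP_H)), seq_len(reps),
                  seq_len(reps)),
    condition = c(rep("transdiff", length(TP_H) * reps),
                  rep("negative_control", reps),
                  rep("positive_control", reps)),
    stringsAsFactors = FALSE
  )
  beta_matrix(mat, samples)
}

# Minimal manifest from parallel vectors.
make_manifest <- function(probe_ids, pos = seq_along(probe_ids) * 1000,
                          genes = rep("", length(probe_ids)),
                          feats = NULL, chrom = "chrS") {
  if (is.null(feats)) feats <- ifelse(genes == "", "", "Body")
  probe_manifest(data.frame(
    probe_id = probe_ids, chrom = chrom, pos = pos,
    gene_symbols = genes, feature_classes = feats, stringsAsFactors = FALSE
  ))
}

# Interaction set from 0-based fragment coordinates.
make_interactions <- function(bait_start, bait_name, oe_start,
                              frag = 2000L, chrom = "chrS") {
  interaction_set(data.frame(
    bait_chr = chrom, bait_start = bait_start, bait_end = bait_start + frag,
    bait_name = bait_name,
    otherEnd_chr = chrom, otherEnd_start = oe_start,
    otherEnd_end = oe_start + frag, otherEnd_name = ".",
    N_reads = 10L, score = 5.0, stringsAsFactors = FALSE
  ))
}

# Contact profile over a uniform fragment grid with given counts; bait at the
# grid centre unless stated.
make_profile <- function(counts, frag = 1000L, bait_pos = NULL,
                         condition = "t0", chrom = "chrS") {
  n <- length(counts)
  starts <- (seq_len(n) - 1L) * frag
  if (is.null(bait_pos)) bait_pos <- starts[(n + 1L) %/% 2L] + frag / 2
  contact_profile(
    data.frame(chrom = chrom, start = starts, end = starts + frag,
               stringsAsFactors = FALSE),
    counts, bait_pos = bait_pos, condition = condition
  )
}

# A distal_links-shaped data frame for multiplicity/partition fixtures.
make_distal_links <- function(probe_id, target_gene, reg_class,
                              r = NULL, p_perm = NULL) {
  n <- length(probe_id)
  if (is.null(r)) r <- ifelse(reg_class == "silencer", 0.99, -0.99)
  if (is.null(p_perm)) p_perm <- ifelse(reg_class == "uncorrelated", 0.9,
                                        0.001)
  structure(
    data.frame(probe_id = probe_id, interaction_id = sprintf("int%04d",
                                                             seq_len(n)),
               target_gene = target_gene, r = r, p_perm = p_perm,
               direction = "hypo", reg_class = reg_class,
               cpg_context = "non_gene", stringsAsFactors = FALSE),
    class = c("distal_links", "data.frame")
  )
}
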