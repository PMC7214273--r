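# Seeded synthetic study generator with planted ground truth.
#
# The generator emulates the statistical structure of a
# B-ALL-to-macrophage transdifferentiation methylome study: a probes x
# samples beta matrix over the seven timepoints 0, 3, 12, 24, 48, 72 and
# 168 h with replicates plus negative-control (parental line) and
# positive-control (macrophage-like) profiles; a gene x timepoint log2
# expression matrix; an EPIC-style probe manifest; PCHi-C interaction calls;
# TF binding-site and CTCF motif-site tracks; and a pair of UMI-4C contact
# profiles with a planted loop gain. The genome model is a single synthetic
# chromosome tiled by equal restriction fragments, with baits at gene
# promoters - simplicity over realism.

.TIMEPOINTS_H <- c(0L, 3L, 12L, 24L, 48L, 72L, 168L)

#' Configuration of the synthetic study
#'
#' All randomness downstream of \code{\link{generate_dataset}} is fixed by
#' \code{seed}. Planted-link counts default to fixed proportions of the
#' planted hypomethylated set (20\% demethylation-activation, 5\%
#' demethylation-repression local links; 12\% enhancer, 8\% silencer distal
#' links), echoing the roughly 80:20 activation:repression and 60:40
#' enhancer:silencer splits seen in this kind of study.
#'
#' @param n_probes Number of array probes.
#' @param n_planted_hypo,n_planted_hyper Planted differential probes by
#'   direction (may be 0 for null calibration runs).
#' @param replicates_per_timepoint Replicates per transdiff timepoint and per
#'   control condition.
#' @param beta_noise_sd Additive beta noise sd (truncated to keep values in
#'   \[0,1\]).
#' @param beta_noise_model \code{"truncnorm"} (default) or \code{"beta"}
#'   (Beta-distributed noise with matched mean and sd).
#' @param expr_noise_sd Gaussian noise sd on log2 expression.
#' @param n_genes Number of genes.
#' @param gene_assoc_fraction Fraction of non-link probes annotated to a
#'   random gene.
#' @param n_interactions Background PCHi-C interactions (planted ones are
#'   added on top).
#' @param n_local_activation,n_local_repression,n_distal_enhancer,n_distal_silencer
#'   Planted link counts; \code{NULL} (default) derives them from
#'   \code{n_planted_hypo} as above.
#' @param fragment_size_bp Restriction-fragment tile size.
#' @param n_fragments Fragments on the synthetic chromosome.
#' @param umi4c_mean_depth Poisson mean contact count at one fragment from
#'   the bait.
#' @param distance_decay_exponent Contact decay exponent (mean ~
#'   distance^-exponent, distance in fragments).
#' @param loop_gain_factor Fold boost of the loop fragment mean in the
#'   boosted condition.
#' @param umi4c_flank_frags Fragments kept on each side of the bait.
#' @param loop_offset_frags Planted distance (fragments) between the loop
#'   bait and its other-end.
#' @param seed Integer seed fixing all randomness end-to-end.
#' @return List of class \code{"sim_config"}.
#' @export
sim_config <- function(n_probes = 2000L,
                       n_planted_hypo = 100L,
                       n_planted_hyper = 1L,
                       replicates_per_timepoint = 3L,
                       beta_noise_sd = 0.03,
                       beta_noise_model = c("truncnorm", "beta"),
                       expr_noise_sd = 0.2,
                       n_genes = 300L,
                       gene_assoc_fraction = 0.5,
                       n_interactions = 150L,
                       n_local_activation = NULL,
                       n_local_repression = NULL,
                       n_distal_enhancer = NULL,
                       n_distal_silencer = NULL,
                       fragment_size_bp = 4000L,
                       n_fragments = 5000L,
                       umi4c_mean_depth = 2000,
                       distance_decay_exponent = 1,
                       loop_gain_factor = 5,
                       umi4c_flank_frags = 200L,
                       loop_offset_frags = 50L,
                       seed = 1L) {
  beta_noise_model <- match.arg(beta_noise_model)
  if (is.null(n_local_activation)) n_local_activation <- floor(0.20 * n_planted_hypo)
  if (is.null(n_local_repression)) n_local_repression <- floor(0.05 * n_planted_hypo)
  if (is.null(n_distal_enhancer)) n_distal_enhancer <- floor(0.12 * n_planted_hypo)
  if (is.null(n_distal_silencer)) n_distal_silencer <- floor(0.08 * n_planted_hypo)
  cfg <- list(
    n_probes = as.integer(n_probes),
    n_planted_hypo = as.integer(n_planted_hypo),
    n_planted_hyper = as.integer(n_planted_hyper),
    replicates_per_timepoint = as.integer(replicates_per_timepoint),
    beta_noise_sd = beta_noise_sd,
    beta_noise_model = beta_noise_model,
    expr_noise_sd = expr_noise_sd,
    n_genes = as.integer(n_genes),
    gene_assoc_fraction = gene_assoc_fraction,
    n_interactions = as.integer(n_interactions),
    n_local_activation = as.integer(n_local_activation),
    n_local_repression = as.integer(n_local_repression),
    n_distal_enhancer = as.integer(n_distal_enhancer),
    n_distal_silencer = as.integer(n_distal_silencer),
    fragment_size_bp = as.integer(fragment_size_bp),
    n_fragments = as.integer(n_fragments),
    umi4c_mean_depth = umi4c_mean_depth,
    distance_decay_exponent = distance_decay_exponent,
    loop_gain_factor = loop_gain_factor,
    umi4c_flank_frags = as.integer(umi4c_flank_frags),
    loop_offset_frags = as.integer(loop_offset_frags),
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_probes < 1 || n_genes < 1 || n_fragments < 1 ||
          replicates_per_timepoint < 1 || fragment_size_bp < 1) {
      .stopf("config error: core sizes must be positive")
    }
    if (n_planted_hypo < 0 || n_planted_hyper < 0) {
      .stopf("config error: planted counts must be non-negative")
    }
    if (n_planted_hypo + n_planted_hyper > n_probes) {
      .stopf("config error: n_planted exceeds n_probes")
    }
    if (beta_noise_sd < 0 || expr_noise_sd < 0) {
      .stopf("config error: noise sds must be >= 0")
    }
    n_links <- n_local_activation + n_local_repression +
      n_distal_enhancer + n_distal_silencer
    if (n_links > n_planted_hypo) {
      .stopf("config error: planted links exceed planted hypo probes")
    }
    if (n_links > n_genes) {
      .stopf("config error: planted links exceed n_genes")
    }
  })
  class(cfg) <- "sim_config"
  cfg
}

# Truncated-Gaussian noise around mu, confined to [0,1] (inverse-CDF method).
.rnoise01 <- function(mu, sd, model = "truncnorm") {
  if (sd == 0) return(mu)
  if (model == "beta") {
    m <- pmin(pmax(mu, 1e-3), 1 - 1e-3)
    v <- pmin(sd^2, 0.95 * m * (1 - m))
    nu <- m * (1 - m) / v - 1
    return(stats::rbeta(length(mu), m * nu, (1 - m) * nu))
  }
  lo <- stats::pnorm((0 - mu) / sd)
  hi <- stats::pnorm((1 - mu) / sd)
  x <- stats::qnorm(lo + stats::runif(length(mu)) * (hi - lo)) * sd + mu
  pmin(pmax(x, 0), 1)
}

# Plateau pairs: high in [0.7, 0.95], low in [0.05, 0.25], jointly
# conditioned on high - low >= 0.67 so the expected endpoint |delta beta|
# clears the 0.66 call threshold for every planted probe.
.draw_plateaus <- function(n) {
  high <- numeric(n); low <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    h <- stats::runif(length(todo), 0.70, 0.95)
    l <- stats::runif(length(todo), 0.05, 0.25)
    ok <- (h - l) >= 0.67
    high[todo[ok]] <- h[ok]
    low[todo[ok]] <- l[ok]
    todo <- todo[!ok]
  }
  list(high = high, low = low)
}

# Expected beta over the timecourse: logistic decay (hypo) or rise (hyper)
# between the plateaus, midpoint drawn in [12, 72] h, scale midpoint/6 so
# both plateaus are effectively reached at the endpoints.
.trajectory <- function(high, low, midpoint, timepoints, direction) {
  s <- midpoint / 6
  frac <- stats::plogis(outer(midpoint, timepoints, `-`) / s)
  if (direction == "hyper") frac <- 1 - frac
  low + (high - low) * frac
}

#' Simulate a pair of UMI-4C contact profiles
#'
#' Counts per fragment are Poisson with mean
#' \code{mean_depth * k^(-decay)} where k is the fragment's distance from
#' the bait in fragments (k >= 1); the loop fragment's mean is multiplied by
#' \code{loop_gain} in the second condition only. Used by
#' \code{\link{generate_dataset}} and directly for contact-test calibration
#' experiments.
#'
#' @param n_fragments Odd number of fragments in the grid (bait at the
#'   centre).
#' @param fragment_size_bp Fragment size in bp.
#' @param mean_depth Poisson mean at one fragment from the bait.
#' @param decay Distance-decay exponent.
#' @param loop_offset Loop fragment offset from the bait in fragments
#'   (\code{NULL} for no planted loop).
#' @param loop_gain Fold gain at the loop fragment in condition B.
#' @param conditions Labels of the two conditions.
#' @param chrom Chromosome name.
#' @param seed Seed for the Poisson draws.
#' @return List with \code{a}, \code{b} (\code{\link{contact_profile}}s),
#'   \code{loop_index} (grid index of the loop fragment or \code{NULL}) and
#'   \code{loop_pos} (its midpoint bp).
#' @export
simulate_contact_pair <- function(n_fragments = 401L, fragment_size_bp = 4000L,
                                  mean_depth = 2000, decay = 1,
                                  loop_offset = 50L, loop_gain = 5,
                                  conditions = c("t0", "t168"),
                                  chrom = "chrS", seed = 1L) {
  stopifnot(n_fragments %% 2 == 1)
  starts <- (seq_len(n_fragments) - 1L) * fragment_size_bp
  grid <- data.frame(chrom = chrom, start = starts,
                     end = starts + fragment_size_bp,
                     stringsAsFactors = FALSE)
  bait_index <- (n_fragments + 1L) %/% 2L
  bait_pos <- grid$start[bait_index] + fragment_size_bp / 2
  k <- pmax(1L, abs(seq_len(n_fragments) - bait_index))
  mu <- mean_depth * k^(-decay)
  loop_index <- NULL
  mu_b <- mu
  if (!is.null(loop_offset)) {
    loop_index <- bait_index + as.integer(loop_offset)
    stopifnot(loop_index >= 1, loop_index <= n_fragments)
    mu_b[loop_index] <- mu_b[loop_index] * loop_gain
  }
  .local_seed(seed, {
    a <- contact_profile(grid, stats::rpois(n_fragments, mu),
                         bait_pos = bait_pos, condition = conditions[1])
    b <- contact_profile(grid, stats::rpois(n_fragments, mu_b),
                         bait_pos = bait_pos, condition = conditions[2])
    list(a = a, b = b, loop_index = loop_index,
         loop_pos = if (is.null(loop_index)) NULL else
           grid$start[loop_index] + fragment_size_bp / 2)
  })
}

#' Index of the fragment containing a position
#' @param profile A \code{\link{contact_profile}}.
#' @param pos Position in bp.
#' @return Integer fragment index, or \code{NA} if no fragment contains it.
#' @export
fragment_index <- function(profile, pos) {
  i <- which(profile$start <= pos & pos < profile$end)
  if (length(i) == 0) NA_integer_ else i[1]
}

#' Generate the full synthetic study
#'
#' Planted hypomethylated probes follow a logistic demethylation trajectory
#' from a high plateau at 0 h to a low plateau at 168 h (expected endpoint
#' |delta beta| > 0.66 by construction); hypermethylated probes mirror it;
#' null probes have constant expected beta. The positive-control profile
#' equals the planted 168 h expectation and the negative control the 0 h
#' expectation. Activation-linked gene expression increases affinely with
#' (1 - beta) of its planted probe; repression-linked decreases; distal
#' enhancer/silencer targets behave likewise through a planted PCHi-C
#' interaction whose other-end contains the probe. One planted enhancer
#' doubles as the UMI-4C loop target.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List of class \code{"synthetic_study"} with elements \code{beta}
#'   (\code{\link{beta_matrix}}), \code{expr}, \code{manifest},
#'   \code{interactions}, \code{tf_sites}, \code{tf_categories},
#'   \code{ctcf_sites}, \code{contacts} (list \code{a}, \code{b}),
#'   \code{truth} (\code{"synthetic_truth"}) and \code{config}.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  .local_seed(cfg$seed, .generate_dataset_impl(cfg))
}

.generate_dataset_impl <- function(cfg) {
  tps <- .TIMEPOINTS_H
  chrom <- "chrS"
  L <- cfg$n_fragments * cfg$fragment_size_bp
  frag_starts <- (seq_len(cfg$n_fragments) - 1L) * cfg$fragment_size_bp

  probe_id <- sprintf("cg%08d", seq_len(cfg$n_probes))
  pos <- sort(sample.int(L, cfg$n_probes))

  # roles
  shuffled <- sample.int(cfg$n_probes)
  n_hypo <- cfg$n_planted_hypo; n_hyper <- cfg$n_planted_hyper
  hypo_idx <- shuffled[seq_len(n_hypo)]
  hyper_idx <- shuffled[n_hypo + seq_len(n_hyper)]
  n_act <- cfg$n_local_activation; n_rep <- cfg$n_local_repression
  n_enh <- cfg$n_distal_enhancer; n_sil <- cfg$n_distal_silencer
  local_idx <- hypo_idx[seq_len(n_act + n_rep)]
  act_idx <- local_idx[seq_len(n_act)]
  rep_idx <- setdiff(local_idx, act_idx)
  distal_idx <- hypo_idx[n_act + n_rep + seq_len(n_enh + n_sil)]
  enh_idx <- distal_idx[seq_len(n_enh)]
  sil_idx <- setdiff(distal_idx, enh_idx)

  # genes at distinct promoter fragments
  gene_id <- sprintf("gene%04d", seq_len(cfg$n_genes))
  gene_frag <- sample.int(cfg$n_fragments, cfg$n_genes)
  gene_pool <- sample.int(cfg$n_genes)
  local_genes <- gene_id[gene_pool[seq_len(n_act + n_rep)]]
  distal_gene_idx <- gene_pool[n_act + n_rep + seq_len(n_enh + n_sil)]
  distal_genes <- gene_id[distal_gene_idx]

  # planted distal probes get distinct fragments away from gene baits
  if (length(distal_idx) > 0) {
    free_frags <- setdiff(seq_len(cfg$n_fragments), gene_frag)
    d_frags <- sample(free_frags, length(distal_idx))
    pos[distal_idx] <- frag_starts[d_frags] +
      sample.int(cfg$fragment_size_bp - 1L, length(distal_idx), replace = TRUE)
  }

  # loop target: first planted enhancer; its gene promoter is re-seated a
  # fixed fragment offset away so the loop sits inside the reliable UMI-4C
  # distance band
  loop <- NULL
  if (n_enh > 0) {
    loop_probe_i <- enh_idx[1]
    probe_frag <- (pos[loop_probe_i] - 1L) %/% cfg$fragment_size_bp + 1L
    cand <- c(probe_frag + cfg$loop_offset_frags,
              probe_frag - cfg$loop_offset_frags)
    cand <- cand[cand >= 1 & cand <= cfg$n_fragments]
    cand <- c(setdiff(cand, gene_frag), cand)[1]
    gene_frag[distal_gene_idx[1]] <- cand
    loop <- list(gene = distal_genes[1], probe_id = probe_id[loop_probe_i],
                 boosted_condition = "t168")
  }

  # expected beta trajectories
  E <- matrix(rep(stats::runif(cfg$n_probes, 0.05, 0.95), length(tps)),
              ncol = length(tps))
  if (n_hypo > 0) {
    pl <- .draw_plateaus(n_hypo)
    mid <- stats::runif(n_hypo, 12, 72)
    E[hypo_idx, ] <- .trajectory(pl$high, pl$low, mid, tps, "hypo")
  }
  if (n_hyper > 0) {
    pl <- .draw_plateaus(n_hyper)
    mid <- stats::runif(n_hyper, 12, 72)
    E[hyper_idx, ] <- .trajectory(pl$high, pl$low, mid, tps, "hyper")
  }

  # samples: transdiff replicates per timepoint + controls at the endpoint
  # expectations
  reps <- cfg$replicates_per_timepoint
  td_meta <- expand.grid(replicate = seq_len(reps), timepoint_h = tps)
  samples <- data.frame(
    sample_id = c(
      sprintf("td_t%03d_r%d", td_meta$timepoint_h, td_meta$replicate),
      sprintf("neg_r%d", seq_len(reps)),
      sprintf("pos_r%d", seq_len(reps))
    ),
    timepoint_h = c(td_meta$timepoint_h, rep(NA_integer_, 2 * reps)),
    replicate = c(td_meta$replicate, seq_len(reps), seq_len(reps)),
    condition = c(rep("transdiff", nrow(td_meta)),
                  rep("negative_control", reps),
                  rep("positive_control", reps)),
    stringsAsFactors = FALSE
  )
  mu_cols <- cbind(E[, match(td_meta$timepoint_h, tps), drop = FALSE],
                   matrix(rep(E[, 1], reps), ncol = reps),
                   matrix(rep(E[, length(tps)], reps), ncol = reps))
  beta_vals <- matrix(
    .rnoise01(as.numeric(mu_cols), cfg$beta_noise_sd, cfg$beta_noise_model),
    nrow = cfg$n_probes
  )
  dimnames(beta_vals) <- list(probe_id, samples$sample_id)
  bm <- beta_matrix(beta_vals, samples)

  # expression: genes x timepoints, log2 scale
  base <- stats::runif(cfg$n_genes, 4, 10)
  expr <- matrix(rep(base, length(tps)), ncol = length(tps),
                 dimnames = list(gene_id, paste0("t", tps)))
  plant_expr <- function(gene, probe_i, sign) {
    b <- stats::runif(1, 1.5, 3)
    drive <- 1 - E[probe_i, ]
    expr[gene, ] <<- expr[gene, ] + sign * b * drive
  }
  link_rows <- list()
  for (j in seq_along(act_idx)) {
    plant_expr(local_genes[j], act_idx[j], +1)
    link_rows[[length(link_rows) + 1L]] <- data.frame(
      probe_id = probe_id[act_idx[j]], gene = local_genes[j],
      sign = "activation", stringsAsFactors = FALSE)
  }
  for (j in seq_along(rep_idx)) {
    g <- local_genes[n_act + j]
    plant_expr(g, rep_idx[j], -1)
    link_rows[[length(link_rows) + 1L]] <- data.frame(
      probe_id = probe_id[rep_idx[j]], gene = g,
      sign = "repression", stringsAsFactors = FALSE)
  }
  distal_rows <- list()
  for (j in seq_along(enh_idx)) {
    plant_expr(distal_genes[j], enh_idx[j], +1)
    distal_rows[[length(distal_rows) + 1L]] <- data.frame(
      probe_id = probe_id[enh_idx[j]], gene = distal_genes[j],
      sign = "enhancer", stringsAsFactors = FALSE)
  }
  for (j in seq_along(sil_idx)) {
    g <- distal_genes[n_enh + j]
    plant_expr(g, sil_idx[j], -1)
    distal_rows[[length(distal_rows) + 1L]] <- data.frame(
      probe_id = probe_id[sil_idx[j]], gene = g,
      sign = "silencer", stringsAsFactors = FALSE)
  }
  expr <- expr + matrix(stats::rnorm(length(expr), 0, cfg$expr_noise_sd),
                        nrow = nrow(expr))
  attr(expr, "timepoints_h") <- tps

  # manifest: planted local probes annotated to their gene; a background
  # fraction of the remaining probes annotated to random genes
  feature_pool <- c("TSS1500", "TSS200", "5UTR", "FirstExon", "Body", "3UTR")
  gene_symbols <- rep("", cfg$n_probes)
  feature_classes <- rep("", cfg$n_probes)
  gene_symbols[local_idx] <- c(local_genes[seq_len(n_act)],
                               local_genes[n_act + seq_len(n_rep)])
  feature_classes[local_idx] <- sample(feature_pool, length(local_idx),
                                       replace = TRUE)
  others <- setdiff(seq_len(cfg$n_probes), local_idx)
  annotate <- others[stats::runif(length(others)) < cfg$gene_assoc_fraction]
  gene_symbols[annotate] <- gene_id[sample.int(cfg$n_genes, length(annotate),
                                               replace = TRUE)]
  feature_classes[annotate] <- sample(feature_pool, length(annotate),
                                      replace = TRUE)
  manifest <- probe_manifest(data.frame(
    probe_id = probe_id, chrom = chrom, pos = pos,
    gene_symbols = gene_symbols, feature_classes = feature_classes,
    stringsAsFactors = FALSE
  ))

  # PCHi-C interactions: planted (bait = target gene promoter fragment,
  # other-end = probe fragment) + background pairs avoiding planted probes
  frag_of <- function(p) (p - 1L) %/% cfg$fragment_size_bp + 1L
  mk_int <- function(bait_frag, bait_name, oe_frag) {
    data.frame(
      bait_chr = chrom,
      bait_start = frag_starts[bait_frag],
      bait_end = frag_starts[bait_frag] + cfg$fragment_size_bp,
      bait_name = bait_name,
      otherEnd_chr = chrom,
      otherEnd_start = frag_starts[oe_frag],
      otherEnd_end = frag_starts[oe_frag] + cfg$fragment_size_bp,
      otherEnd_name = ".",
      N_reads = stats::rpois(length(bait_frag), 50) + 1L,
      score = round(stats::runif(length(bait_frag), 5, 15), 2),
      stringsAsFactors = FALSE
    )
  }
  planted_frags <- unique(frag_of(pos[c(hypo_idx, hyper_idx)]))
  ints <- list()
  if (length(distal_idx) > 0) {
    d_genes_all <- c(distal_genes[seq_len(n_enh)],
                     distal_genes[n_enh + seq_len(n_sil)])
    ints[[1]] <- mk_int(gene_frag[match(d_genes_all, gene_id)], d_genes_all,
                        frag_of(pos[distal_idx]))
  }
  if (cfg$n_interactions > 0) {
    bg_bait <- sample.int(cfg$n_genes, cfg$n_interactions, replace = TRUE)
    free <- setdiff(seq_len(cfg$n_fragments), c(planted_frags, gene_frag))
    bg_oe <- sample(free, cfg$n_interactions, replace = TRUE)
    ints[[length(ints) + 1L]] <- mk_int(gene_frag[bg_bait], gene_id[bg_bait],
                                        bg_oe)
  }
  interactions <- interaction_set(do.call(rbind, ints))

  # TF binding sites: signal TFs cover the planted local probes, background
  # sites elsewhere; categories enrich the signal TFs for immune terms
  signal_tfs <- c("SPI1", "GATA2", "FOXC1", "MEIS1", "HOXA2", "HOXC11",
                  "CEBPA", "IRF8", "RUNX1", "MAFB")
  bg_tfs <- sprintf("TF%02d", seq_len(20))
  tf_rows <- list()
  if (length(local_idx) > 0) {
    for (i in local_idx) {
      for (tf in sample(signal_tfs, 2)) {
        s <- max(0L, pos[i] - 1L - sample.int(250L, 1))
        tf_rows[[length(tf_rows) + 1L]] <- data.frame(
          start = s, end = s + 300L, name = tf, stringsAsFactors = FALSE)
      }
    }
  }
  n_bg_sites <- 200L
  bs <- sample.int(L - 301L, n_bg_sites)
  tf_rows[[length(tf_rows) + 1L]] <- data.frame(
    start = bs, end = bs + 300L,
    name = sample(c(signal_tfs, bg_tfs), n_bg_sites, replace = TRUE,
                  prob = c(rep(1, length(signal_tfs)),
                           rep(4, length(bg_tfs)))),
    stringsAsFactors = FALSE
  )
  tf_df <- do.call(rbind, tf_rows)
  tf_sites <- .gr0(chrom, tf_df$start, tf_df$end, name = tf_df$name)
  tf_sites <- GenomicRanges::sort(tf_sites, ignore.strand = TRUE)
  immune_cats <- c("immune system development", "cell fate commitment",
                   "leukocyte differentiation")
  generic_cats <- c("metabolic process", "cell cycle", "RNA processing",
                    "adhesion", "signal transduction")
  tf_categories <- rbind(
    data.frame(tf = rep(signal_tfs, each = 2),
               category = as.vector(vapply(seq_along(signal_tfs), function(i) {
                 immune_cats[1 + (i + 0:1) %% 3]
               }, character(2))),
               stringsAsFactors = FALSE),
    data.frame(tf = rep(bg_tfs, each = 2),
               category = sample(generic_cats, 2 * length(bg_tfs),
                                 replace = TRUE),
               stringsAsFactors = FALSE)
  )

  # CTCF motif sites over (up to) four planted distal probes
  ctcf_sites <- GenomicRanges::GRanges()
  ctcf_probes <- character(0)
  if (length(distal_idx) > 0) {
    take <- distal_idx[seq_len(min(4L, length(distal_idx)))]
    ctcf_probes <- probe_id[take]
    s <- pmax(0L, pos[take] - 10L)
    ctcf_sites <- .gr0(chrom, s, s + 19L, name = "CTCF")
  }

  # UMI-4C contact profiles around the loop bait (or the chromosome centre
  # when no loop is planted)
  if (!is.null(loop)) {
    bait_frag <- gene_frag[distal_gene_idx[1]]
    oe_frag <- frag_of(pos[enh_idx[1]])
  } else {
    bait_frag <- cfg$n_fragments %/% 2L
    oe_frag <- NA_integer_
  }
  flank <- cfg$umi4c_flank_frags
  grid_idx <- max(1L, bait_frag - flank):min(cfg$n_fragments, bait_frag + flank)
  grid <- data.frame(chrom = chrom, start = frag_starts[grid_idx],
                     end = frag_starts[grid_idx] + cfg$fragment_size_bp,
                     stringsAsFactors = FALSE)
  bait_pos <- frag_starts[bait_frag] + cfg$fragment_size_bp / 2
  k <- pmax(1L, abs(grid_idx - bait_frag))
  mu <- cfg$umi4c_mean_depth * k^(-cfg$distance_decay_exponent)
  mu_b <- mu
  loop_grid_index <- NULL
  if (!is.null(loop)) {
    loop_grid_index <- match(oe_frag, grid_idx)
    mu_b[loop_grid_index] <- mu_b[loop_grid_index] * cfg$loop_gain_factor
    loop$grid_index <- loop_grid_index
    loop$loop_pos <- frag_starts[oe_frag] + cfg$fragment_size_bp / 2
    loop$bait_pos <- bait_pos
  }
  contacts <- list(
    a = contact_profile(grid, stats::rpois(nrow(grid), mu),
                        bait_pos = bait_pos, condition = "t0"),
    b = contact_profile(grid, stats::rpois(nrow(grid), mu_b),
                        bait_pos = bait_pos, condition = "t168")
  )

  truth <- structure(list(
    dmc = data.frame(
      probe_id = probe_id[c(hypo_idx, hyper_idx)],
      direction = c(rep("hypo", n_hypo), rep("hyper", n_hyper)),
      stringsAsFactors = FALSE
    ),
    local_links = if (length(link_rows) > 0) do.call(rbind, link_rows) else
      data.frame(probe_id = character(0), gene = character(0),
                 sign = character(0), stringsAsFactors = FALSE),
    distal_links = if (length(distal_rows) > 0) do.call(rbind, distal_rows) else
      data.frame(probe_id = character(0), gene = character(0),
                 sign = character(0), stringsAsFactors = FALSE),
    loop = loop,
    ctcf_probes = ctcf_probes
  ), class = "synthetic_truth")
  # attach interaction ids to the planted distal links
  if (nrow(truth$distal_links) > 0) {
    truth$distal_links$interaction_id <-
      interactions$id[seq_len(nrow(truth$distal_links))]
  }

  structure(list(
    beta = bm, expr = expr, manifest = manifest,
    interactions = interactions, tf_sites = tf_sites,
    tf_categories = tf_categories, ctcf_sites = ctcf_sites,
    contacts = contacts, truth = truth, config = cfg
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "synthetic_study (seed %d): %d probes (%d hypo + %d hyper planted), %d genes, %d interactions\n",
    x$config$seed, x$config$n_probes, x$config$n_planted_hypo,
    x$config$n_planted_hyper, x$config$n_genes, nrow(x$interactions)
  ))
  invisible(x)
}

#' Flat table of the planted ground truth
#'
#' One row per planted fact, for test assertions: differential probes
#' (\code{kind = "dmc"}), local links, distal links, CTCF-motif probes and
#' the loop target.
#'
#' @param truth A \code{"synthetic_truth"} from
#'   \code{\link{generate_dataset}}.
#' @return Data frame with columns \code{kind}, \code{probe_id},
#'   \code{gene}, \code{detail}.
#' @export
truth_report <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  rows <- list(
    data.frame(kind = rep("dmc", nrow(truth$dmc)),
               probe_id = truth$dmc$probe_id,
               gene = rep(NA_character_, nrow(truth$dmc)),
               detail = truth$dmc$direction,
               stringsAsFactors = FALSE),
    data.frame(kind = rep("local_link", nrow(truth$local_links)),
               probe_id = truth$local_links$probe_id,
               gene = truth$local_links$gene,
               detail = truth$local_links$sign, stringsAsFactors = FALSE),
    data.frame(kind = rep("distal_link", nrow(truth$distal_links)),
               probe_id = truth$distal_links$probe_id,
               gene = truth$distal_links$gene,
               detail = truth$distal_links$sign, stringsAsFactors = FALSE),
    if (length(truth$ctcf_probes) > 0) {
      data.frame(kind = "ctcf", probe_id = truth$ctcf_probes,
                 gene = NA_character_, detail = "ctcf_motif",
                 stringsAsFactors = FALSE)
    },
    if (!is.null(truth$loop)) {
      data.frame(kind = "loop", probe_id = truth$loop$probe_id,
                 gene = truth$loop$gene,
                 detail = truth$loop$boosted_condition,
                 stringsAsFactors = FALSE)
    }
  )
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write all study fixtures in the package's file dialects
#'
#' @param study A \code{"synthetic_study"}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(dir, x)
  write_beta_matrix(study$beta, f("beta.tsv"), f("samples.tsv"))
  write_expression(study$expr, f("expression.tsv"))
  write_manifest(study$manifest, f("manifest.tsv"))
  write_interactions(study$interactions, f("interactions.ibed"))
  write_bed(study$tf_sites, f("tf_sites.bed"))
  utils::write.table(study$tf_categories, f("tf_categories.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(study$ctcf_sites) > 0) write_bed(study$ctcf_sites, f("ctcf_sites.bed"))
  write_contacts(study$contacts$a, f("contacts_t0.tsv"))
  write_contacts(study$contacts$b, f("contacts_t168.tsv"))
  utils::write.table(truth_report(study$truth), f("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(study$config), f("config.yaml"))
  invisible(vapply(c("beta.tsv", "samples.tsv", "expression.tsv",
                     "manifest.tsv", "interactions.ibed", "tf_sites.bed",
                     "tf_categories.tsv", "contacts_t0.tsv",
                     "contacts_t168.tsv", "truth.tsv", "config.yaml"),
                   f, character(1)))
}

#' Read a simulation config from YAML
#' @param path YAML file with \code{\link{sim_config}} fields.
#' @return A \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  do.call(sim_config, vals[intersect(names(vals), known)])
}
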