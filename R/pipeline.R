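# End-to-end orchestration: simulate -> dmc -> annotate -> link-local ->
# enrich -> link-distal -> umi4c, with one config and a structured report.

#' Run the full analysis pipeline on a synthetic or supplied study
#'
#' Executes every stage in order on a seeded synthetic study (default) or a
#' pre-built study object, and returns a run report whose headline counts
#' mirror the tallies such an analysis produces: significant CpGs and their
#' direction split, gene/non-gene partition, correlated local links by
#' class, overlapped TFs and enriched categories, distal CpGs and their
#' correlated subset, target genes with the enhancer/silencer split, the
#' interaction-multiplicity histogram, the CTCF-motif overlap count, and the
#' UMI-4C contact test at the top differential fragment.
#'
#' @param config A \code{\link{sim_config}} (ignored when \code{study} is
#'   supplied).
#' @param study Optional pre-built \code{"synthetic_study"}-shaped list; the
#'   elements \code{beta}, \code{expr}, \code{manifest},
#'   \code{interactions}, \code{tf_sites}, \code{tf_categories},
#'   \code{ctcf_sites}, \code{contacts} are used.
#' @param out_dir Optional directory; when given, every stage output, a
#'   human-readable report and a config echo are written there.
#' @param p_threshold,delta_threshold,adjust Passed to
#'   \code{\link{call_dmcs}}.
#' @param link_p_threshold Passed to the linkage stages.
#' @param concordance_tol Passed to \code{\link{control_concordance}}.
#' @param umi4c_window Fragment index window (on the distance-filtered grid)
#'   for \code{\link{contact_test}}; default \code{NULL} tests the fragment
#'   with the largest absolute scale-1 differential contact.
#' @param smoothing_window,domainogram_scales UMI-4C smoothing parameters.
#' @return Object of class \code{"run_report"}: a list with \code{counts},
#'   stage \code{results}, \code{paths} (when written), \code{config} and
#'   \code{seed}.
#' @export
run_pipeline <- function(config = sim_config(), study = NULL, out_dir = NULL,
                         p_threshold = 0.05, delta_threshold = 0.66,
                         adjust = "none", link_p_threshold = 0.05,
                         concordance_tol = 0.2, umi4c_window = NULL,
                         smoothing_window = 5L,
                         domainogram_scales = c(1L, 3L, 5L, 11L, 21L)) {
  stage <- "simulate"
  report <- tryCatch({
    if (is.null(study)) study <- generate_dataset(config)

    stage <- "dmc"
    dmcs <- call_dmcs(study$beta, p_threshold = p_threshold,
                      delta_threshold = delta_threshold, adjust = adjust)
    passing <- dmcs$probe_id[dmcs$passes]
    conc <- control_concordance(study$beta, dmcs, tol = concordance_tol)

    stage <- "annotate"
    part <- partition_by_gene(passing, study$manifest)

    stage <- "link-local"
    local <- build_local_links(dmcs, study$manifest, study$beta, study$expr,
                               link_p_threshold = link_p_threshold)
    correlated_local <- unique(local$probe_id[local$link_class != "none"])

    stage <- "enrich"
    tf_universe <- sort(unique(
      as.character(S4Vectors::mcols(study$tf_sites)$name)))
    tf_map <- overlap_tf_sites(correlated_local, study$manifest,
                               study$tf_sites)
    enrich <- enrich_categories(tf_map$tfs, tf_universe, study$tf_categories)

    stage <- "link-distal"
    mapping <- map_cpgs_to_other_ends(passing, study$interactions,
                                      study$manifest)
    distal <- build_distal_links(mapping, dmcs, study$interactions,
                                 study$beta, study$expr, study$manifest,
                                 link_p_threshold = link_p_threshold)
    dsum <- summary(distal)
    mult <- multiplicity_classes(distal)
    classified_probes <- unique(
      distal$probe_id[distal$reg_class != "uncorrelated"])
    ctcf <- if (length(study$ctcf_sites) > 0) {
      ctcf_overlap(attr(mapping, "distal_probes"), study$manifest,
                   motif_sites = study$ctcf_sites)
    } else character(0)

    stage <- "umi4c"
    pa <- distance_filter(study$contacts$a)
    pb <- distance_filter(study$contacts$b)
    dg <- domainogram(pa, pb, scales = domainogram_scales)
    if (is.null(umi4c_window)) {
      umi4c_window <- which.max(abs(dg[1, ]))
    }
    ct <- contact_test(pa, pb, umi4c_window)

    n_pass <- length(passing)
    counts <- list(
      n_probes = nrow(dmcs),
      n_significant = n_pass,
      n_hypo = sum(dmcs$passes & dmcs$direction == "hypo"),
      n_hyper = sum(dmcs$passes & dmcs$direction == "hyper"),
      fraction_macrophage_like = attr(conc, "fraction_macrophage_like"),
      n_gene_associated = length(part$gene_associated),
      n_non_gene = length(part$non_gene),
      pct_gene_associated = unname(part$fractions_pct["gene_associated"]),
      pct_non_gene = unname(part$fractions_pct["non_gene"]),
      n_local_correlated_probes = length(correlated_local),
      n_local_genes = length(unique(
        local$gene[local$link_class != "none"])),
      n_activation = sum(local$link_class == "activation"),
      n_repression = sum(local$link_class == "repression"),
      n_tfs = tf_map$n_tfs,
      n_enriched_categories = sum(enrich$q < 0.05),
      top_categories = utils::head(enrich$category, 3),
      n_distal_probes = length(attr(mapping, "distal_probes")),
      n_distal_correlated = dsum$n_probes_correlated,
      n_target_genes = dsum$n_target_genes,
      n_enhancer_genes = dsum$n_enhancer_genes,
      n_silencer_genes = dsum$n_silencer_genes,
      multiplicity = mult,
      n_ctcf = length(ctcf),
      loop_window = ct$window[1],
      loop_chi2 = ct$chi2[1],
      loop_p_adj = ct$p_adj[1]
    )
    structure(list(
      counts = counts,
      results = list(dmcs = dmcs, concordance = conc, partition = part,
                     local_links = local, tf_overlap = tf_map,
                     enrichment = enrich, mapping = mapping,
                     distal_links = distal, multiplicity = mult,
                     ctcf_probes = ctcf, domainogram = dg,
                     contact_test = ct,
                     profiles = list(a = pa, b = pb)),
      config = study$config, seed = study$config$seed, paths = NULL
    ), class = "run_report")
  }, error = function(e) {
    .stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  if (!is.null(out_dir)) report$paths <- .write_report(report, out_dir)
  report
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(out_dir, x)
  res <- report$results
  wt <- function(x, name) {
    utils::write.table(as.data.frame(x), f(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f(name)
  }
  paths <- c(
    dmc = wt(res$dmcs, "dmc.tsv"),
    concordance = wt(res$concordance, "concordance.tsv"),
    local_links = wt(res$local_links, "local_links.tsv"),
    enrichment = wt(res$enrichment, "enrichment.tsv"),
    distal_links = wt(res$distal_links, "distal_links.tsv"),
    contact_test = wt(res$contact_test, "contact_test.tsv"),
    domainogram = wt(cbind(attr(res$domainogram, "fragments"),
                           t(unclass(res$domainogram))),
                     "domainogram.tsv")
  )
  if (!is.null(report$config)) {
    yaml::write_yaml(unclass(report$config), f("config_echo.yaml"))
    paths <- c(paths, config = f("config_echo.yaml"))
  }
  co <- report$counts
  flat <- co[vapply(co, function(v) is.numeric(v) && length(v) == 1,
                    logical(1))]
  flat <- c(flat, as.list(co$multiplicity))
  utils::write.table(
    data.frame(key = names(flat), value = unlist(flat)),
    f("report.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::capture.output(print(report), file = f("report.txt"))
  c(paths, report_tsv = f("report.tsv"), report = f("report.txt"))
}

#' @export
print.run_report <- function(x, ...) {
  co <- x$counts
  cat("=== pipeline run report ===\n")
  if (!is.null(x$seed)) cat(sprintf("seed: %d\n", x$seed))
  cat(sprintf("significant CpGs: %d of %d probes (%d hypo [%s], %d hyper)\n",
              co$n_significant, co$n_probes, co$n_hypo,
              if (co$n_significant > 0) .pct1(co$n_hypo / co$n_significant)
              else "-", co$n_hyper))
  cat(sprintf("macrophage-like at 168 h: %s of significant CpGs\n",
              if (is.na(co$fraction_macrophage_like)) "-" else
                .pct1(co$fraction_macrophage_like)))
  cat(sprintf("gene-associated: %d (%.1f%%); non-gene: %d (%.1f%%)\n",
              co$n_gene_associated, co$pct_gene_associated,
              co$n_non_gene, co$pct_non_gene))
  cat(sprintf("local links: %d CpGs / %d genes correlated (%d activation, %d repression)\n",
              co$n_local_correlated_probes, co$n_local_genes,
              co$n_activation, co$n_repression))
  cat(sprintf("TF binding sites overlapped: %d TFs; %d enriched categories (q < 0.05)\n",
              co$n_tfs, co$n_enriched_categories))
  if (length(co$top_categories) > 0) {
    cat(sprintf("  top: %s\n", paste(co$top_categories, collapse = "; ")))
  }
  cat(sprintf("distal (PCHi-C other-end) CpGs: %d; correlated: %d -> %d target genes (%d enhancer, %d silencer)\n",
              co$n_distal_probes, co$n_distal_correlated, co$n_target_genes,
              co$n_enhancer_genes, co$n_silencer_genes))
  cat(sprintf("multiplicity: unique %d, dual %d, complex %d; CTCF-motif CpGs: %d\n",
              co$multiplicity["unique"], co$multiplicity["dual"],
              co$multiplicity["complex"], co$n_ctcf))
  cat(sprintf("UMI-4C top window %s: chi2 = %.1f, adjusted p = %.3g\n",
              co$loop_window, co$loop_chi2, co$loop_p_adj))
  invisible(x)
}
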