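# Promoter-capture Hi-C integration: place significant CpGs into interaction
# other-ends, correlate their methylation with looped target-gene expression,
# and classify candidate enhancers vs silencers.

#' Map CpGs into PCHi-C other-end fragments
#'
#' A probe maps to every interaction whose other-end fragment contains its
#' manifest position. Probes with at least one hit form the distal-regulatory
#' subset; gene-associated probes are eligible too, since a CpG near a gene
#' can also act as a long-range interactor sequence.
#'
#' @param probes Character vector of probe ids (typically the passing DMCs).
#' @param interactions An \code{\link{interaction_set}}.
#' @param manifest A \code{\link{probe_manifest}}.
#' @param include_bait Also map probes falling inside bait fragments
#'   (default \code{FALSE}: other-end only).
#' @param min_score Optional interaction-score threshold; interactions below
#'   it are ignored (default \code{NULL}: calls are assumed pre-filtered).
#' @return Data frame of class \code{"cpg_interaction_map"} with columns
#'   \code{probe_id}, \code{interaction_id}; the distal probe subset is in
#'   attribute \code{distal_probes}.
#' @export
map_cpgs_to_other_ends <- function(probes, interactions, manifest,
                                   include_bait = FALSE, min_score = NULL) {
  probes <- as.character(probes)
  i <- match(probes, manifest$probe_id)
  if (anyNA(i)) {
    .stopf("annotation error: probe '%s' absent from manifest",
           probes[which(is.na(i))[1]])
  }
  ints <- interactions
  if (!is.null(min_score)) ints <- ints[ints$score >= min_score, , drop = FALSE]
  pairs <- data.frame(probe_id = character(0), interaction_id = character(0),
                      stringsAsFactors = FALSE)
  if (length(probes) > 0 && nrow(ints) > 0) {
    pos <- .pos_gr(manifest$chrom[i], manifest$pos[i])
    oe <- .gr0(ints$otherEnd_chr, ints$otherEnd_start, ints$otherEnd_end)
    hits <- GenomicRanges::findOverlaps(pos, oe, ignore.strand = TRUE)
    pairs <- data.frame(
      probe_id = probes[S4Vectors::queryHits(hits)],
      interaction_id = ints$id[S4Vectors::subjectHits(hits)],
      stringsAsFactors = FALSE
    )
    if (include_bait) {
      bt <- .gr0(ints$bait_chr, ints$bait_start, ints$bait_end)
      bhits <- GenomicRanges::findOverlaps(pos, bt, ignore.strand = TRUE)
      pairs <- unique(rbind(pairs, data.frame(
        probe_id = probes[S4Vectors::queryHits(bhits)],
        interaction_id = ints$id[S4Vectors::subjectHits(bhits)],
        stringsAsFactors = FALSE
      )))
    }
    pairs <- pairs[order(pairs$probe_id, pairs$interaction_id), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  attr(pairs, "distal_probes") <- sort(unique(pairs$probe_id))
  class(pairs) <- c("cpg_interaction_map", "data.frame")
  pairs
}

#' Classify distal CpG-gene links as enhancer or candidate silencer
#'
#' For every (probe, interaction, bait gene) triple of the mapping with an
#' expression row, correlates the probe's per-timepoint mean beta with the
#' looped target gene's expression (exact permutation test, see
#' \code{\link{correlate_series}}). A hypomethylated probe whose
#' demethylation tracks expression gain (r < 0) is a candidate
#' \code{"enhancer"}; one whose demethylation tracks expression loss
#' (r > 0) is a candidate \code{"silencer"}; signs invert for
#' hypermethylated probes; non-significant links are
#' \code{"uncorrelated"}. An interaction with two bait genes yields two
#' candidate links (genes, not interactions, are counted downstream).
#'
#' @param mapping Output of \code{\link{map_cpgs_to_other_ends}}.
#' @param dmcs A \code{dmc_result} supplying probe directions (or a probe id
#'   vector, then all treated as hypomethylated).
#' @param interactions The \code{\link{interaction_set}} used for the
#'   mapping.
#' @param bm A \code{\link{beta_matrix}}.
#' @param expr Expression matrix (genes x timepoints, log2).
#' @param manifest A \code{\link{probe_manifest}} (for the CpG context
#'   label).
#' @param link_p_threshold Permutation-p threshold (default 0.05).
#' @return Data frame of class \code{"distal_links"}: \code{probe_id},
#'   \code{interaction_id}, \code{target_gene}, \code{r}, \code{p_perm},
#'   \code{direction}, \code{reg_class}, \code{cpg_context}.
#' @export
build_distal_links <- function(mapping, dmcs, interactions, bm, expr,
                               manifest, link_p_threshold = 0.05) {
  dirs <- .probe_directions(dmcs)
  rows <- list()
  uncovered <- character(0)
  for (k in seq_len(nrow(mapping))) {
    p <- mapping$probe_id[k]
    id <- mapping$interaction_id[k]
    genes <- bait_genes(interactions, id)
    if (length(genes) == 0) next
    series <- .probe_timecourse(bm, p)
    ctx <- .cpg_context(p, manifest)
    for (g in genes) {
      y <- .expr_series(expr, g, as.integer(names(series)))
      if (is.null(y)) {
        uncovered <- c(uncovered, g)
        next
      }
      cs <- .safe_correlate(as.numeric(series), y)
      dir <- unname(dirs[p])
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = p, interaction_id = id, target_gene = g,
        r = cs$r, p_perm = cs$p_perm, direction = dir,
        reg_class = .link_class(cs$r, cs$p_perm, dir, link_p_threshold,
                                labels = c("enhancer", "silencer", "uncorrelated")),
        cpg_context = ctx, stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(rows) > 0) do.call(rbind, rows) else data.frame(
    probe_id = character(0), interaction_id = character(0),
    target_gene = character(0), r = numeric(0), p_perm = numeric(0),
    direction = character(0), reg_class = character(0),
    cpg_context = character(0), stringsAsFactors = FALSE
  )
  attr(res, "uncovered") <- unique(uncovered)
  attr(res, "link_p_threshold") <- link_p_threshold
  class(res) <- c("distal_links", "data.frame")
  res
}

# Per-gene regulatory class over the classified links: a gene is assigned the
# class of its strongest link (smallest p_perm; ties by larger |r|, then
# enhancer). Guarantees enhancer + silencer gene counts partition the
# distinct correlated target genes.
.gene_classes <- function(links) {
  sig <- links[links$reg_class != "uncorrelated", , drop = FALSE]
  if (nrow(sig) == 0) return(stats::setNames(character(0), character(0)))
  sig <- sig[order(sig$p_perm, -abs(sig$r), sig$reg_class), , drop = FALSE]
  first <- sig[!duplicated(sig$target_gene), , drop = FALSE]
  stats::setNames(first$reg_class, first$target_gene)
}

#' @method summary distal_links
#' @export
summary.distal_links <- function(object, ...) {
  sig <- object[object$reg_class != "uncorrelated", , drop = FALSE]
  gc <- .gene_classes(object)
  out <- list(
    n_links_tested = nrow(object),
    n_probes_mapped = length(unique(object$probe_id)),
    n_probes_correlated = length(unique(sig$probe_id)),
    n_target_genes = length(gc),
    n_enhancer_genes = sum(gc == "enhancer"),
    n_silencer_genes = sum(gc == "silencer")
  )
  class(out) <- "summary.distal_links"
  out
}

#' @export
print.summary.distal_links <- function(x, ...) {
  cat(sprintf(
    "distal links: %d mapped probes, %d correlated; %d target genes (%d enhancer, %d silencer)\n",
    x$n_probes_mapped, x$n_probes_correlated, x$n_target_genes,
    x$n_enhancer_genes, x$n_silencer_genes
  ))
  invisible(x)
}

#' @export
print.distal_links <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' Interaction multiplicity of classified distal CpGs
#'
#' Counts, per classified probe, the distinct target genes with a
#' significant link: one gene is a unique interaction, two genes dual, three
#' or more complex. The three counts partition the classified probes.
#'
#' @param links A \code{\link{build_distal_links}} result.
#' @return Named integer vector \code{c(unique, dual, complex)}.
#' @export
multiplicity_classes <- function(links) {
  sig <- links[links$reg_class != "uncorrelated", , drop = FALSE]
  if (nrow(sig) == 0) return(c(unique = 0L, dual = 0L, complex = 0L))
  per_probe <- tapply(sig$target_gene, sig$probe_id,
                      function(g) length(unique(g)))
  c(unique = sum(per_probe == 1L),
    dual = sum(per_probe == 2L),
    complex = sum(per_probe >= 3L))
}

#' CpGs overlapping CTCF binding motifs
#'
#' Either intersects probe positions with a supplied motif-site interval
#' track, or scans a supplied sequence for an IUPAC consensus pattern on both
#' strands and intersects with the match footprints.
#'
#' @param probes Character vector of probe ids.
#' @param manifest A \code{\link{probe_manifest}}.
#' @param motif_sites Optional \code{GRanges} of motif sites (e.g. from
#'   \code{\link{read_bed}}).
#' @param sequence Optional character or \code{DNAString}: the chromosome
#'   sequence (probe positions are 1-based offsets into it).
#' @param pattern IUPAC consensus to scan when \code{sequence} is given.
#' @param seq_chrom Chromosome name the sequence represents (default: the
#'   single chromosome in the manifest).
#' @return Character vector: the subset of \code{probes} inside a motif site.
#' @export
ctcf_overlap <- function(probes, manifest, motif_sites = NULL,
                         sequence = NULL, pattern = NULL, seq_chrom = NULL) {
  probes <- as.character(probes)
  if (is.null(motif_sites) && is.null(sequence)) {
    .stopf("config error: supply either `motif_sites` or `sequence` + `pattern`")
  }
  if (is.null(motif_sites)) {
    if (is.null(pattern)) .stopf("config error: `pattern` required with `sequence`")
    if (is.null(seq_chrom)) {
      seq_chrom <- unique(manifest$chrom)
      if (length(seq_chrom) != 1) {
        .stopf("config error: `seq_chrom` required for a multi-chromosome manifest")
      }
    }
    motif_sites <- scan_motif(sequence, pattern, chrom = seq_chrom)
  }
  if (length(motif_sites) == 0 || length(probes) == 0) return(character(0))
  i <- match(probes, manifest$probe_id)
  if (anyNA(i)) {
    .stopf("annotation error: probe '%s' absent from manifest",
           probes[which(is.na(i))[1]])
  }
  pos <- .pos_gr(manifest$chrom[i], manifest$pos[i])
  hits <- GenomicRanges::findOverlaps(pos, motif_sites, ignore.strand = TRUE)
  sort(unique(probes[S4Vectors::queryHits(hits)]))
}

#' Scan a sequence for an IUPAC consensus on both strands
#'
#' @param sequence Character or \code{DNAString}.
#' @param pattern IUPAC consensus string.
#' @param chrom Chromosome name for the returned ranges.
#' @return \code{GRanges} of match footprints in forward coordinates
#'   (1-based closed), strand recording the matched orientation.
#' @export
scan_motif <- function(sequence, pattern, chrom = "chrS") {
  seq <- Biostrings::DNAString(as.character(sequence))
  fwd <- Biostrings::matchPattern(Biostrings::DNAString(pattern), seq,
                                  fixed = FALSE)
  rev <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(pattern)), seq,
    fixed = FALSE
  )
  mk <- function(m, strand) {
    if (length(m) == 0) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(chrom, IRanges::IRanges(IRanges::start(m),
                                                   IRanges::end(m)),
                           strand = strand)
  }
  out <- c(mk(fwd, "+"), mk(rev, "-"))
  GenomicRanges::sort(out, ignore.strand = TRUE)
}
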