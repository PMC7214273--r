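# Genomic-context annotation of significant CpGs from the probe manifest.

.PROMOTER_CLASSES <- c("TSS1500", "TSS200", "5UTR", "FirstExon")

#' Partition probes by gene association
#'
#' Splits a probe set into gene-associated probes (non-empty gene symbol
#' list in the manifest) and probes in genomic regions without any annotated
#' gene. The two sets are disjoint and their union is the input; a probe
#' annotated to several genes is counted once.
#'
#' @param probes Character vector of probe ids (all present in the manifest).
#' @param manifest A \code{\link{probe_manifest}}.
#' @return List with elements \code{gene_associated}, \code{non_gene}
#'   (character vectors preserving input order) and \code{fractions_pct}
#'   (named numeric, percentages rounded to one decimal).
#' @export
partition_by_gene <- function(probes, manifest) {
  probes <- as.character(probes)
  i <- match(probes, manifest$probe_id)
  if (anyNA(i)) {
    .stopf("annotation error: probe '%s' absent from manifest",
           probes[which(is.na(i))[1]])
  }
  has_gene <- manifest$gene_symbols[i] != ""
  n <- length(probes)
  fr <- if (n > 0) {
    c(gene_associated = round(100 * sum(has_gene) / n, 1),
      non_gene = round(100 * sum(!has_gene) / n, 1))
  } else {
    c(gene_associated = NA_real_, non_gene = NA_real_)
  }
  list(
    gene_associated = probes[has_gene],
    non_gene = probes[!has_gene],
    fractions_pct = fr
  )
}

#' Promoter status of a (probe, gene) annotation
#'
#' A probe is in the promoter of its annotated gene when its manifest
#' feature class for that gene is TSS1500, TSS200, 5UTR or FirstExon (the
#' standard EPIC-manifest promoter set); Body and 3UTR are nonpromoter.
#'
#' @param probe_id Single probe id.
#' @param gene Gene symbol the probe is annotated to.
#' @param manifest A \code{\link{probe_manifest}}.
#' @return \code{"promoter"} or \code{"nonpromoter"}.
#' @export
promoter_status <- function(probe_id, gene, manifest) {
  i <- match(probe_id, manifest$probe_id)
  if (is.na(i)) .stopf("annotation error: probe '%s' absent from manifest", probe_id)
  genes <- .split_field(manifest$gene_symbols[i])
  feats <- .split_field(manifest$feature_classes[i])
  j <- match(gene, genes)
  if (is.na(j)) {
    .stopf("probe '%s' is not annotated to gene '%s'", probe_id, gene)
  }
  if (feats[j] %in% .PROMOTER_CLASSES) "promoter" else "nonpromoter"
}

# Context label for a probe: non_gene, gene_promoter (promoter for at least
# one annotated gene) or gene_nonpromoter.
.cpg_context <- function(probe_id, manifest) {
  genes <- manifest_genes(manifest, probe_id)
  if (length(genes) == 0) return("non_gene")
  st <- vapply(genes, function(g) promoter_status(probe_id, g, manifest),
               character(1))
  if (any(st == "promoter")) "gene_promoter" else "gene_nonpromoter"
}
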