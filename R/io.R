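#' Construct a beta-value matrix with sample metadata
#'
#' Bundles a probes x samples matrix of methylation beta values (each in
#' \[0,1\]) with a sample metadata table. Samples belong to a
#' transdifferentiation timecourse (condition \code{"transdiff"} with a
#' timepoint in hours) or to a control profile (\code{"negative_control"},
#' the untreated parental line; \code{"positive_control"}, the target cell
#' type), for which \code{timepoint_h} is \code{NA}.
#'
#' @param beta Numeric matrix, probes in rows (rownames = probe ids), samples
#'   in columns (colnames = sample ids). All values must be finite and in
#'   \[0,1\].
#' @param samples Data frame with columns \code{sample_id},
#'   \code{timepoint_h}, \code{replicate}, \code{condition}; one row per
#'   column of \code{beta}.
#' @return An object of class \code{"beta_matrix"}: a list with elements
#'   \code{beta} and \code{samples} (reordered to match the columns).
#' @export
beta_matrix <- function(beta, samples) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    .stopf("`beta` must be a numeric matrix")
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    .stopf("`beta` must carry probe rownames and sample colnames")
  }
  bad <- which(!is.finite(beta) | beta < 0 | beta > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    .stopf(
      "malformed beta value %s for probe '%s', sample '%s' (must be in [0,1])",
      format(beta[bad[1, 1], bad[1, 2]]),
      rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]]
    )
  }
  req <- c("sample_id", "timepoint_h", "replicate", "condition")
  if (!is.data.frame(samples) || !all(req %in% names(samples))) {
    .stopf("`samples` must be a data frame with columns %s",
           paste(req, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) .stopf("duplicated sample_id in metadata")
  missing <- setdiff(colnames(beta), samples$sample_id)
  if (length(missing) > 0) {
    .stopf("metadata error: no metadata row for sample column '%s'", missing[1])
  }
  samples <- samples[match(colnames(beta), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  ok_cond <- c("transdiff", "negative_control", "positive_control")
  if (!all(samples$condition %in% ok_cond)) {
    .stopf("condition must be one of %s", paste(ok_cond, collapse = ", "))
  }
  td <- samples$condition == "transdiff"
  if (any(td & is.na(samples$timepoint_h))) {
    .stopf("transdiff samples must have a non-missing timepoint_h")
  }
  samples$timepoint_h <- as.integer(samples$timepoint_h)
  samples$replicate <- as.integer(samples$replicate)
  structure(list(beta = beta, samples = samples), class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  tp <- sort(unique(x$samples$timepoint_h[x$samples$condition == "transdiff"]))
  cat(sprintf(
    "beta_matrix: %d probes x %d samples (%d timepoints: %s h; %d control samples)\n",
    nrow(x$beta), ncol(x$beta), length(tp), paste(tp, collapse = ", "),
    sum(x$samples$condition != "transdiff")
  ))
  invisible(x)
}

#' Read / write a beta matrix as TSV
#'
#' The matrix file is tab-separated with a \code{probe_id} first column and
#' one column per sample; the metadata file maps \code{sample_id} to
#' timepoint, replicate and condition. Values outside \[0,1\] raise an error
#' naming the offending probe and sample.
#'
#' @param path Path of the matrix TSV.
#' @param meta_path Path of the sample metadata TSV.
#' @return A \code{\link{beta_matrix}}.
#' @export
read_beta_matrix <- function(path, meta_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) .stopf("beta matrix '%s' has no sample columns", path)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) .stopf("non-numeric beta values in '%s'", path)
  rownames(mat) <- as.character(tab[[1]])
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  if ("timepoint_h" %in% names(meta)) {
    meta$timepoint_h <- suppressWarnings(as.integer(meta$timepoint_h))
  }
  beta_matrix(mat, meta)
}

#' @rdname read_beta_matrix
#' @param x A \code{beta_matrix}.
#' @export
write_beta_matrix <- function(x, path, meta_path) {
  stopifnot(inherits(x, "beta_matrix"))
  out <- data.frame(probe_id = rownames(x$beta), x$beta,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, meta_path))
}

#' Read / write a gene expression matrix as TSV
#'
#' Genes in rows (first column \code{gene}), one column per transdiff
#' timepoint named \code{t<hours>} (e.g. \code{t0}, \code{t168}). Values are
#' taken as already on a log2 scale; no re-normalisation is applied.
#'
#' @param path File path.
#' @return Numeric matrix, genes x timepoints, with an attribute
#'   \code{timepoints_h} giving the hours per column.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- as.character(tab[[1]])
  if (!is.numeric(mat) || any(!is.finite(mat))) {
    .stopf("expression matrix '%s' contains non-finite values", path)
  }
  attr(mat, "timepoints_h") <- as.integer(sub("^t", "", colnames(mat)))
  mat
}

#' @rdname read_expression
#' @param expr Expression matrix as returned by \code{read_expression}.
#' @export
write_expression <- function(expr, path) {
  out <- data.frame(gene = rownames(expr), expr,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a probe manifest
#'
#' EPIC-style manifest: one row per probe with the 1-based bp position of the
#' interrogated CpG, a possibly empty \code{';'}-joined gene symbol list and a
#' \code{';'}-joined feature-class list aligned with the genes (classes from
#' TSS1500, TSS200, 5UTR, FirstExon, Body, 3UTR).
#'
#' @param path File path of the manifest TSV.
#' @return Data frame of class \code{"probe_manifest"} with columns
#'   \code{probe_id}, \code{chrom}, \code{pos}, \code{gene_symbols},
#'   \code{feature_classes}.
#' @export
read_manifest <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(gene_symbols = "character",
                                          feature_classes = "character"))
  probe_manifest(tab)
}

#' @rdname read_manifest
#' @param manifest A \code{probe_manifest}.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_manifest
#' @param x Data frame with manifest columns.
#' @export
probe_manifest <- function(x) {
  req <- c("probe_id", "chrom", "pos", "gene_symbols", "feature_classes")
  if (!all(req %in% names(x))) {
    .stopf("manifest needs columns %s", paste(req, collapse = ", "))
  }
  x$gene_symbols[is.na(x$gene_symbols)] <- ""
  x$feature_classes[is.na(x$feature_classes)] <- ""
  if (any(x$pos < 1)) .stopf("manifest positions are 1-based; pos < 1 found")
  empty_g <- x$gene_symbols == ""
  empty_f <- x$feature_classes == ""
  if (any(empty_g != empty_f)) {
    .stopf("manifest invariant violated: gene_symbols empty iff feature_classes empty")
  }
  if (anyDuplicated(x$probe_id)) .stopf("duplicated probe_id in manifest")
  x <- x[, req]
  class(x) <- c("probe_manifest", "data.frame")
  x
}

# Split a ';'-joined manifest field into a character vector ("" -> empty).
.split_field <- function(s) {
  if (is.na(s) || s == "") character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
}

#' Genes annotated to a probe
#' @param manifest A \code{probe_manifest}.
#' @param probe_id Single probe id.
#' @return Character vector of gene symbols (possibly empty).
#' @export
manifest_genes <- function(manifest, probe_id) {
  i <- match(probe_id, manifest$probe_id)
  if (is.na(i)) .stopf("annotation error: probe '%s' absent from manifest", probe_id)
  .split_field(manifest$gene_symbols[i])
}

#' Read / write PCHi-C interaction calls (ibed dialect)
#'
#' One interaction per line with columns \code{bait_chr}, \code{bait_start},
#' \code{bait_end}, \code{bait_name} (\code{';'}-separated bait gene
#' symbols), \code{otherEnd_chr}, \code{otherEnd_start}, \code{otherEnd_end},
#' \code{otherEnd_name}, \code{N_reads}, \code{score}. Intervals are 0-based
#' half-open. Records with an empty bait_name are flagged unannotated but
#' retained.
#'
#' @param path File path.
#' @return Data frame of class \code{"interaction_set"} with the ibed columns
#'   plus a stable \code{id} and a logical \code{unannotated} flag.
#' @export
read_interactions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(bait_name = "character",
                                          otherEnd_name = "character"))
  interaction_set(tab)
}

#' @rdname read_interactions
#' @param x Data frame with ibed columns.
#' @export
interaction_set <- function(x) {
  req <- c("bait_chr", "bait_start", "bait_end", "bait_name",
           "otherEnd_chr", "otherEnd_start", "otherEnd_end", "otherEnd_name",
           "N_reads", "score")
  if (!all(req %in% names(x))) {
    .stopf("ibed table needs columns %s", paste(req, collapse = ", "))
  }
  if (!is.numeric(x$score)) .stopf("parse error: non-numeric interaction score")
  if (any(x$bait_end <= x$bait_start) || any(x$otherEnd_end <= x$otherEnd_start)) {
    .stopf("malformed interval in ibed record: end <= start")
  }
  if (any(x$bait_start < 0) || any(x$otherEnd_start < 0)) {
    .stopf("malformed interval in ibed record: negative start")
  }
  x$bait_name[is.na(x$bait_name)] <- ""
  x <- x[, req]
  x$id <- sprintf("int%04d", seq_len(nrow(x)))
  x$unannotated <- x$bait_name == "" | x$bait_name == "."
  class(x) <- c("interaction_set", "data.frame")
  x
}

#' @rdname read_interactions
#' @param interactions An \code{interaction_set}.
#' @export
write_interactions <- function(interactions, path) {
  cols <- c("bait_chr", "bait_start", "bait_end", "bait_name",
            "otherEnd_chr", "otherEnd_start", "otherEnd_end", "otherEnd_name",
            "N_reads", "score")
  utils::write.table(interactions[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Bait gene symbols of an interaction record
#' @param interactions An \code{interaction_set}.
#' @param id Interaction id.
#' @return Character vector of bait gene symbols (empty if unannotated).
#' @export
bait_genes <- function(interactions, id) {
  i <- match(id, interactions$id)
  if (is.na(i)) .stopf("unknown interaction id '%s'", id)
  g <- .split_field(interactions$bait_name[i])
  g[g != "."]
}

#' Read a BED track of named intervals
#'
#' BED3+ per UCSC conventions (0-based half-open on disk; returned as the
#' usual 1-based closed \code{GRanges}). Intervals are sorted by
#' (chrom, start). Strand is parsed but ignored by every overlap operation in
#' this package: CpG methylation is strand-symmetric.
#'
#' @param path File path.
#' @return A \code{GRanges}, possibly with a \code{name} metadata column;
#'   empty file yields an empty \code{GRanges}.
#' @export
read_bed <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(GenomicRanges::GRanges())
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) .stopf("malformed interval in BED '%s': %s", path,
                               conditionMessage(e))
  )
  if (any(GenomicRanges::start(gr) < 1)) {
    .stopf("malformed interval in BED '%s': negative start", path)
  }
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' @rdname read_bed
#' @param gr A \code{GRanges} to write.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a contact profile as bedGraph
#'
#' One record per restriction fragment. By default the depth-normalised UMI
#' count is written; pass \code{values} (e.g. from
#' \code{\link{smooth_profile}}) to export a smoothed trend line instead.
#'
#' @param profile A \code{\link{contact_profile}}.
#' @param path Output path.
#' @param values Optional numeric vector, one value per fragment.
#' @export
write_bedgraph <- function(profile, path, values = NULL) {
  stopifnot(inherits(profile, "contact_profile"))
  if (is.null(values)) {
    total <- sum(profile$umi_count)
    values <- if (total > 0) profile$umi_count / total else rep(0, nrow(profile))
  }
  if (length(values) != nrow(profile)) {
    .stopf("`values` must have one entry per fragment")
  }
  gr <- .gr0(profile$chrom, profile$start, profile$end, score = values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read / write per-fragment UMI-4C contact counts
#'
#' TSV with columns \code{chrom}, \code{start}, \code{end} (0-based
#' half-open restriction fragments) and \code{umi_count}.
#'
#' @param path File path.
#' @param bait_pos Bait position in bp on the fragment coordinate axis.
#' @param condition Condition label (e.g. \code{"t0"}).
#' @return A \code{\link{contact_profile}}.
#' @export
read_contacts <- function(path, bait_pos, condition) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  contact_profile(tab[, c("chrom", "start", "end")], tab$umi_count,
                  bait_pos = bait_pos, condition = condition)
}

#' @rdname read_contacts
#' @param profile A \code{contact_profile}.
#' @export
write_contacts <- function(profile, path) {
  utils::write.table(
    data.frame(chrom = profile$chrom, start = profile$start,
               end = profile$end, umi_count = profile$umi_count),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
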