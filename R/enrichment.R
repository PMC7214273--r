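# TF binding-site overlap and hypergeometric category enrichment.

#' Map CpGs to transcription-factor binding sites
#'
#' A probe maps to TF t iff its manifest position (1-based bp) lies inside at
#' least one track interval named t, under the package-wide coordinate
#' convention (a 1-based position p is inside a 0-based half-open interval
#' \[start, end) iff start <= p - 1 < end). Strand is ignored.
#'
#' @param probes Character vector of probe ids.
#' @param manifest A \code{\link{probe_manifest}} supplying positions.
#' @param tf_track \code{GRanges} of binding sites with a \code{name}
#'   metadata column holding the TF symbol (e.g. from
#'   \code{\link{read_bed}}).
#' @return List with \code{map} (named list: probe id -> sorted character
#'   vector of TF names, empty overlaps allowed), \code{tfs} (the union TF
#'   set, sorted) and \code{n_tfs}.
#' @export
overlap_tf_sites <- function(probes, manifest, tf_track) {
  probes <- as.character(probes)
  i <- match(probes, manifest$probe_id)
  if (anyNA(i)) {
    .stopf("annotation error: probe '%s' absent from manifest",
           probes[which(is.na(i))[1]])
  }
  map <- stats::setNames(rep(list(character(0)), length(probes)), probes)
  if (length(probes) > 0 && length(tf_track) > 0) {
    pos <- .pos_gr(manifest$chrom[i], manifest$pos[i])
    hits <- GenomicRanges::findOverlaps(pos, tf_track, ignore.strand = TRUE)
    nm <- as.character(S4Vectors::mcols(tf_track)$name)
    spl <- split(nm[S4Vectors::subjectHits(hits)], S4Vectors::queryHits(hits))
    for (q in names(spl)) map[[as.integer(q)]] <- sort(unique(spl[[q]]))
  }
  tfs <- sort(unique(unlist(map, use.names = FALSE)))
  list(map = map, tfs = tfs, n_tfs = length(tfs))
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing at least
#' k category members when n items are drawn without replacement from a
#' universe of N containing K members. Computed through the stable log-space
#' tail of \code{stats::phyper}.
#'
#' @param k Observed category members in the selection.
#' @param K Category members in the universe.
#' @param n Selection size.
#' @param N Universe size.
#' @return Probability in (0, 1\].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n)) {
    .stopf("invalid hypergeometric bounds: need 0 <= k <= min(K, n), K <= N, n <= N")
  }
  if (k == 0) return(1)
  .p_floor(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Category overrepresentation by hypergeometric test
#'
#' Tests each category for overrepresentation of the selected TF set against
#' the universe. Categories with no selected member (k = 0) are dropped; BH
#' q-values are computed over all tested categories. Results are sorted by
#' p ascending, ties broken by category name.
#'
#' @param selected Character vector, a subset of \code{universe} (e.g. the
#'   TFs whose sites overlap correlated CpGs).
#' @param universe Character vector of all eligible TFs (by default the TFs
#'   present in the supplied track).
#' @param category_map Data frame with columns \code{tf} and \code{category}
#'   (one row per membership), or a named list mapping TF -> character vector
#'   of categories. TFs absent from the map count in N but in no category.
#' @param adjust Multiplicity adjustment for the q column (default
#'   \code{"bh"}).
#' @return Data frame of class \code{"enrichment_result"}: \code{category},
#'   \code{k}, \code{K}, \code{n}, \code{N}, \code{p_hyper}, \code{q}.
#' @export
enrich_categories <- function(selected, universe, category_map,
                              adjust = c("bh", "none")) {
  adjust <- match.arg(adjust)
  selected <- unique(as.character(selected))
  universe <- unique(as.character(universe))
  if (!all(selected %in% universe)) {
    .stopf("selected set is not a subset of the universe (e.g. '%s')",
           setdiff(selected, universe)[1])
  }
  if (is.list(category_map) && !is.data.frame(category_map)) {
    category_map <- data.frame(
      tf = rep(names(category_map), lengths(category_map)),
      category = unlist(category_map, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("tf", "category") %in% names(category_map)))
  category_map <- category_map[category_map$tf %in% universe, , drop = FALSE]
  N <- length(universe)
  n <- length(selected)
  cats <- sort(unique(category_map$category))
  rows <- lapply(cats, function(cc) {
    members <- unique(category_map$tf[category_map$category == cc])
    K <- length(members)
    k <- length(intersect(members, selected))
    if (k < 1) return(NULL)
    data.frame(category = cc, k = k, K = K, n = n, N = N,
               p_hyper = hypergeom_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  res <- if (length(rows) > 0) do.call(rbind, rows) else data.frame(
    category = character(0), k = integer(0), K = integer(0), n = integer(0),
    N = integer(0), p_hyper = numeric(0), stringsAsFactors = FALSE
  )
  res$q <- if (adjust == "bh") stats::p.adjust(res$p_hyper, "BH") else res$p_hyper
  res <- res[order(res$p_hyper, res$category), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}
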