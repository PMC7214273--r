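# Methylation-expression linkage across the timecourse.
#
# With only seven timepoints the t-approximation for a Pearson correlation is
# poor, so significance comes from an exact permutation test: the two-sided p
# is the fraction of all n! pairings (identity included) whose |r| reaches
# the observed |r|. For n <= 8 all n! pairings are enumerated; beyond that a
# seeded Monte-Carlo sample of pairings is used with an add-one estimator.

#' Correlation of two short series with an exact permutation p-value
#'
#' @param x,y Numeric vectors of equal length n >= 3, both non-constant
#'   (typically per-timepoint mean beta and per-timepoint log2 expression).
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param n_perm Number of Monte-Carlo permutations when n > exact_n_max.
#' @param perm_seed Seed for the Monte-Carlo path (ignored when enumerating).
#' @param exact_n_max Largest n for which the n! pairings are fully
#'   enumerated (default 8; lower it to force the Monte-Carlo path).
#' @return List with \code{r}, \code{p_perm} and \code{method}
#'   (\code{"enumeration"} or \code{"monte_carlo"}).
#' @export
correlate_series <- function(x, y, method = c("pearson", "spearman"),
                             n_perm = 10000, perm_seed = 1L,
                             exact_n_max = 8L) {
  method <- match.arg(method)
  n <- length(x)
  if (length(y) != n) .stopf("x and y must have equal length")
  if (n < 3) .stopf("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    .stopf("undefined correlation: constant series")
  }
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  r_obs <- stats::cor(x, y)
  if (n <= exact_n_max) {
    perms <- .permutations(n)
    # r for permuted y depends only on sum(x * y[perm]); precompute moments
    sx <- sum(x); sy <- sum(y)
    ssx <- sum(x^2); ssy <- sum(y^2)
    denom <- sqrt(ssx - sx^2 / n) * sqrt(ssy - sy^2 / n)
    sxy <- as.numeric(matrix(x, 1) %*% matrix(y[t(perms)], nrow = n))
    r_perm <- (sxy - sx * sy / n) / denom
    p <- mean(abs(r_perm) >= abs(r_obs) - 1e-12)
    list(r = r_obs, p_perm = p, method = "enumeration")
  } else {
    p <- .local_seed(perm_seed, {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        if (abs(stats::cor(x, sample(y))) >= abs(r_obs) - 1e-12) hits <- hits + 1L
      }
      (1 + hits) / (1 + n_perm)
    })
    list(r = r_obs, p_perm = p, method = "monte_carlo")
  }
}

# correlate_series that degrades gracefully on constant series (possible in
# noiseless simulations): such pairs carry no evidence, r = NA and p = 1.
.safe_correlate <- function(x, y, method = "pearson") {
  tryCatch(correlate_series(x, y, method = method),
           error = function(e) list(r = NA_real_, p_perm = 1,
                                    method = "degenerate"))
}

# Per-timepoint mean beta of one probe across transdiff replicates.
.probe_timecourse <- function(bm, probe_id) {
  i <- match(probe_id, rownames(bm$beta))
  if (is.na(i)) .stopf("probe '%s' not in beta matrix", probe_id)
  td <- bm$samples$condition == "transdiff"
  tp <- bm$samples$timepoint_h[td]
  vals <- bm$beta[i, td]
  means <- tapply(vals, tp, mean)
  tps <- as.integer(names(means))
  ord <- order(tps)
  stats::setNames(as.numeric(means[ord]), tps[ord])
}

# Match expression columns to the timepoints of a beta series.
.expr_series <- function(expr, gene, timepoints) {
  i <- match(gene, rownames(expr))
  if (is.na(i)) return(NULL)
  hours <- attr(expr, "timepoints_h")
  if (is.null(hours)) hours <- as.integer(sub("^t", "", colnames(expr)))
  j <- match(timepoints, hours)
  if (anyNA(j)) return(NULL)
  as.numeric(expr[i, j])
}

# Classify a significant correlation relative to the probe's methylation
# direction. For a hypomethylated probe, r < 0 means expression rises as beta
# falls (activation); r > 0 means demethylation tracks expression loss
# (repression). Signs invert for hypermethylated probes.
.link_class <- function(r, p, direction, threshold,
                        labels = c("activation", "repression", "none")) {
  if (!is.finite(r) || p >= threshold) return(labels[3])
  sign_r <- if (direction == "hypo") r else -r
  if (sign_r < 0) labels[1] else labels[2]
}

#' Link passing DMCs to expression of their annotated genes
#'
#' For every (passing probe, annotated gene) pair with an expression row,
#' correlates the per-timepoint mean beta with the gene's expression across
#' the timecourse and classifies significant links: for a hypomethylated
#' probe, demethylation with expression gain (r < 0) is
#' \code{"activation"}, demethylation with expression loss (r > 0) is
#' \code{"repression"}; signs invert for hypermethylated probes. A probe
#' annotated to k genes yields up to k independently tested links.
#'
#' @param dmcs A \code{dmc_result} or character vector of probe ids
#'   (then all treated as hypomethylated).
#' @param manifest A \code{\link{probe_manifest}}.
#' @param bm A \code{\link{beta_matrix}}.
#' @param expr Expression matrix from \code{\link{read_expression}} or the
#'   simulator, genes x timepoints, log2 scale.
#' @param link_p_threshold Permutation-p threshold for a significant link
#'   (default 0.05).
#' @param adjust \code{"none"} (default, each link tested independently) or
#'   \code{"bh"} to classify on BH-adjusted permutation p-values.
#' @param method Correlation flavour, passed to
#'   \code{\link{correlate_series}}.
#' @return Data frame of class \code{"local_links"}: \code{probe_id},
#'   \code{gene}, \code{r}, \code{p_perm}, \code{direction},
#'   \code{link_class}. Genes without expression rows are listed in the
#'   \code{uncovered} attribute.
#' @export
build_local_links <- function(dmcs, manifest, bm, expr,
                              link_p_threshold = 0.05,
                              adjust = c("none", "bh"),
                              method = c("pearson", "spearman")) {
  adjust <- match.arg(adjust)
  method <- match.arg(method)
  probes <- .passing_probes(dmcs)
  dirs <- .probe_directions(dmcs)
  rows <- list()
  uncovered <- character(0)
  for (p in probes) {
    genes <- manifest_genes(manifest, p)
    if (length(genes) == 0) next
    series <- .probe_timecourse(bm, p)
    for (g in genes) {
      y <- .expr_series(expr, g, as.integer(names(series)))
      if (is.null(y)) {
        uncovered <- c(uncovered, g)
        next
      }
      cs <- .safe_correlate(as.numeric(series), y, method = method)
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = p, gene = g, r = cs$r, p_perm = cs$p_perm,
        direction = unname(dirs[p]), stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(rows) > 0) do.call(rbind, rows) else data.frame(
    probe_id = character(0), gene = character(0), r = numeric(0),
    p_perm = numeric(0), direction = character(0), stringsAsFactors = FALSE
  )
  p_class <- if (adjust == "bh") stats::p.adjust(res$p_perm, "BH") else res$p_perm
  res$link_class <- vapply(seq_len(nrow(res)), function(k) {
    .link_class(res$r[k], p_class[k], res$direction[k], link_p_threshold)
  }, character(1))
  attr(res, "uncovered") <- unique(uncovered)
  attr(res, "link_p_threshold") <- link_p_threshold
  class(res) <- c("local_links", "data.frame")
  res
}

#' @method summary local_links
#' @export
summary.local_links <- function(object, ...) {
  sig <- object[object$link_class != "none", , drop = FALSE]
  out <- list(
    n_links_tested = nrow(object),
    n_probes_linked = length(unique(sig$probe_id)),
    n_genes_linked = length(unique(sig$gene)),
    n_activation = sum(sig$link_class == "activation"),
    n_repression = sum(sig$link_class == "repression")
  )
  class(out) <- "summary.local_links"
  out
}

#' @export
print.summary.local_links <- function(x, ...) {
  cat(sprintf(
    "local links: %d tested; %d probes / %d genes significantly correlated (%d activation, %d repression)\n",
    x$n_links_tested, x$n_probes_linked, x$n_genes_linked,
    x$n_activation, x$n_repression
  ))
  invisible(x)
}

#' @export
print.local_links <- function(x, ...) {
  print(summary(x))
  invisible(x)
}
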