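# Differential CpG methylation calling over the transdifferentiation course.
#
# The caller applies the conjunction of an endpoint beta-change filter and a
# per-probe significance test: a probe passes when p < p_threshold (strict)
# AND |delta_beta| >= delta_threshold (inclusive). Statistics are computed on
# beta values directly; an M-value transform is available for the test stage
# only, never for the delta filter.

# Column indices of transdiff samples at a given timepoint.
.td_cols <- function(bm, t) {
  which(bm$samples$condition == "transdiff" &
          !is.na(bm$samples$timepoint_h) & bm$samples$timepoint_h == t)
}

.ctrl_cols <- function(bm, condition) which(bm$samples$condition == condition)

#' Endpoint beta change of a probe
#'
#' Signed change in mean methylation beta between two timepoints of the
#' transdifferentiation course, \eqn{\Delta\beta = \bar\beta(t_{to}) -
#' \bar\beta(t_{from})}.
#'
#' @param bm A \code{\link{beta_matrix}}.
#' @param probe_id Single probe id.
#' @param t_from,t_to Timepoints in hours (defaults 0 and 168).
#' @return Signed delta beta in \[-1, 1\].
#' @export
delta_beta <- function(bm, probe_id, t_from = 0, t_to = 168) {
  i <- match(probe_id, rownames(bm$beta))
  if (is.na(i)) .stopf("probe '%s' not in beta matrix", probe_id)
  c_from <- .td_cols(bm, t_from)
  c_to <- .td_cols(bm, t_to)
  if (length(c_from) < 1) .stopf("no transdiff samples at %d h", t_from)
  if (length(c_to) < 1) .stopf("no transdiff samples at %d h", t_to)
  mean(bm$beta[i, c_to]) - mean(bm$beta[i, c_from])
}

# Row-wise Welch two-sample t p-values (two-sided). Degenerate rows with zero
# pooled standard error get p = 1 when the means agree, else the smallest
# positive double (the statistic is infinite).
.welch_p_rows <- function(g1, g2) {
  n1 <- ncol(g1); n2 <- ncol(g2)
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- apply(g1, 1, stats::var); v2 <- apply(g2, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  p <- rep(1, length(m1))
  ok <- se2 > 0
  tt <- (m2[ok] - m1[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
  p[ok] <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  deg_diff <- !ok & m1 != m2
  p[deg_diff] <- .Machine$double.xmin
  .p_floor(p)
}

# Row-wise one-way ANOVA F p-values across groups given by `fac`.
.anova_p_rows <- function(mat, fac) {
  fac <- factor(fac)
  k <- nlevels(fac)
  n <- ncol(mat)
  if (k < 2) .stopf("anova_f requires >= 2 timepoints")
  if (n - k < 1) .stopf("anova_f requires replication (no residual df)")
  gm <- rowMeans(mat)
  group_means <- vapply(levels(fac), function(l) {
    rowMeans(mat[, fac == l, drop = FALSE])
  }, numeric(nrow(mat)))
  sizes <- as.numeric(table(fac))
  ss_between <- as.numeric((group_means - gm)^2 %*% sizes)
  ss_total <- rowSums((mat - gm)^2)
  ss_within <- ss_total - ss_between
  p <- rep(1, nrow(mat))
  ok <- ss_within > 0
  f <- (ss_between[ok] / (k - 1)) / (ss_within[ok] / (n - k))
  p[ok] <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  deg <- !ok & ss_between > 0
  p[deg] <- .Machine$double.xmin
  .p_floor(p)
}

# logit transform used by the optional M-value test stage
.m_values <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Per-probe significance test for methylation change
#'
#' \code{welch_t} compares the 0 h and 168 h replicate groups with a
#' two-sided Welch t-test (Welch-Satterthwaite degrees of freedom);
#' \code{anova_f} is a one-way F-test across all transdiff timepoints. When
#' both groups have zero variance and equal means the p-value is 1 by
#' convention.
#'
#' @inheritParams delta_beta
#' @param method Test to use, \code{"welch_t"} (default) or \code{"anova_f"}.
#' @param use_m_values Run the test on logit-transformed M-values instead of
#'   raw betas. Affects the test only; delta filtering always uses betas.
#' @return Two-sided p-value in (0, 1\].
#' @export
test_probe <- function(bm, probe_id, method = c("welch_t", "anova_f"),
                       use_m_values = FALSE) {
  method <- match.arg(method)
  i <- match(probe_id, rownames(bm$beta))
  if (is.na(i)) .stopf("probe '%s' not in beta matrix", probe_id)
  vals <- bm$beta[i, , drop = FALSE]
  if (use_m_values) vals <- .m_values(vals)
  if (method == "welch_t") {
    c0 <- .td_cols(bm, 0); c1 <- .td_cols(bm, 168)
    if (length(c0) < 2 || length(c1) < 2) {
      .stopf("welch_t requires >= 2 replicates at both 0 h and 168 h")
    }
    .welch_p_rows(vals[, c0, drop = FALSE], vals[, c1, drop = FALSE])
  } else {
    td <- bm$samples$condition == "transdiff"
    tp <- bm$samples$timepoint_h[td]
    counts <- table(tp)
    if (sum(counts >= 2) < 2) {
      .stopf("anova_f requires >= 2 replicates at >= 2 timepoints")
    }
    .anova_p_rows(vals[, td, drop = FALSE], tp)
  }
}

#' Call differentially methylated CpGs
#'
#' Scores every probe of the timecourse: endpoint \eqn{\Delta\beta} (168 h
#' minus 0 h), a per-probe p-value (see \code{\link{test_probe}}), a BH
#' q-value, a direction label (hypo when \eqn{\Delta\beta < 0}, hyper
#' otherwise) and the pass flag \eqn{p < p_{thr}} (strict, on the q-value
#' when \code{adjust = "bh"}) and \eqn{|\Delta\beta| \ge \delta_{thr}}
#' (inclusive).
#'
#' @inheritParams test_probe
#' @param p_threshold Significance threshold (default 0.05, strict \code{<}).
#' @param delta_threshold Minimum absolute beta change (default 0.66,
#'   inclusive \code{>=}).
#' @param adjust \code{"none"} filters on raw p (default); \code{"bh"}
#'   filters on the BH q-value.
#' @return Data frame of class \code{"dmc_result"}, one row per probe, with
#'   columns \code{probe_id}, \code{beta_t0}, \code{beta_t168},
#'   \code{delta_beta}, \code{p_value}, \code{q_value}, \code{direction},
#'   \code{passes}.
#' @export
call_dmcs <- function(bm, p_threshold = 0.05, delta_threshold = 0.66,
                      adjust = c("none", "bh"),
                      method = c("welch_t", "anova_f"),
                      use_m_values = FALSE) {
  adjust <- match.arg(adjust)
  method <- match.arg(method)
  if (nrow(bm$beta) == 0) .stopf("empty beta matrix")
  c0 <- .td_cols(bm, 0); c1 <- .td_cols(bm, 168)
  if (length(c0) < 1 || length(c1) < 1) {
    .stopf("transdiff samples required at both 0 h and 168 h")
  }
  beta_t0 <- rowMeans(bm$beta[, c0, drop = FALSE])
  beta_t168 <- rowMeans(bm$beta[, c1, drop = FALSE])
  delta <- beta_t168 - beta_t0
  vals <- if (use_m_values) .m_values(bm$beta) else bm$beta
  p <- if (method == "welch_t") {
    if (length(c0) < 2 || length(c1) < 2) {
      .stopf("welch_t requires >= 2 replicates at both 0 h and 168 h")
    }
    .welch_p_rows(vals[, c0, drop = FALSE], vals[, c1, drop = FALSE])
  } else {
    td <- bm$samples$condition == "transdiff"
    .anova_p_rows(vals[, td, drop = FALSE], bm$samples$timepoint_h[td])
  }
  q <- stats::p.adjust(p, method = "BH")
  p_filter <- if (adjust == "bh") q else p
  passes <- (p_filter < p_threshold) & (abs(delta) >= delta_threshold)
  res <- data.frame(
    probe_id = rownames(bm$beta),
    beta_t0 = beta_t0, beta_t168 = beta_t168, delta_beta = delta,
    p_value = p, q_value = q,
    direction = ifelse(delta < 0, "hypo", "hyper"),
    passes = passes,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(res, "p_threshold") <- p_threshold
  attr(res, "delta_threshold") <- delta_threshold
  attr(res, "adjust") <- adjust
  attr(res, "method") <- method
  class(res) <- c("dmc_result", "data.frame")
  res
}

#' @method summary dmc_result
#' @export
summary.dmc_result <- function(object, ...) {
  pass <- object[object$passes, , drop = FALSE]
  out <- list(
    n_probes = nrow(object),
    n_pass = nrow(pass),
    n_hypo = sum(pass$direction == "hypo"),
    n_hyper = sum(pass$direction == "hyper"),
    p_threshold = attr(object, "p_threshold"),
    delta_threshold = attr(object, "delta_threshold"),
    adjust = attr(object, "adjust")
  )
  class(out) <- "summary.dmc_result"
  out
}

#' @export
print.summary.dmc_result <- function(x, ...) {
  cat(sprintf(
    "DMC call: %d / %d probes pass (p < %g [%s], |delta beta| >= %g)\n",
    x$n_pass, x$n_probes, x$p_threshold, x$adjust, x$delta_threshold
  ))
  if (x$n_pass > 0) {
    cat(sprintf("  hypomethylated: %d (%s); hypermethylated: %d (%s)\n",
                x$n_hypo, .pct1(x$n_hypo / x$n_pass),
                x$n_hyper, .pct1(x$n_hyper / x$n_pass)))
  }
  invisible(x)
}

#' @export
print.dmc_result <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

# Probe ids passing the filter, from a dmc_result or a bare character vector.
.passing_probes <- function(dmcs) {
  if (inherits(dmcs, "dmc_result")) dmcs$probe_id[dmcs$passes]
  else as.character(dmcs)
}

# Direction lookup (named vector) for passing probes.
.probe_directions <- function(dmcs) {
  if (inherits(dmcs, "dmc_result")) {
    stats::setNames(dmcs$direction, dmcs$probe_id)
  } else {
    stats::setNames(rep("hypo", length(dmcs)), as.character(dmcs))
  }
}

#' Concordance of the transdifferentiation endpoint with control methylomes
#'
#' For each passing DMC, compares the mean 168 h beta with the
#' positive-control (target cell type) and negative-control (parental line)
#' mean betas. A probe is called \code{macrophage_like} when its endpoint is
#' within \code{tol} of the positive control and strictly closer to the
#' positive than to the negative control.
#'
#' @inheritParams call_dmcs
#' @param dmcs A \code{dmc_result} (its passing probes are used) or a
#'   character vector of probe ids.
#' @param tol Maximum absolute distance to the positive control (default 0.2).
#' @return Data frame with columns \code{probe_id}, \code{dist_to_positive},
#'   \code{dist_to_negative}, \code{macrophage_like}; the fraction
#'   macrophage-like is attached as attribute \code{fraction_macrophage_like}.
#' @export
control_concordance <- function(bm, dmcs, tol = 0.2) {
  probes <- .passing_probes(dmcs)
  pos <- .ctrl_cols(bm, "positive_control")
  neg <- .ctrl_cols(bm, "negative_control")
  if (length(pos) < 1) .stopf("no positive_control samples in metadata")
  if (length(neg) < 1) .stopf("no negative_control samples in metadata")
  c168 <- .td_cols(bm, 168)
  if (length(c168) < 1) .stopf("no transdiff samples at 168 h")
  i <- match(probes, rownames(bm$beta))
  if (anyNA(i)) .stopf("probe '%s' not in beta matrix", probes[which(is.na(i))[1]])
  b168 <- rowMeans(bm$beta[i, c168, drop = FALSE])
  bpos <- rowMeans(bm$beta[i, pos, drop = FALSE])
  bneg <- rowMeans(bm$beta[i, neg, drop = FALSE])
  dpos <- abs(b168 - bpos)
  dneg <- abs(b168 - bneg)
  res <- data.frame(
    probe_id = probes,
    dist_to_positive = dpos,
    dist_to_negative = dneg,
    macrophage_like = (dpos < tol) & (dpos < dneg),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(res, "fraction_macrophage_like") <-
    if (nrow(res) > 0) mean(res$macrophage_like) else NA_real_
  res
}
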