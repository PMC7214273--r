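# Bait-anchored UMI-4C contact profiles: distance filtering, smoothing,
# multi-scale domainograms and a 2x2 chi-square differential contact test.

#' Per-fragment UMI-4C contact profile
#'
#' Unique-molecule contact counts per restriction fragment around one bait,
#' for one condition. Fragments are 0-based half-open, non-overlapping and
#' sorted.
#'
#' @param fragments Data frame with columns \code{chrom}, \code{start},
#'   \code{end}.
#' @param counts Non-negative integer UMI counts, one per fragment.
#' @param bait_pos Bait position in bp.
#' @param condition Condition label.
#' @return Data frame of class \code{"contact_profile"} with columns
#'   \code{chrom}, \code{start}, \code{end}, \code{umi_count}; attributes
#'   \code{bait_pos}, \code{condition}, \code{total_umis}.
#' @export
contact_profile <- function(fragments, counts, bait_pos, condition) {
  stopifnot(all(c("chrom", "start", "end") %in% names(fragments)))
  if (length(counts) != nrow(fragments)) {
    .stopf("one UMI count per fragment required")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    .stopf("UMI counts must be non-negative integers")
  }
  if (any(fragments$end <= fragments$start)) {
    .stopf("malformed fragment: end <= start")
  }
  ord <- order(fragments$chrom, fragments$start)
  fragments <- fragments[ord, , drop = FALSE]
  counts <- counts[ord]
  if (any(fragments$start[-1] < fragments$end[-nrow(fragments)] &
            fragments$chrom[-1] == fragments$chrom[-nrow(fragments)])) {
    .stopf("fragments must be non-overlapping")
  }
  res <- data.frame(chrom = fragments$chrom, start = fragments$start,
                    end = fragments$end, umi_count = as.integer(counts),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "bait_pos") <- bait_pos
  attr(res, "condition") <- condition
  attr(res, "total_umis") <- sum(counts)
  class(res) <- c("contact_profile", "data.frame")
  res
}

#' @export
print.contact_profile <- function(x, ...) {
  cat(sprintf(
    "contact_profile [%s]: %d fragments, %d UMIs, bait at %s:%s\n",
    attr(x, "condition"), nrow(x), attr(x, "total_umis"),
    x$chrom[1], format(attr(x, "bait_pos"), big.mark = ",")
  ))
  invisible(x)
}

# Fragment midpoints on the bp axis (0-based half-open fragments).
.frag_mid <- function(profile) (profile$start + profile$end) / 2

#' Restrict a profile to the reliable distance band
#'
#' UMI-4C quantification is reliable only for fragments between roughly
#' 0.5 kb and 1 Mb from the bait; fragments whose midpoint distance falls
#' outside \[min_bp, max_bp\] (inclusive at both ends) are removed.
#'
#' @param profile A \code{\link{contact_profile}}.
#' @param min_bp,max_bp Distance bounds in bp (defaults 500 and 1e6).
#' @return Filtered \code{contact_profile} (totals recomputed).
#' @export
distance_filter <- function(profile, min_bp = 500, max_bp = 1e6) {
  if (min_bp >= max_bp) .stopf("config error: min_bp must be < max_bp")
  d <- abs(.frag_mid(profile) - attr(profile, "bait_pos"))
  keep <- d >= min_bp & d <= max_bp
  contact_profile(profile[keep, c("chrom", "start", "end"), drop = FALSE],
                  profile$umi_count[keep],
                  bait_pos = attr(profile, "bait_pos"),
                  condition = attr(profile, "condition"))
}

# Centred moving average with truncated windows at the edges.
.moving_avg <- function(x, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Smoothed contact trend line
#'
#' Depth-normalises the counts (count / total UMIs of the profile) and
#' applies a centred moving average over \code{window_frags} fragments;
#' windows are truncated at the profile edges.
#'
#' @param profile A \code{\link{contact_profile}}.
#' @param window_frags Odd window width in fragments (1 = identity on the
#'   normalised counts).
#' @return Numeric vector of smoothed normalised contact frequencies, one
#'   per fragment.
#' @export
smooth_profile <- function(profile, window_frags = 5L) {
  if (window_frags < 1 || window_frags %% 2 == 0) {
    .stopf("config error: window_frags must be a positive odd integer")
  }
  total <- attr(profile, "total_umis")
  norm <- if (total > 0) profile$umi_count / total else rep(0, nrow(profile))
  .moving_avg(norm, as.integer(window_frags))
}

#' Multi-scale domainogram of differential mean contacts
#'
#' For each scale s and fragment i, the mean over the s-fragment window
#' centred at i of the depth-normalised counts of condition B minus the same
#' for condition A. At scale 1 the values equal the raw normalised
#' difference.
#'
#' @param profA,profB \code{\link{contact_profile}}s on identical fragment
#'   grids (apply \code{\link{distance_filter}} first).
#' @param scales Integer vector of odd window sizes in fragments.
#' @return Object of class \code{"domainogram"}: a scales x fragments
#'   matrix with attributes \code{scales}, \code{fragments},
#'   \code{conditions}.
#' @export
domainogram <- function(profA, profB, scales = c(1L, 3L, 5L, 11L, 21L)) {
  if (nrow(profA) != nrow(profB) ||
        !all(profA$start == profB$start & profA$end == profB$end &
               profA$chrom == profB$chrom)) {
    .stopf("profiles must share an identical fragment grid")
  }
  if (any(scales < 1) || any(scales %% 2 == 0)) {
    .stopf("config error: scales must be positive odd integers")
  }
  totA <- attr(profA, "total_umis"); totB <- attr(profB, "total_umis")
  nA <- if (totA > 0) profA$umi_count / totA else rep(0, nrow(profA))
  nB <- if (totB > 0) profB$umi_count / totB else rep(0, nrow(profB))
  mat <- t(vapply(as.integer(scales), function(s) {
    .moving_avg(nB, s) - .moving_avg(nA, s)
  }, numeric(nrow(profA))))
  rownames(mat) <- paste0("scale", scales)
  structure(mat,
            scales = as.integer(scales),
            fragments = profA[, c("chrom", "start", "end")],
            conditions = c(attr(profA, "condition"), attr(profB, "condition")),
            class = c("domainogram", class(mat)))
}

#' @export
print.domainogram <- function(x, ...) {
  cond <- attr(x, "conditions")
  cat(sprintf(
    "domainogram: %d scales x %d fragments (differential mean contacts, %s - %s)\n",
    nrow(x), ncol(x), cond[2], cond[1]
  ))
  invisible(x)
}

#' @method plot domainogram
#' @export
plot.domainogram <- function(x, ...) {
  graphics::image(
    x = seq_len(ncol(x)), y = seq_len(nrow(x)), z = t(unclass(x)),
    xlab = "fragment", ylab = "scale (fragments)",
    yaxt = "n", main = "differential mean contacts", ...
  )
  graphics::axis(2, at = seq_len(nrow(x)), labels = attr(x, "scales"))
  invisible(x)
}

#' @method plot contact_profile
#' @export
plot.contact_profile <- function(x, window_frags = 5L, ...) {
  graphics::plot(
    .frag_mid(x), smooth_profile(x, window_frags), type = "l",
    xlab = "position (bp)", ylab = "normalised contacts",
    main = sprintf("contact profile [%s]", attr(x, "condition")), ...
  )
  graphics::abline(v = attr(x, "bait_pos"), lty = 2)
  invisible(x)
}

#' Chi-square test for differential contacts in a target window
#'
#' Builds the 2x2 table \code{[[A_in, A_out], [B_in, B_out]]} of UMI counts
#' inside and outside the target fragment window and applies the Pearson
#' chi-square test with one degree of freedom (no continuity correction by
#' default). When several windows are tested in one call, adjusted p-values
#' are BH across windows; a single window reports adjusted = raw.
#'
#' @param profA,profB \code{\link{contact_profile}}s on identical grids.
#' @param target_window Integer vector of fragment indices (e.g.
#'   \code{10:14}) or a list of such windows.
#' @param correct Apply the Yates continuity correction (default
#'   \code{FALSE}).
#' @return Data frame with one row per window: \code{window}, \code{chi2},
#'   \code{p}, \code{p_adj}, and counts \code{A_in}, \code{A_out},
#'   \code{B_in}, \code{B_out}.
#' @export
contact_test <- function(profA, profB, target_window, correct = FALSE) {
  if (nrow(profA) == 0 || nrow(profB) == 0) {
    .stopf("profiles are empty after filtering")
  }
  if (nrow(profA) != nrow(profB)) {
    .stopf("profiles must share an identical fragment grid")
  }
  windows <- if (is.list(target_window)) target_window else list(target_window)
  n <- nrow(profA)
  rows <- lapply(windows, function(w) {
    w <- as.integer(w)
    if (any(w < 1) || any(w > n)) .stopf("target window outside fragment grid")
    a_in <- sum(profA$umi_count[w]); a_out <- sum(profA$umi_count[-w])
    b_in <- sum(profB$umi_count[w]); b_out <- sum(profB$umi_count[-w])
    tab <- matrix(c(a_in, a_out, b_in, b_out), nrow = 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      .stopf("degenerate 2x2 table: a margin is zero (window %d..%d)",
             min(w), max(w))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    data.frame(window = sprintf("%d-%d", min(w), max(w)),
               chi2 = unname(ct$statistic), p = .p_floor(unname(ct$p.value)),
               A_in = a_in, A_out = a_out, B_in = b_in, B_out = b_out,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res <- res[, c("window", "chi2", "p", "p_adj",
                 "A_in", "A_out", "B_in", "B_out")]
  rownames(res) <- NULL
  res
}
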