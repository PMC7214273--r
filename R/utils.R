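# Internal helpers shared across modules.

# Convert 0-based half-open intervals (BED convention) to GRanges (1-based
# closed). This, together with .pos_gr(), is the single place where the two
# coordinate dialects meet: a 1-based manifest position p falls in [start, end)
# iff start <= p - 1 < end, i.e. start + 1 <= p <= end in 1-based closed terms.
.gr0 <- function(chrom, start, end, ...) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    ...
  )
}

# Single 1-based bp positions (EPIC-manifest convention) as width-1 GRanges.
.pos_gr <- function(chrom, pos) {
  GenomicRanges::GRanges(seqnames = chrom, ranges = IRanges::IRanges(pos, pos))
}

# Evaluate expr with a private RNG stream, restoring the caller's stream.
.local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Percentage formatted to one decimal place, e.g. "56.2%".
.pct1 <- function(x) sprintf("%.1f%%", 100 * x)

# Smallest representable positive p-value; used so p stays in (0, 1] even for
# degenerate infinite test statistics.
.p_floor <- function(p) pmax(p, .Machine$double.xmin)

# All n! permutations of 1..n as an (n! x n) integer matrix, lexicographic in
# the first column. Only used for n <= 8 (40320 rows); cached per n since the
# linkage stages enumerate repeatedly.
.perm_cache <- new.env(parent = emptyenv())
.permutations <- function(n) {
  n <- as.integer(n)
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  res <- if (n == 1L) {
    matrix(1L, 1L, 1L)
  } else {
    sub <- .permutations(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i) {
      rest <- seq_len(n)[-i]
      cbind(rep.int(i, nrow(sub)), matrix(rest[sub], nrow(sub)))
    }))
  }
  .perm_cache[[key]] <- res
  res
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
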