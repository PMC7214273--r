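# Independent brute-force oracles used to cross-check the package's
# implementations. Kept deliberately naive and algorithmically distinct from
# the production code paths.

TP_H <- c(0L, 3L, 12L, 24L, 48L, 72L, 168L)

`%||%` <- function(a, b) if (is.null(a)) b else a

# All permutations of 1..n by insertion (distinct from the package's
# selection-based recursion).
perms_oracle <- function(n) {
  acc <- list(1L)
  for (k in 2:n) {
    acc <- unlist(lapply(acc, function(p) {
      lapply(seq_len(k), function(i) append(p, k, after = i - 1L))
    }), recursive = FALSE)
  }
  do.call(rbind, acc)
}

# Exact two-sided permutation p for the Pearson correlation, by looping cor()
# over every pairing.
perm_p_oracle <- function(x, y) {
  pm <- perms_oracle(length(x))
  r0 <- abs(cor(x, y))
  hits <- 0L
  for (i in seq_len(nrow(pm))) {
    if (abs(cor(x, y[pm[i, ]])) >= r0) hits <- hits + 1L
  }
  hits / nrow(pm)
}

# All-pairs interval containment: 1-based position p inside 0-based
# half-open [start, end) iff start <= p - 1 < end.
naive_overlap_oracle <- function(p_chrom, p_pos, iv) {
  lapply(seq_along(p_pos), function(i) {
    hit <- iv$chrom == p_chrom[i] &
      iv$start <= p_pos[i] - 1 & p_pos[i] - 1 < iv$end
    which(hit)
  })
}

# Hypergeometric upper tail by direct enumeration of binomial coefficients
# (exact for N <= 25, where choose() is integer-valued and representable).
hyper_oracle <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Pearson chi-square for a 2x2 table, closed form.
chi2_oracle <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  stat <- N * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# IUPAC sliding-window scan (both strands) returning 1-based match starts on
# the forward strand.
iupac_scan_oracle <- function(sequence, pattern) {
  iupac <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
             S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT",
             H = "ACT", V = "ACG", N = "ACGT")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  match_at <- function(seq_chars, pat_chars, i) {
    all(vapply(seq_along(pat_chars), function(j) {
      grepl(seq_chars[i + j - 1], iupac[[pat_chars[j]]], fixed = TRUE)
    }, logical(1)))
  }
  sc <- strsplit(sequence, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  rc <- rev(unname(comp[strsplit(sequence, "")[[1]]]))
  L <- length(sc); m <- length(pc)
  fwd <- Filter(function(i) match_at(sc, pc, i), seq_len(L - m + 1))
  rev_hits <- Filter(function(i) match_at(rc, pc, i), seq_len(L - m + 1))
  # a reverse-strand match starting at i (in revcomp coords) spans forward
  # positions [L - i - m + 2, L - i + 1]
  list(fwd_starts = unlist(fwd),
       rev_starts_forward_coords = sort(L - unlist(rev_hits) - m + 2))
}
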