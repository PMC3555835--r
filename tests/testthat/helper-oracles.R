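# Independent oracles used to check the package's algorithmic cores.
# These deliberately take different code paths from the implementation.

# Brute-force end-tolerant matching: enumerate every (5' trim, 3' trim)
# substring of the query as a candidate identical core, locate it in the
# reference by position-wise character comparison, and account terminal
# variant nucleotides directly from the alignment geometry. Returns the
# minimal total terminal variants against one reference, or Inf.
oracle_match_cost <- function(query, ref, tolerance = 4L) {
  qb <- strsplit(query, "")[[1]]
  rb <- strsplit(ref, "")[[1]]
  lq <- length(qb)
  lr <- length(rb)
  best <- Inf
  for (t5 in 0:tolerance) {
    for (t3 in 0:(tolerance - t5)) {
      clen <- lq - t5 - t3
      if (clen < 1L || clen < lq - tolerance) next
      core <- qb[(t5 + 1L):(lq - t3)]
      if (clen > lr) next
      for (p in 1:(lr - clen + 1L)) {
        if (!all(rb[p:(p + clen - 1L)] == core)) next
        n5 <- max(t5, p - 1L)
        n3 <- max(t3, lr - (p + clen - 1L))
        if (n5 + n3 <= tolerance) best <- min(best, n5 + n3)
      }
    }
  }
  best
}

# Exhaustive enumeration of nested secondary structures (no memoization):
# maximum number of base pairs with a minimum hairpin loop, Watson-Crick
# plus G.U. Exponential; only for short sequences / sparse pairing.
oracle_max_pairs <- function(seq, min_loop = 3L) {
  b <- strsplit(toupper(seq), "")[[1]]
  ok <- function(x, y) {
    (x == "A" && y == "T") || (x == "T" && y == "A") ||
      (x == "C" && y == "G") || (x == "G" && y == "C") ||
      (x == "G" && y == "T") || (x == "T" && y == "G")
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (ok(b[i], b[k])) {
        left <- if (k - 1L >= i + 1L) rec(i + 1L, k - 1L) else 0L
        right <- if (j >= k + 1L) rec(k + 1L, j) else 0L
        best <- max(best, 1L + left + right)
      }
    }
    best
  }
  rec(1L, length(b))
}

# Exhaustive hypergeometric tails: enumerate every size-n draw from a
# universe of N genes whose first K are the category.
oracle_hypergeom <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  list(p_over = mean(overlap >= k), p_under = mean(overlap <= k))
}

# Direct BH step-up evaluation from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  ps <- p[o]
  for (i in seq_len(m)) {
    q_sorted[i] <- min((m / i:m) * ps[i:m])
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# String-level reverse complement, independent of Biostrings.
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# A small, fast simulation configuration shared across tests.
test_config <- function(seed = 101L, depth = 700L, n_mirnas = 10L,
                        n_novel = 2L, n_decoys = 1L, ...) {
  depths <- stats::setNames(rep(depth, 7L),
                            default_library_specs()$library_id)
  simulation_config(seed = seed, n_mirnas = n_mirnas, n_novel = n_novel,
                    n_decoys = n_decoys, library_depths = depths, ...)
}

zero_noise_model <- list(p_shift5 = 0, p_shift3 = 0, p_internal_edit = 0,
                         max_shift = 2L)
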