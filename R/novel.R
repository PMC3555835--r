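#' Perfect-match genomic loci of a sequence
#'
#' Reports every exact occurrence of `seq` on either strand of the genome.
#' Minus-strand hits are found through the reverse complement and reported
#' in plus coordinates with `strand = "-"`. Coordinates are 0-based
#' half-open (the internal convention; user-facing tables are 1-based).
#'
#' @param seq a single tag sequence.
#' @param genome a [Biostrings::DNAStringSet] (one entry per chromosome).
#' @return data.frame with `chrom`, `start`, `end`, `strand`.
#' @export
map_perfect <- function(seq, genome) {
  stopifnot(length(seq) == 1L)
  seq <- canonical_dna(seq)
  out <- list()
  pat_fwd <- Biostrings::DNAString(seq)
  pat_rev <- Biostrings::reverseComplement(pat_fwd)
  for (chrom in names(genome)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pat_fwd else pat_rev
      m <- Biostrings::matchPattern(pat, genome[[chrom]])
      if (length(m) > 0L) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = Biostrings::start(m) - 1L,
          end = Biostrings::end(m), strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select novel miRNA candidate tags
#'
#' A tag is kept iff it maps to exactly one perfect locus in the genome,
#' its length is within `[min_len, max_len]`, the locus does not intersect
#' the annotation mask, and its copy number is strictly greater than
#' `cn_greater_than`. The filters commute; they are applied in one pass.
#'
#' @param tags unannotated tag data.frame (see [assign_tags()]).
#' @param genome a [Biostrings::DNAStringSet].
#' @param mask a [GenomicRanges::GRanges] of annotated features.
#' @param min_len,max_len inclusive length bounds (nt).
#' @param cn_greater_than copy-number threshold (kept iff CN > this).
#' @return data.frame of candidate tags with locus columns `chrom`,
#'   `start`, `end`, `strand` (0-based half-open).
#' @export
select_candidates <- function(tags, genome, mask, min_len = 19L,
                              max_len = 23L, cn_greater_than = 2L) {
  keep <- list()
  for (i in seq_len(nrow(tags))) {
    if (tags$length[i] < min_len || tags$length[i] > max_len) next
    if (tags$cn[i] <= cn_greater_than) next
    loci <- map_perfect(tags$sequence[i], genome)
    if (nrow(loci) != 1L) next
    if (length(mask) > 0L) {
      locus_gr <- GenomicRanges::GRanges(
        seqnames = loci$chrom,
        ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end))
      ov <- GenomicRanges::countOverlaps(locus_gr, mask,
                                         ignore.strand = TRUE)
      if (ov > 0L) next
    }
    keep[[length(keep) + 1L]] <- cbind(tags[i, , drop = FALSE], loci)
  }
  if (length(keep) == 0L) {
    out <- cbind(tags[0L, , drop = FALSE],
                 data.frame(chrom = character(), start = integer(),
                            end = integer(), strand = character()))
    return(out)
  }
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out
}

#' Cluster candidate tags by genomic position
#'
#' Single-linkage grouping of loci overlapping by at least 1 nt on the same
#' chromosome and strand. The cluster reference sequence is the member with
#' the highest CN (ties broken by lexicographic sequence order).
#'
#' @param candidates data.frame from [select_candidates()].
#' @return list of clusters, each a list with `cluster_id`, `members`
#'   (data.frame), `reference_sequence`, `cn`, `isomir_count`, `chrom`,
#'   `start`, `end`, `strand` (span and reference locus, 0-based half-open).
#' @export
cluster_by_locus <- function(candidates) {
  if (nrow(candidates) == 0L) return(list())
  ord <- order(candidates$chrom, candidates$strand, candidates$start,
               candidates$end)
  cand <- candidates[ord, , drop = FALSE]
  grp <- integer(nrow(cand))
  g <- 0L
  cur_end <- -Inf
  cur_key <- ""
  for (i in seq_len(nrow(cand))) {
    key <- paste(cand$chrom[i], cand$strand[i])
    if (key != cur_key || cand$start[i] >= cur_end) {
      g <- g + 1L
      cur_end <- cand$end[i]
      cur_key <- key
    } else {
      cur_end <- max(cur_end, cand$end[i])
    }
    grp[i] <- g
  }
  clusters <- vector("list", g)
  for (k in seq_len(g)) {
    members <- cand[grp == k, , drop = FALSE]
    members <- members[order(-members$cn, members$sequence), , drop = FALSE]
    rownames(members) <- NULL
    clusters[[k]] <- list(
      cluster_id = sprintf("Cl-%d", k),
      members = members,
      reference_sequence = members$sequence[1L],
      cn = sum(members$cn),
      isomir_count = nrow(members),
      chrom = members$chrom[1L],
      start = members$start[1L],     # reference locus
      end = members$end[1L],
      strand = members$strand[1L],
      span_start = min(members$start),
      span_end = max(members$end))
  }
  clusters
}

#' Extract the putative precursor of a candidate cluster
#'
#' Returns the strand-oriented genomic sequence covering the cluster's
#' reference locus plus `flank` nt on both sides; flanks are clipped at
#' chromosome ends (and the clipping logged). The mature span within the
#' precursor is recorded 1-based.
#'
#' @param cluster one cluster from [cluster_by_locus()].
#' @param genome a [Biostrings::DNAStringSet].
#' @param flank flank size in nt.
#' @return list with `sequence`, `mature_start`, `mature_end` (1-based,
#'   within the oriented precursor), `clipped5`, `clipped3` (nt lost to
#'   chromosome boundaries, on the oriented 5'/3' sides).
#' @export
extract_precursor <- function(cluster, genome, flank = 50L) {
  if (!cluster$chrom %in% names(genome)) {
    stop("locus on missing chromosome: ", cluster$chrom)
  }
  chrom_len <- length(genome[[cluster$chrom]])
  ws <- max(0L, cluster$start - flank)          # 0-based window
  we <- min(chrom_len, cluster$end + flank)
  left_clip <- flank - (cluster$start - ws)
  right_clip <- flank - (we - cluster$end)
  win <- as.character(Biostrings::subseq(genome[[cluster$chrom]],
                                         start = ws + 1L, end = we))
  L <- cluster$end - cluster$start
  if (cluster$strand == "+") {
    list(sequence = win,
         mature_start = cluster$start - ws + 1L,
         mature_end = cluster$start - ws + L,
         clipped5 = left_clip, clipped3 = right_clip)
  } else {
    list(sequence = revcomp(win),
         mature_start = we - cluster$end + 1L,
         mature_end = we - cluster$end + L,
         clipped5 = right_clip, clipped3 = left_clip)
  }
}

pairable_matrix <- function(allow_gu = TRUE) {
  m <- matrix(FALSE, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
  m["A", "T"] <- m["T", "A"] <- TRUE
  m["C", "G"] <- m["G", "C"] <- TRUE
  if (allow_gu) m["G", "T"] <- m["T", "G"] <- TRUE   # G.U wobble
  m
}

#' Fold a precursor by base-pair maximization and judge the hairpin
#'
#' Computes a maximum-base-pair nested secondary structure of the precursor
#' by dynamic programming (minimum hairpin loop 3 nt; Watson-Crick plus,
#' optionally, G.U pairs), then evaluates hairpin criteria on the mature
#' span: at least `min_arm_pairs` pairs formed between the mature span and
#' the opposite arm (the side carrying the majority of its pairing), with
#' at most `branch_tolerance` stray pairs off that arm (pairs to the
#' minority side or wholly inside the mature span). Base-pair maximization
#' is used deliberately instead of thermodynamic free-energy minimization:
#' the pass/fail criteria, not energies, drive the decision, and the DP is
#' auditable against exhaustive structure enumeration. Because maximization
#' decorates structures with incidental pairs a strict zero-stray rule
#' would reject genuine stems, hence the small tolerance.
#'
#' @param precursor precursor sequence.
#' @param mature_start,mature_end 1-based mature span within the precursor.
#' @param min_arm_pairs minimum pairs between the mature span and the
#'   opposite arm for a pass (the canonical "~16 bp" guideline).
#' @param min_loop minimum hairpin loop length in nt.
#' @param branch_tolerance maximum stray (off-arm or intra-mature) pairs
#'   compatible with an unbranched verdict.
#' @param allow_gu allow G.U wobble pairs. Note wobbles are not closed
#'   under complementation, so only Watson-Crick-only folds have a pair
#'   count exactly invariant under reverse complement.
#' @return object of class `hairpin_fold`: list with `structure`
#'   (dot-bracket), `n_pairs`, `pairs` (2-column matrix of paired
#'   positions), `mature_arm_pairs`, `unbranched`, `pass`, `mature_span`.
#' @export
fold_hairpin <- function(precursor, mature_start, mature_end,
                         min_arm_pairs = 16L, min_loop = 3L,
                         branch_tolerance = 2L, allow_gu = TRUE) {
  precursor <- canonical_dna(precursor)
  n <- nchar(precursor)
  L <- mature_end - mature_start + 1L
  if (n < L) stop("precursor shorter than the mature span")
  if (mature_start < 1L || mature_end > n) {
    stop("mature span outside the precursor")
  }
  b <- strsplit(precursor, "")[[1L]]
  pm <- pairable_matrix(allow_gu)
  can <- matrix(FALSE, n, n)
  ok <- b %in% DNA_BASES
  can[ok, ok] <- pm[b[ok], b[ok]]

  dp <- matrix(0L, n, n)
  if (n > min_loop + 1L) {
    for (span in (min_loop + 1L):(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- max(dp[i + 1L, j], dp[i, j - 1L])
        if (can[i, j]) best <- max(best, dp[i + 1L, j - 1L] + 1L)
        if (span >= 2L) {
          k <- i:(j - 1L)
          best <- max(best, max(dp[i, k] + dp[cbind(k + 1L, j)]))
        }
        dp[i, j] <- best
      }
    }
  }

  pairs <- matrix(integer(0), ncol = 2L)
  if (n >= 2L && dp[1L, n] > 0L) {
    stack <- list(c(1L, n))
    acc <- vector("list", n)
    n_acc <- 0L
    while (length(stack) > 0L) {
      ij <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- ij[1L]; j <- ij[2L]
      if (j - i <= min_loop || dp[i, j] == 0L) next
      if (can[i, j] && dp[i, j] == dp[i + 1L, j - 1L] + 1L) {
        n_acc <- n_acc + 1L
        acc[[n_acc]] <- c(i, j)
        stack[[length(stack) + 1L]] <- c(i + 1L, j - 1L)
      } else if (dp[i, j] == dp[i + 1L, j]) {
        stack[[length(stack) + 1L]] <- c(i + 1L, j)
      } else if (dp[i, j] == dp[i, j - 1L]) {
        stack[[length(stack) + 1L]] <- c(i, j - 1L)
      } else {
        for (k in i:(j - 1L)) {
          if (dp[i, k] + dp[k + 1L, j] == dp[i, j]) {
            stack[[length(stack) + 1L]] <- c(i, k)
            stack[[length(stack) + 1L]] <- c(k + 1L, j)
            break
          }
        }
      }
    }
    if (n_acc > 0L) {
      pairs <- do.call(rbind, acc[seq_len(n_acc)])
    }
  }

  db <- rep(".", n)
  if (nrow(pairs) > 0L) {
    db[pairs[, 1L]] <- "("
    db[pairs[, 2L]] <- ")"
  }
  span <- mature_start:mature_end
  in_span <- matrix(c(pairs[, 1L] %in% span, pairs[, 2L] %in% span),
                    ncol = 2L)
  arm_pair <- xor(in_span[, 1L], in_span[, 2L])
  internal <- in_span[, 1L] & in_span[, 2L]
  partners <- ifelse(in_span[arm_pair, 1L], pairs[arm_pair, 2L],
                     pairs[arm_pair, 1L])
  left <- sum(partners < mature_start)
  right <- sum(partners > mature_end)
  mature_arm_pairs <- max(left, right)
  stray <- min(left, right) + sum(internal)
  unbranched <- stray <= branch_tolerance
  structure(list(
    structure = paste(db, collapse = ""),
    n_pairs = nrow(pairs),
    pairs = pairs,
    mature_arm_pairs = mature_arm_pairs,
    unbranched = unbranched,
    pass = mature_arm_pairs >= min_arm_pairs && unbranched,
    mature_span = c(mature_start, mature_end)
  ), class = "hairpin_fold")
}

#' @export
print.hairpin_fold <- function(x, ...) {
  cat("Hairpin fold:", x$n_pairs, "base pairs,",
      x$mature_arm_pairs, "mature-arm pairs;",
      if (x$pass) "PASS" else "fail", "\n")
  cat(x$structure, "\n")
  invisible(x)
}

#' Screen unannotated tags for novel miRNA candidates
#'
#' Runs the full discovery cascade: unique perfect mapping with length,
#' mask and CN filters, positional clustering, precursor extraction with
#' `flank`-nt flanks, and hairpin folding with the Ambros-style criteria.
#'
#' @param tags unannotated tag data.frame.
#' @param genome a [Biostrings::DNAStringSet].
#' @param mask a [GenomicRanges::GRanges] annotation mask.
#' @param flank precursor flank in nt.
#' @inheritParams select_candidates
#' @inheritParams fold_hairpin
#' @return list with `clusters` (each cluster augmented with `precursor`
#'   and `fold`) and `table` (report data.frame, loci 1-based inclusive).
#' @export
discover_novel <- function(tags, genome, mask, flank = 50L, min_len = 19L,
                           max_len = 23L, cn_greater_than = 2L,
                           min_arm_pairs = 16L) {
  cand <- select_candidates(tags, genome, mask, min_len = min_len,
                            max_len = max_len,
                            cn_greater_than = cn_greater_than)
  clusters <- cluster_by_locus(cand)
  for (k in seq_along(clusters)) {
    prec <- extract_precursor(clusters[[k]], genome, flank = flank)
    fold <- fold_hairpin(prec$sequence, prec$mature_start, prec$mature_end,
                         min_arm_pairs = min_arm_pairs)
    clusters[[k]]$precursor <- prec
    clusters[[k]]$fold <- fold
    clusters[[k]]$validated <- fold$pass
  }
  table <- if (length(clusters) == 0L) {
    data.frame(cluster_id = character(), locus = character(),
               cn = integer(), isomirs = integer(),
               reference_sequence = character(), fold_pass = logical(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      cluster_id = vapply(clusters, `[[`, character(1), "cluster_id"),
      locus = vapply(clusters, function(cl)
        sprintf("%s:%d:%d:%s", cl$chrom, cl$start + 1L, cl$end, cl$strand),
        character(1)),
      cn = vapply(clusters, `[[`, numeric(1), "cn"),
      isomirs = vapply(clusters, `[[`, numeric(1), "isomir_count"),
      reference_sequence = vapply(clusters, `[[`, character(1),
                                  "reference_sequence"),
      fold_pass = vapply(clusters, `[[`, logical(1), "validated"),
      stringsAsFactors = FALSE)
  }
  list(clusters = clusters, table = table)
}
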