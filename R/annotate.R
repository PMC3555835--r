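# Normalize any accepted mature-reference representation to a data.frame
# with mirna_id / sequence / species columns.
as_mature_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    reference <- data.frame(mirna_id = names(reference),
                            sequence = as.character(reference),
                            stringsAsFactors = FALSE)
  } else if (is.character(reference)) {
    ids <- names(reference)
    if (is.null(ids)) ids <- sprintf("ref%d", seq_along(reference))
    reference <- data.frame(mirna_id = ids, sequence = unname(reference),
                            stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(reference),
            all(c("mirna_id", "sequence") %in% names(reference)))
  if (anyDuplicated(reference$mirna_id)) stop("duplicated reference ids")
  reference$sequence <- canonical_dna(reference$sequence)
  reference$species <- tolower(sub("-.*$", "", reference$mirna_id))
  reference
}

#' End-tolerant exact-core match of a tag against mature references
#'
#' Finds, over all ungapped offsets of the query against each reference, the
#' alignment minimizing the total number of terminal variant nucleotides:
#' query extensions beyond the reference, query truncations relative to the
#' reference, and mismatching terminal positions, summed over both ends. The
#' overlapping core must be 100% identical and at least
#' `query length - tolerance` nt long; a match requires the total terminal
#' variants not to exceed `tolerance` (default 4, summed over both ends,
#' not 4 per end).
#'
#' @param query a single tag sequence (15-29 nt).
#' @param reference mature reference: data.frame (`mirna_id`, `sequence`),
#'   named character vector, or [Biostrings::DNAStringSet].
#' @param tolerance maximum total terminal variant nucleotides.
#' @return `NULL` if no reference matches, else a list with `mirna_index`,
#'   `mirna_id`, `offset` (query 5' start relative to reference 5' start),
#'   `n5`, `n3` (terminal variant nucleotides per end), `core_len` and
#'   `cost` (= n5 + n3) for the best match under the assignment priority
#'   (lower cost, then "ssc" species, then longer core, then lexicographic
#'   id).
#' @export
match_end_tolerant <- function(query, reference, tolerance = 4L) {
  hits <- match_candidates(query, reference, tolerance)
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  as.list(hits[1L, ])
}

# All per-reference best matches for a query, ordered by assignment
# priority. Shared by match_end_tolerant() and assign_tags().
match_candidates <- function(query, reference, tolerance = 4L) {
  if (length(query) != 1L || is.na(query) || nchar(query) == 0L) {
    stop("query must be a single non-empty sequence")
  }
  query <- canonical_dna(query)
  ref <- as_mature_reference(reference)
  if (nrow(ref) == 0L) return(NULL)
  lq <- nchar(query)

  # Subject = all references joined with a non-base separator so one
  # fixed-string search per trimmed core covers every reference.
  seqs <- ref$sequence
  lens <- nchar(seqs)
  starts <- cumsum(c(1L, lens[-length(lens)] + 1L))  # subject pos of ref[i][1]
  subject <- paste(seqs, collapse = "#")

  out <- vector("list", 32L)
  n_out <- 0L
  for (t5 in 0:tolerance) {
    for (t3 in 0:(tolerance - t5)) {
      if (lq - t5 - t3 < 1L) next
      core <- substr(query, t5 + 1L, lq - t3)
      pos <- gregexpr(core, subject, fixed = TRUE)[[1L]]
      if (pos[1L] < 0L) next
      core_len <- lq - t5 - t3
      idx <- findInterval(pos, starts)
      p <- pos - starts[idx] + 1L          # 1-based core start within ref
      ref5 <- p - 1L
      ref3 <- lens[idx] - (p + core_len - 1L)
      n5 <- pmax(t5, ref5)
      n3 <- pmax(t3, ref3)
      keep <- (n5 + n3) <= tolerance
      if (!any(keep)) next
      n_out <- n_out + 1L
      out[[n_out]] <- data.frame(
        mirna_index = idx[keep], n5 = n5[keep], n3 = n3[keep],
        core_len = core_len, offset = ref5[keep] - t5,
        cost = (n5 + n3)[keep])
    }
  }
  if (n_out == 0L) return(NULL)
  hits <- do.call(rbind, out[seq_len(n_out)])
  # best alignment per reference: min cost, then max core
  hits <- hits[order(hits$mirna_index, hits$cost, -hits$core_len,
                     hits$n5, hits$offset), ]
  hits <- hits[!duplicated(hits$mirna_index), , drop = FALSE]
  hits$mirna_id <- ref$mirna_id[hits$mirna_index]
  hits$species <- ref$species[hits$mirna_index]
  # assignment priority across references
  hits <- hits[order(hits$cost, hits$species != "ssc", -hits$core_len,
                     hits$mirna_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("mirna_index", "mirna_id", "offset", "n5", "n3", "core_len",
           "cost")]
}

#' Assign unique tags to miRNA clusters
#'
#' Each tag is matched end-tolerantly against the full mature reference and
#' assigned to at most one miRNA under the priority: lower total terminal
#' variants, species prefix "ssc" first, longer identical core, then
#' lexicographic id. Unassigned tags are returned for novel discovery.
#'
#' @param tags filtered tag data.frame (see [filter_tags()]).
#' @param reference mature reference (see [match_end_tolerant()]).
#' @param tolerance maximum total terminal variant nucleotides.
#' @return list with `clusters` (named list of miRNA clusters, each a list
#'   with `mirna_id`, `reference_sequence`, `members` data.frame, `cn`,
#'   `per_library`, `isomir_count`, `predominant`,
#'   `diverges_from_reference`) and `unannotated` (tag data.frame).
#' @export
assign_tags <- function(tags, reference, tolerance = 4L) {
  ref <- as_mature_reference(reference)
  lib_cols <- setdiff(names(tags), c("sequence", "length", "cn"))
  n <- nrow(tags)
  assigned_id <- rep(NA_character_, n)
  n5 <- n3 <- rep(NA_integer_, n)
  if (nrow(ref) > 0L) {
    for (i in seq_len(n)) {
      hit <- match_candidates(tags$sequence[i], ref, tolerance)
      if (!is.null(hit)) {
        assigned_id[i] <- hit$mirna_id[1L]
        n5[i] <- hit$n5[1L]
        n3[i] <- hit$n3[1L]
      }
    }
  }
  unannotated <- tags[is.na(assigned_id), , drop = FALSE]
  rownames(unannotated) <- NULL

  clusters <- list()
  for (id in unique(assigned_id[!is.na(assigned_id)])) {
    sel <- which(assigned_id == id)
    members <- tags[sel, , drop = FALSE]
    members$n5 <- n5[sel]
    members$n3 <- n3[sel]
    members <- members[order(-members$cn, members$sequence), , drop = FALSE]
    rownames(members) <- NULL
    per_library <- colSums(members[, lib_cols, drop = FALSE])
    ref_seq <- ref$sequence[ref$mirna_id == id]
    clusters[[id]] <- list(
      mirna_id = id,
      reference_sequence = ref_seq,
      members = members,
      cn = sum(members$cn),
      per_library = per_library,
      isomir_count = nrow(members),
      predominant = members$sequence[1L],
      diverges_from_reference = members$sequence[1L] != ref_seq)
  }
  list(clusters = clusters[order(names(clusters))],
       unannotated = unannotated)
}

#' Build the miRNA expression profile table
#'
#' Clusters with copy number below `min_cluster_cn` are excluded; remaining
#' rows report cluster CN, the percentage share of total reads, the isomiR
#' count, per-library counts, the predominant isomiR and whether it diverges
#' from the reference database sequence.
#'
#' @param clusters cluster list from [assign_tags()].
#' @param min_cluster_cn minimum cluster CN to be retained.
#' @param grand_total denominator for the percentage share (total
#'   length-filtered reads); defaults to the summed per-library counts of
#'   the retained clusters.
#' @return data.frame ordered by decreasing CN.
#' @export
build_profile <- function(clusters, min_cluster_cn = 3L, grand_total = NULL) {
  keep <- Filter(function(cl) cl$cn >= min_cluster_cn, clusters)
  if (length(keep) == 0L) {
    return(data.frame(mirna_id = character(), cn = integer(),
                      share_pct = numeric(), isomir_count = integer(),
                      predominant = character(),
                      diverges_from_reference = logical(),
                      stringsAsFactors = FALSE))
  }
  lib_names <- names(keep[[1L]]$per_library)
  per_lib <- t(vapply(keep, function(cl) cl$per_library,
                      numeric(length(lib_names))))
  if (is.null(grand_total)) grand_total <- sum(per_lib)
  out <- data.frame(
    mirna_id = vapply(keep, `[[`, character(1), "mirna_id"),
    cn = vapply(keep, `[[`, numeric(1), "cn"),
    share_pct = round(vapply(keep, `[[`, numeric(1), "cn") /
                        grand_total * 100, 2L),
    isomir_count = vapply(keep, `[[`, numeric(1), "isomir_count"),
    per_lib,
    predominant = vapply(keep, `[[`, character(1), "predominant"),
    diverges_from_reference = vapply(keep, `[[`, logical(1),
                                     "diverges_from_reference"),
    check.names = FALSE, stringsAsFactors = FALSE)
  out <- out[order(-out$cn, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-group predominant isomiR of a cluster
#'
#' For each group, the member sequence with the maximal summed normalized
#' count (counts per thousand) over that group's libraries. Ties are broken
#' by lexicographic sequence order; a group with zero counts across all
#' members yields `NA`.
#'
#' @param cluster one cluster from [assign_tags()].
#' @param groups named character vector mapping library id to group label.
#' @param library_totals named numeric vector of per-library totals used
#'   for normalization.
#' @return named character vector, one predominant sequence per group.
#' @export
per_group_predominance <- function(cluster, groups, library_totals) {
  libs <- names(groups)
  counts <- as.matrix(cluster$members[, libs, drop = FALSE])
  cpt <- sweep(counts, 2L, library_totals[libs], "/") * 1000
  out <- character(0)
  for (g in unique(groups)) {
    score <- rowSums(cpt[, libs[groups == g], drop = FALSE])
    if (all(score == 0)) {
      out[g] <- NA_character_
      next
    }
    best <- which(score == max(score))
    out[g] <- sort(cluster$members$sequence[best])[1L]
  }
  out
}
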