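#' Demultiplex pooled reads and trim MIDs and 3' adapters
#'
#' A read is assigned to the unique library whose 5-nt MID is an exact
#' prefix; the MID is removed and the insert is the region before the first
#' exact occurrence of that library's 3' adapter (the full remainder if the
#' adapter is absent). Unassignable or empty reads are never silently
#' dropped: they are returned in a discard log with a reason
#' (`no_mid`, `empty_insert`).
#'
#' @param reads character vector (or [Biostrings::DNAStringSet]) of raw
#'   reads, 5'->3'.
#' @param library_specs data.frame with `library_id`, `mid`, `adapter3`
#'   (see [default_library_specs()]).
#' @return list with `assigned` (named list, one character vector of inserts
#'   per library) and `discards` (data.frame `read`, `reason`).
#' @export
demultiplex_and_trim <- function(reads, library_specs) {
  validate_library_specs(library_specs)
  if (is.null(library_specs$mid) || is.null(library_specs$adapter3)) {
    stop("library_specs must provide mid and adapter3 for demultiplexing")
  }
  reads <- canonical_dna(as.character(reads))
  mids <- library_specs$mid
  prefix <- substr(reads, 1L, 5L)
  lib_idx <- match(prefix, mids)

  assigned <- stats::setNames(vector("list", nrow(library_specs)),
                              library_specs$library_id)
  discard_read <- character(0)
  discard_reason <- character(0)

  no_mid <- is.na(lib_idx)
  if (any(no_mid)) {
    discard_read <- reads[no_mid]
    discard_reason <- rep("no_mid", sum(no_mid))
  }
  for (j in seq_len(nrow(library_specs))) {
    sel <- which(!no_mid & lib_idx == j)
    rest <- substr(reads[sel], 6L, nchar(reads[sel]))
    apos <- as.integer(regexpr(library_specs$adapter3[j], rest,
                               fixed = TRUE))
    ins <- ifelse(apos > 0L, substr(rest, 1L, apos - 1L), rest)
    empty <- ins == ""
    if (any(empty)) {
      discard_read <- c(discard_read, reads[sel][empty])
      discard_reason <- c(discard_reason, rep("empty_insert", sum(empty)))
    }
    assigned[[j]] <- ins[!empty]
  }
  list(assigned = assigned,
       discards = data.frame(read = discard_read, reason = discard_reason,
                             stringsAsFactors = FALSE))
}

#' Collapse per-library inserts to unique tags with counts
#'
#' Applies U->T canonicalization, drops inserts with non-ACGT characters
#' (logged), and collapses identical sequences across all libraries into one
#' tag with per-library counts and total copy number (CN).
#'
#' @param assigned named list of character vectors of inserts, one per
#'   library (as returned by [demultiplex_and_trim()]).
#' @return list with `tags` (data.frame: `sequence`, `length`, one count
#'   column per library, `cn`) and `discards` (data.frame `read`, `reason`).
#' @export
collapse_reads <- function(assigned) {
  libs <- names(assigned)
  if (is.null(libs)) stop("assigned inserts must be named by library")
  clean <- lapply(assigned, function(x) canonical_dna(x))
  bad <- lapply(clean, function(x) grepl("[^ACGT]", x))
  bad_reads <- unlist(lapply(seq_along(clean),
                             function(j) clean[[j]][bad[[j]]]),
                      use.names = FALSE)
  discards <- data.frame(read = as.character(bad_reads),
                         reason = rep("non_acgt", length(bad_reads)),
                         stringsAsFactors = FALSE)
  clean <- lapply(seq_along(clean), function(j) clean[[j]][!bad[[j]]])

  all_seqs <- sort(unique(unlist(clean, use.names = FALSE)))
  counts <- vapply(clean, function(x) {
    as.integer(table(factor(x, levels = all_seqs)))
  }, integer(length(all_seqs)))
  if (length(all_seqs) == 1L) counts <- matrix(counts, nrow = 1L)
  if (length(all_seqs) == 0L) {
    counts <- matrix(integer(0), nrow = 0L, ncol = length(libs))
  }
  colnames(counts) <- libs
  tags <- data.frame(sequence = all_seqs, length = nchar(all_seqs),
                     counts, cn = as.integer(rowSums(counts)),
                     check.names = FALSE, stringsAsFactors = FALSE)
  rownames(tags) <- NULL
  list(tags = tags, discards = discards)
}

#' Length and copy-number filter on unique tags
#'
#' Keeps a tag iff `min_len <= length <= max_len` (inclusive) and
#' `CN >= min_cn`. Removal reasons are logged per tag.
#'
#' @param tags tag data.frame from [collapse_reads()].
#' @param min_len,max_len inclusive length bounds in nt.
#' @param min_cn minimum total copy number.
#' @return list with `tags` (kept rows) and `removed` (data.frame
#'   `sequence`, `reason`).
#' @export
filter_tags <- function(tags, min_len = 15L, max_len = 29L, min_cn = 3L) {
  if (min_len > max_len) stop("min_len must not exceed max_len")
  too_short <- tags$length < min_len
  too_long <- tags$length > max_len
  low_cn <- tags$cn < min_cn
  reason <- ifelse(too_short | too_long, "length",
                   ifelse(low_cn, "count", NA_character_))
  removed <- data.frame(sequence = tags$sequence[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  kept <- tags[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  list(tags = kept, removed = removed)
}

#' Run demultiplexing, collapsing and filtering in one call
#'
#' @inheritParams demultiplex_and_trim
#' @inheritParams filter_tags
#' @return list with `tags` (filtered tag table), `discards` (read-level
#'   discard log), `removed` (tag-level removal log) and `library_totals`
#'   (named vector of per-library totals of the kept, length-filtered
#'   reads -- the normalization denominators of the expression stage).
#' @export
preprocess_reads <- function(reads, library_specs, min_len = 15L,
                             max_len = 29L, min_cn = 3L) {
  dm <- demultiplex_and_trim(reads, library_specs)
  cl <- collapse_reads(dm$assigned)
  fl <- filter_tags(cl$tags, min_len = min_len, max_len = max_len,
                    min_cn = min_cn)
  lib_cols <- library_specs$library_id
  # Library totals are the per-library counts of all length-filtered reads
  # (before the CN filter): the library-size denominators used downstream.
  in_len <- cl$tags$length >= min_len & cl$tags$length <= max_len
  totals <- if (any(in_len)) {
    colSums(cl$tags[in_len, lib_cols, drop = FALSE])
  } else {
    stats::setNames(rep(0L, length(lib_cols)), lib_cols)
  }
  list(tags = fl$tags,
       discards = rbind(dm$discards, cl$discards),
       removed = fl$removed,
       library_totals = totals)
}
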