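DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of plain character sequences
#'
#' Thin wrapper around [Biostrings::reverseComplement()] accepting and
#' returning plain character vectors, used throughout for strand handling.
#'
#' @param x character vector of DNA sequences (ACGT).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Canonical sequence form used everywhere internally: uppercase, U -> T.
canonical_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Derive stage-specific seeds from one global seed by fixed offsets, kept
# below 2^31 so they remain valid R integers.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647L)
}

#' Read a library specification table
#'
#' The table must carry columns `library_id`, `group`, `mid`, `adapter3`
#' (plus optional `breed`, `total_counts`). MIDs must be distinct.
#'
#' @param path path to a tab-separated file.
#' @return data.frame of library specifications.
#' @export
read_library_table <- function(path) {
  specs <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("library_id", "group")
  missing <- setdiff(required, names(specs))
  if (length(missing) > 0) {
    stop("library table lacks columns: ", paste(missing, collapse = ", "))
  }
  specs
}

validate_library_specs <- function(specs) {
  stopifnot(is.data.frame(specs))
  if (anyDuplicated(specs$library_id)) {
    stop("duplicated library ids")
  }
  if (!is.null(specs$mid)) {
    if (anyDuplicated(specs$mid)) stop("two libraries share a MID")
    if (any(nchar(specs$mid) != 5L)) stop("MIDs must be 5 nt")
  }
  if (any(is.na(specs$group) | specs$group == "")) {
    stop("every library needs a group assignment")
  }
  invisible(specs)
}
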