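#' Run the full small-RNA analysis pipeline on a simulation
#'
#' Orchestrates simulate -> preprocess -> annotate -> discover -> express
#' and collects report tables: a per-library sequencing summary, the
#' most-abundant miRNA profile (default cutoff CN > 350), the novel
#' candidate report and the between-group fold-change table.
#'
#' @param config an `srna_config` (see [simulation_config()]); used to
#'   simulate reads when `sim` is not supplied.
#' @param sim optionally, an existing `srna_simulation` to analyse.
#' @param tolerance annotation end tolerance in nt.
#' @param min_len,max_len tag length filter bounds.
#' @param min_cn tag copy-number filter.
#' @param min_cluster_cn miRNA-level copy-number filter.
#' @param fc_threshold differential-expression fold-change threshold.
#' @param flank precursor flank for novel discovery.
#' @param abundant_cn_cutoff CN cutoff of the most-abundant table.
#' @return object of class `srna_run`: list with `tags`, `clusters`,
#'   `profile`, `unannotated`, `novel`, `comparisons`, `library_summary`,
#'   `abundant`, `library_totals`, `filter_log` and the inputs used.
#' @export
run_pipeline <- function(config = simulation_config(), sim = NULL,
                         tolerance = 4L, min_len = 15L, max_len = 29L,
                         min_cn = 3L, min_cluster_cn = 3L,
                         fc_threshold = 1.5, flank = 50L,
                         abundant_cn_cutoff = 350L) {
  if (is.null(sim)) sim <- simulate_srna_experiment(config)
  specs <- sim$config$library_specs
  groups <- stats::setNames(specs$group, specs$library_id)

  pre <- preprocess_reads(sim$reads, specs, min_len = min_len,
                          max_len = max_len, min_cn = min_cn)
  ann <- assign_tags(pre$tags, sim$reference$mature, tolerance = tolerance)
  grand_total <- sum(pre$library_totals)
  profile <- build_profile(ann$clusters, min_cluster_cn = min_cluster_cn,
                           grand_total = grand_total)
  novel <- discover_novel(ann$unannotated, sim$reference$genome,
                          sim$reference$mask, flank = flank)
  comparisons <- if (nrow(profile) > 0L) {
    counts <- as.matrix(profile[, specs$library_id, drop = FALSE])
    rownames(counts) <- profile$mirna_id
    compare_groups(counts, pre$library_totals, groups,
                   threshold = fc_threshold)
  } else {
    data.frame()
  }

  lib_cols <- specs$library_id
  annotated_seqs <- do.call(rbind, lapply(ann$clusters, `[[`, "members"))
  species_of <- function(members) {
    # split annotated counts by species prefix of the assigned reference
    ssc <- vapply(ann$clusters, function(cl)
      if (startsWith(tolower(cl$mirna_id), "ssc")) cl$per_library
      else cl$per_library * 0, numeric(length(lib_cols)))
    other <- vapply(ann$clusters, function(cl)
      if (!startsWith(tolower(cl$mirna_id), "ssc")) cl$per_library
      else cl$per_library * 0, numeric(length(lib_cols)))
    list(ssc = if (length(ann$clusters)) rowSums(matrix(ssc,
           nrow = length(lib_cols))) else rep(0, length(lib_cols)),
         other = if (length(ann$clusters)) rowSums(matrix(other,
           nrow = length(lib_cols))) else rep(0, length(lib_cols)))
  }
  sp <- species_of()
  unann_counts <- if (nrow(ann$unannotated) > 0L) {
    colSums(ann$unannotated[, lib_cols, drop = FALSE])
  } else {
    rep(0, length(lib_cols))
  }
  unique_seqs <- vapply(lib_cols, function(l)
    sum(pre$tags[[l]] > 0), numeric(1))
  library_summary <- data.frame(
    library_id = lib_cols, group = specs$group,
    total_counts = as.numeric(pre$library_totals[lib_cols]),
    unique_sequences = as.numeric(unique_seqs),
    annotated_ssc = as.numeric(sp$ssc),
    annotated_other = as.numeric(sp$other),
    unannotated = as.numeric(unann_counts),
    stringsAsFactors = FALSE)

  abundant <- profile[profile$cn > abundant_cn_cutoff, , drop = FALSE]
  filter_log <- list(read_discards = table(pre$discards$reason),
                     tag_removals = table(pre$removed$reason))

  structure(list(
    tags = pre$tags, clusters = ann$clusters, profile = profile,
    unannotated = ann$unannotated, novel = novel,
    comparisons = comparisons, library_summary = library_summary,
    abundant = abundant, library_totals = pre$library_totals,
    filter_log = filter_log, sim = sim, groups = groups
  ), class = "srna_run")
}

#' @export
print.srna_run <- function(x, ...) {
  cat("Small-RNA pipeline run\n")
  cat(sprintf("  libraries: %d (%s reads kept)\n",
              nrow(x$library_summary),
              format(sum(x$library_totals), big.mark = ",")))
  cat(sprintf("  unique tags kept: %d\n", nrow(x$tags)))
  cat(sprintf("  miRNA profile: %d miRNAs (cluster CN filter applied)\n",
              nrow(x$profile)))
  cat(sprintf("  unannotated tags: %d\n", nrow(x$unannotated)))
  cat(sprintf("  novel candidate clusters: %d (%d hairpin-validated)\n",
              nrow(x$novel$table), sum(x$novel$table$fold_pass)))
  if (nrow(x$comparisons) > 0L) {
    de_cols <- grep("^de_", names(x$comparisons), value = TRUE)
    de_any <- Reduce(`|`, lapply(de_cols, function(cl) x$comparisons[[cl]]))
    cat(sprintf("  differentially expressed in >=1 comparison: %d\n",
                sum(de_any)))
  }
  invisible(x)
}

#' @export
#' @method summary srna_run
summary.srna_run <- function(object, ...) {
  print(object)
  cat("\nPer-library summary:\n")
  print(object$library_summary, row.names = FALSE)
  invisible(object)
}

#' Fold-change table from pre-counted matrices
#'
#' Tables-only entry point: computes the between-group fold-change and DE
#' table directly from a count matrix and library totals, without raw
#' reads. This is the path used with the packaged kidney count fixture.
#'
#' @inheritParams compare_groups
#' @return see [compare_groups()].
#' @export
hts_fold_change_table <- function(counts, library_totals, groups,
                                  threshold = 1.5) {
  compare_groups(counts, library_totals, groups, threshold = threshold)
}

#' Packaged kidney miRNA count fixture
#'
#' Per-library sequencing totals and per-breed counts of the most abundant
#' miRNAs of a seven-library porcine kidney small-RNA run (breed groups
#' EU = Iberian + Wild Boar, EA = Landrace + Large White + Pietrain,
#' AS = Meishan + Vietnamese), as shipped in `inst/extdata`.
#'
#' @return list with `libraries` (data.frame), `counts` (miRNA x library
#'   matrix), `isomirs` (named vector), `totals` (named per-library
#'   totals), `groups` (named group map) and `grand_total`.
#' @export
kidney_fixture <- function() {
  lib_path <- system.file("extdata", "kidney_libraries.tsv",
                          package = "isomiRpipe", mustWork = TRUE)
  cnt_path <- system.file("extdata", "kidney_abundant_counts.tsv",
                          package = "isomiRpipe", mustWork = TRUE)
  libraries <- utils::read.delim(lib_path, stringsAsFactors = FALSE)
  counts_df <- utils::read.delim(cnt_path, check.names = FALSE,
                                 stringsAsFactors = FALSE)
  counts <- as.matrix(counts_df[, libraries$library_id])
  rownames(counts) <- counts_df$mirna_id
  list(libraries = libraries,
       counts = counts,
       isomirs = stats::setNames(counts_df$isomirs, counts_df$mirna_id),
       totals = stats::setNames(libraries$total_counts,
                                libraries$library_id),
       groups = stats::setNames(libraries$group, libraries$library_id),
       grand_total = sum(libraries$total_counts))
}
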