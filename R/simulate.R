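#' Default library specifications for a seven-library kidney run
#'
#' Seven multiplexed libraries named after the breeds of a porcine kidney
#' small-RNA study design: two libraries of European origin (IB, WB), three
#' European commercial libraries (LD, LW, PT) and two of Asian origin
#' (ME, VT). Each library carries a distinct 5-nt multiplex identifier (MID)
#' prepended to its reads and shares one 3' adapter.
#'
#' @return data.frame with columns `library_id`, `breed`, `group`, `mid`,
#'   `adapter3`.
#' @export
default_library_specs <- function() {
  data.frame(
    library_id = c("IB", "WB", "LD", "LW", "PT", "ME", "VT"),
    breed = c("Iberian", "WildBoar", "Landrace", "LargeWhite",
              "Pietrain", "Meishan", "Vietnamese"),
    group = c("EU", "EU", "EA", "EA", "EA", "AS", "AS"),
    mid = c("ACGTA", "CAGTC", "GTCAG", "TCAGT", "AGCTG", "CTGAC", "GACTG"),
    adapter3 = "CTGTAGGCACCATCAAT",
    stringsAsFactors = FALSE
  )
}

#' Configuration for a synthetic small-RNA experiment
#'
#' Bundles every knob of the generator: the genome and reference sizes, the
#' per-library sequencing depths, the isomiR end-shift model, planted group
#' expression effects and the number of planted novel hairpins and
#' non-hairpin decoy loci. Library depths default to the totals of the
#' seven-library kidney run the generator emulates.
#'
#' @param seed single integer; all randomness in the generator derives from
#'   it by fixed offsets.
#' @param n_mirnas number of annotated miRNA hairpin loci to plant.
#' @param genome_length genome size in nt; defaults to 400 nt per planted
#'   locus with a 20 kb floor. Must be at least 200 nt per locus.
#' @param library_specs data.frame as [default_library_specs()].
#' @param library_depths named integer vector of reads per library; names
#'   must match `library_specs$library_id`.
#' @param isomir_model list with `p_shift5`, `p_shift3` (per-end shift
#'   probabilities; 3' variability is typically the larger), `p_internal_edit`
#'   and `max_shift` (maximum end shift in nt, at most 4 to stay inside the
#'   annotation tolerance).
#' @param effect_table data.frame (`mirna_id`, `group`, `effect`) of
#'   multiplicative expression effects, or NULL for none.
#' @param n_novel number of planted unannotated novel hairpins.
#' @param n_decoys number of planted unannotated loci without hairpin
#'   structure (negative controls for discovery).
#' @param background_weight relative expression weight given to each novel
#'   and decoy locus, as a fraction of the summed annotated weights.
#' @return list of class `srna_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_mirnas = 30L,
                              genome_length = NULL,
                              library_specs = default_library_specs(),
                              library_depths = c(IB = 4022L, WB = 18391L,
                                                 LD = 13704L, LW = 23815L,
                                                 PT = 20215L, ME = 17407L,
                                                 VT = 17751L),
                              isomir_model = list(p_shift5 = 0.1,
                                                  p_shift3 = 0.3,
                                                  p_internal_edit = 0.02,
                                                  max_shift = 2L),
                              effect_table = NULL,
                              n_novel = 5L,
                              n_decoys = 3L,
                              background_weight = 0.004) {
  validate_library_specs(library_specs)
  if (is.null(names(library_depths))) {
    names(library_depths) <- library_specs$library_id
  }
  if (!setequal(names(library_depths), library_specs$library_id)) {
    stop("library_depths names must match library_specs$library_id")
  }
  if (any(library_depths <= 0)) stop("library depths must be > 0")
  for (p in c("p_shift5", "p_shift3", "p_internal_edit")) {
    if (isomir_model[[p]] < 0 || isomir_model[[p]] > 1) {
      stop(p, " must be a probability in [0, 1]")
    }
  }
  if (isomir_model$max_shift > 4L) {
    stop("max_shift above 4 would exceed the annotation end tolerance")
  }
  n_loci <- n_mirnas + n_novel + n_decoys
  if (is.null(genome_length)) {
    genome_length <- max(20000L, 400L * max(n_loci, 1L))
  }
  if (n_loci > 0 && genome_length < 200L * n_loci) {
    stop("genome too small to place ", n_loci, " loci without overlap; ",
         "need at least ", 200L * n_loci, " nt")
  }
  structure(list(seed = as.integer(seed), n_mirnas = as.integer(n_mirnas),
                 genome_length = as.integer(genome_length),
                 library_specs = library_specs,
                 library_depths = library_depths,
                 isomir_model = isomir_model, effect_table = effect_table,
                 n_novel = as.integer(n_novel),
                 n_decoys = as.integer(n_decoys),
                 background_weight = background_weight),
            class = "srna_config")
}

# Wobble the reverse complement of a mature so the opposite hairpin arm
# stays fully pairable (G.U wobbles allowed) but is not an exact reverse
# complement: otherwise every planted mature would also occur on the minus
# strand and unique-mapping checks would be meaningless.
wobble_arm <- function(mature) {
  arm <- strsplit(revcomp(mature), "")[[1]]
  bases <- strsplit(mature, "")[[1]]
  L <- length(bases)
  # mature position p pairs with arm position L + 1 - p
  cand <- which(bases %in% c("G", "T"))
  if (length(cand) < 2L) return(paste(arm, collapse = ""))  # rare; still pairable
  pick <- sort(sample(cand, min(3L, length(cand))))
  for (p in pick) {
    arm[L + 1L - p] <- if (bases[p] == "G") "T" else "G"
  }
  paste(arm, collapse = "")
}

count_genome_hits <- function(seq, genome_string) {
  fwd <- gregexpr(seq, genome_string, fixed = TRUE)[[1]]
  rev <- gregexpr(revcomp(seq), genome_string, fixed = TRUE)[[1]]
  sum(fwd > 0) + sum(rev > 0)
}

#' Generate a mini genome with planted miRNA hairpins
#'
#' Plants `n_mirnas` annotated hairpin loci (mature 19-23 nt on one arm, an
#' 8-nt loop and a wobbled reverse-complement opposite arm), `n_novel`
#' unannotated hairpins and `n_decoys` unannotated non-hairpin loci into an
#' i.i.d. uniform-ACGT background genome. Every planted mature is guaranteed
#' to occur exactly once over both genome strands, and novel/decoy sequences
#' are guaranteed not to match any annotated mature within the default end
#' tolerance of the annotation stage. The annotation mask covers the
#' annotated hairpin spans only.
#'
#' @param config an `srna_config` from [simulation_config()].
#' @return list of class `srna_reference` with elements `genome`
#'   (a [Biostrings::DNAStringSet] with one chromosome), `mature`
#'   (data.frame `mirna_id`, `sequence`), `mask`
#'   (a [GenomicRanges::GRanges]), and `truth` (data.frame of all planted
#'   loci with 0-based half-open coordinates, strand, kind and base
#'   expression weight).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "srna_config"))
  set.seed(derive_seed(config$seed, 1L))
  glen <- config$genome_length
  n_loci <- config$n_mirnas + config$n_novel + config$n_decoys

  genome <- sample(DNA_BASES, glen, replace = TRUE)
  if (n_loci == 0L) {
    gstr <- paste(genome, collapse = "")
    return(structure(list(
      genome = Biostrings::DNAStringSet(stats::setNames(gstr, "chr1")),
      mature = data.frame(mirna_id = character(), sequence = character(),
                          stringsAsFactors = FALSE),
      mask = GenomicRanges::GRanges(),
      truth = data.frame(mirna_id = character(), sequence = character(),
                         chrom = character(), start = integer(),
                         end = integer(), strand = character(),
                         kind = character(), hairpin_start = integer(),
                         hairpin_end = integer(), base_weight = numeric(),
                         stringsAsFactors = FALSE)
    ), class = "srna_reference"))
  }

  kind <- c(rep("known", config$n_mirnas), rep("novel", config$n_novel),
            rep("decoy", config$n_decoys))
  slot <- glen %/% n_loci
  loci <- vector("list", n_loci)
  gstr <- NULL

  plant_locus <- function(i, genome) {
    L <- sample(19:23, 1L)
    mature <- random_dna(L)
    if (kind[i] == "decoy") {
      block <- mature
      mstart_in_block <- 0L
    } else {
      block <- paste0(mature, random_dna(8L), wobble_arm(mature))
      mstart_in_block <- 0L
    }
    strand <- sample(c("+", "-"), 1L)
    placed <- if (strand == "+") block else revcomp(block)
    bl <- nchar(placed)
    lo <- (i - 1L) * slot
    off <- sample.int(slot - bl - 10L, 1L)
    pos0 <- lo + off                      # 0-based start of block
    genome[(pos0 + 1L):(pos0 + bl)] <- strsplit(placed, "")[[1]]
    # mature span in plus coordinates, 0-based half-open
    if (strand == "+") {
      ms <- pos0
    } else {
      ms <- pos0 + bl - L
    }
    list(genome = genome,
         locus = data.frame(
           mirna_id = if (kind[i] == "known") sprintf("ssc-miR-sim%d", i)
                      else sprintf("%s%d", kind[i], i),
           sequence = mature, chrom = "chr1",
           start = ms, end = ms + L, strand = strand, kind = kind[i],
           hairpin_start = pos0, hairpin_end = pos0 + bl,
           base_weight = NA_real_, stringsAsFactors = FALSE))
  }

  for (i in seq_len(n_loci)) {
    res <- plant_locus(i, genome)
    genome <- res$genome
    loci[[i]] <- res$locus
  }
  truth <- do.call(rbind, loci)
  gstr <- paste(genome, collapse = "")

  # Repair any sequence that is not unique over both strands, or any
  # unannotated sequence matching an annotated mature end-tolerantly.
  known_seqs <- function(tr) tr$sequence[tr$kind == "known"]
  for (iter in 1:50) {
    bad <- vapply(seq_len(n_loci), function(i) {
      s <- truth$sequence[i]
      if (count_genome_hits(s, gstr) != 1L) return(TRUE)
      if (truth$kind[i] != "known" &&
          !is.null(match_end_tolerant(s, known_seqs(truth))$mirna_index)) {
        return(TRUE)
      }
      FALSE
    }, logical(1))
    if (!any(bad)) break
    for (i in which(bad)) {
      res <- plant_locus(i, genome)
      genome <- res$genome
      loci[[i]] <- res$locus
    }
    truth <- do.call(rbind, loci)
    gstr <- paste(genome, collapse = "")
  }

  mask <- GenomicRanges::GRanges()
  if (config$n_mirnas > 0L) {
    k <- truth$kind == "known"
    mask <- GenomicRanges::GRanges(
      seqnames = "chr1",
      ranges = IRanges::IRanges(start = truth$hairpin_start[k] + 1L,
                                end = truth$hairpin_end[k]),
      strand = truth$strand[k])
    names(mask) <- truth$mirna_id[k]
  }

  # Base expression weights: heavy-tailed, as real miRNAomes are dominated
  # by a handful of abundant species.
  w <- numeric(n_loci)
  w[truth$kind == "known"] <- stats::rlnorm(config$n_mirnas, 0, 1)
  bg <- config$background_weight * sum(w)
  w[truth$kind != "known"] <- bg
  truth$base_weight <- w

  mature <- truth[truth$kind == "known", c("mirna_id", "sequence")]
  rownames(mature) <- NULL
  rownames(truth) <- NULL
  structure(list(
    genome = Biostrings::DNAStringSet(stats::setNames(gstr, "chr1")),
    mature = mature, mask = mask, truth = truth
  ), class = "srna_reference")
}

#' Draw isomiR sequence variants of a mature miRNA
#'
#' Each draw independently perturbs the two ends of the mature: with
#' probability `p_shift5` (`p_shift3`) the 5' (3') end is shifted by
#' 1..`max_shift` nt, equally likely a truncation or a templated extension
#' whose bases are read from the precursor context, so drawn variants remain
#' genome-mappable. With probability `p_internal_edit` one internal
#' (non-terminal) position is substituted. With all probabilities zero every
#' draw equals the mature sequence.
#'
#' @param mature mature sequence (>= 2 * `max_shift` nt).
#' @param context precursor context containing the mature, with at least
#'   `max_shift` nt of flank on both sides.
#' @param model isomiR model list (see [simulation_config()]).
#' @param n_draws number of variants to draw.
#' @param mature_offset 1-based position of the mature within `context`.
#' @param seed optional seed set before drawing.
#' @return character vector of `n_draws` tag sequences.
#' @export
simulate_isomirs <- function(mature, context, model, n_draws,
                             mature_offset = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(mature)
  ms <- model$max_shift
  if (L < 2L * ms) stop("mature shorter than twice max_shift")
  if (is.null(mature_offset)) {
    mature_offset <- as.integer(regexpr(mature, context, fixed = TRUE))
    if (mature_offset < 1L) stop("mature not found in context")
  }
  if (mature_offset <= ms || nchar(context) < mature_offset + L - 1L + ms) {
    stop("context must flank the mature by at least max_shift nt")
  }
  n <- as.integer(n_draws)
  if (n == 0L) return(character(0))

  draw_delta <- function(p) {
    hit <- stats::runif(n) < p
    amt <- if (ms > 0) sample.int(ms, n, replace = TRUE) else rep(0L, n)
    dir <- sample(c(-1L, 1L), n, replace = TRUE)  # -1 trim, +1 extend
    ifelse(hit, amt * dir, 0L)
  }
  d5 <- draw_delta(model$p_shift5)
  d3 <- draw_delta(model$p_shift3)
  starts <- mature_offset - d5
  ends <- mature_offset + L - 1L + d3
  out <- substring(context, starts, ends)

  edit <- which(stats::runif(n) < model$p_internal_edit)
  for (i in edit) {
    len <- nchar(out[i])
    if (len < 3L) next
    pos <- sample(2:(len - 1L), 1L)
    old <- substr(out[i], pos, pos)
    substr(out[i], pos, pos) <- sample(setdiff(DNA_BASES, old), 1L)
  }
  out
}

# Strand-oriented mature context (mature +/- max_shift flank) for templated
# extensions, read from the planted genome.
mature_context <- function(truth_row, genome_string, pad) {
  lo <- max(1L, truth_row$start + 1L - pad)
  hi <- min(nchar(genome_string), truth_row$end + pad)
  win <- substr(genome_string, lo, hi)
  if (truth_row$strand == "+") {
    list(context = win, offset = truth_row$start + 1L - lo + 1L)
  } else {
    list(context = revcomp(win), offset = hi - truth_row$end + 1L)
  }
}

#' Simulate multiplexed read libraries from a planted reference
#'
#' For each library, reads are drawn multinomially across all planted loci
#' with probabilities proportional to base expression weights; effects from
#' `config$effect_table` scale an affected miRNA's expected share in that
#' library's group by exactly the stated factor, with the unaffected
#' background renormalized to absorb the compositional shift. Each read's
#' insert is an isomiR draw of the locus sequence, and the emitted read is
#' `MID + insert + 3' adapter`. Per-library read totals equal the
#' configured depths exactly.
#'
#' @param reference an `srna_reference` from [generate_reference()].
#' @param config the `srna_config` used to generate it.
#' @return list of class `srna_simulation` with `reads` (named character
#'   vector, pooled and deterministically shuffled), `truth_counts`
#'   (loci x libraries matrix of realized source counts), `truth_inserts`
#'   (data.frame `library_id`, `mirna_id`, `sequence`, `count` of the exact
#'   insert multiset emitted) and the `reference`/`config` used.
#' @export
simulate_libraries <- function(reference, config) {
  stopifnot(inherits(reference, "srna_reference"),
            inherits(config, "srna_config"))
  set.seed(derive_seed(config$seed, 2L))
  truth <- reference$truth
  specs <- config$library_specs
  depths <- config$library_depths[specs$library_id]
  gstr <- as.character(reference$genome[[1]])
  ms <- config$isomir_model$max_shift

  ctx <- lapply(seq_len(nrow(truth)), function(i)
    mature_context(truth[i, ], gstr, pad = max(ms, 1L)))

  # Effects act on expected read shares: an affected miRNA's sampling
  # probability is scaled by exactly its effect, and the background
  # absorbs the compositional shift, so the planted between-group fold
  # change of affected miRNAs equals the stated effect in expectation.
  eff_probs <- function(lib_group) {
    p <- truth$base_weight / sum(truth$base_weight)
    et <- config$effect_table
    if (is.null(et)) return(p)
    hit <- match(paste(truth$mirna_id, lib_group),
                 paste(et$mirna_id, et$group))
    aff <- !is.na(hit)
    if (!any(aff)) return(p)
    e <- et$effect[hit[aff]]
    s_aff <- sum(p[aff])
    s_new <- sum(p[aff] * e)
    if (s_new >= 1) {
      stop("effect_table scales affected miRNAs past the whole library; ",
           "reduce effects or affected shares")
    }
    p[!aff] <- p[!aff] * (1 - s_new) / (1 - s_aff)
    p[aff] <- p[aff] * e
    p
  }

  counts <- matrix(0L, nrow = nrow(truth), ncol = nrow(specs),
                   dimnames = list(truth$mirna_id, specs$library_id))
  reads <- vector("list", nrow(specs))
  inserts <- vector("list", nrow(specs))
  for (j in seq_len(nrow(specs))) {
    w <- eff_probs(specs$group[j])
    nj <- as.vector(stats::rmultinom(1, depths[j], prob = w))
    counts[, j] <- nj
    lib_inserts <- character(depths[j])
    src <- integer(depths[j])
    pos <- 0L
    for (i in which(nj > 0L)) {
      v <- simulate_isomirs(truth$sequence[i], ctx[[i]]$context,
                            config$isomir_model, nj[i],
                            mature_offset = ctx[[i]]$offset)
      lib_inserts[(pos + 1L):(pos + nj[i])] <- v
      src[(pos + 1L):(pos + nj[i])] <- i
      pos <- pos + nj[i]
    }
    reads[[j]] <- paste0(specs$mid[j], lib_inserts, specs$adapter3[j])
    tab <- stats::aggregate(
      list(count = rep(1L, depths[j])),
      by = list(mirna_id = truth$mirna_id[src], sequence = lib_inserts),
      FUN = sum)
    tab$library_id <- specs$library_id[j]
    inserts[[j]] <- tab
  }
  pooled <- unlist(reads)
  pooled <- pooled[sample.int(length(pooled))]
  names(pooled) <- sprintf("read%07d", seq_along(pooled))
  truth_inserts <- do.call(rbind, inserts)
  truth_inserts <- truth_inserts[order(truth_inserts$library_id,
                                       truth_inserts$mirna_id,
                                       truth_inserts$sequence), ]
  rownames(truth_inserts) <- NULL
  structure(list(reads = pooled, truth_counts = counts,
                 truth_inserts = truth_inserts,
                 reference = reference, config = config),
            class = "srna_simulation")
}

#' Generate reference and libraries in one call
#'
#' @param config an `srna_config`.
#' @return an `srna_simulation`; see [simulate_libraries()].
#' @export
simulate_srna_experiment <- function(config) {
  simulate_libraries(generate_reference(config), config)
}

#' Effect table targeting well-expressed simulated miRNAs
#'
#' Convenience builder mirroring the validation design of profiling
#' studies, where well-expressed miRNAs are the ones taken forward: the
#' `n` most abundant annotated miRNAs whose individual expected read share
#' lies within `share_range` receive a multiplicative effect in one group.
#' The share window keeps each affected miRNA abundant enough for its fold
#' change to be estimable, while excluding dominant miRNAs whose scaling
#' would consume the library (effects act on expected shares; see
#' [simulate_libraries()]).
#'
#' @param reference an `srna_reference`.
#' @param n number of affected miRNAs.
#' @param group group label receiving the effect.
#' @param effect multiplicative effect.
#' @param share_range eligible per-miRNA expected share window.
#' @param max_total_share cap on the summed post-effect share of the
#'   affected set; miRNAs are added in decreasing abundance until the cap
#'   would be exceeded.
#' @return data.frame usable as `effect_table` in [simulation_config()].
#' @export
top_effect_table <- function(reference, n = 10L, group = "EU", effect = 2,
                             share_range = c(0.015, 0.06),
                             max_total_share = 0.6) {
  truth <- reference$truth
  share <- truth$base_weight / sum(truth$base_weight)
  ok <- truth$kind == "known" & share >= share_range[1] &
    share <= share_range[2]
  known <- truth[ok, ]
  known$share <- share[ok]
  known <- known[order(-known$base_weight), ]
  picked <- character(0)
  acc <- 0
  for (i in seq_len(nrow(known))) {
    if (length(picked) >= n) break
    if (acc + known$share[i] * effect > max_total_share) next
    picked <- c(picked, known$mirna_id[i])
    acc <- acc + known$share[i] * effect
  }
  if (length(picked) < n) {
    warning("only ", length(picked), " miRNAs are eligible for the ",
            "requested effect; using those")
  }
  data.frame(mirna_id = picked, group = group, effect = effect,
             stringsAsFactors = FALSE)
}

#' Write a simulation to disk
#'
#' Writes the genome and mature reference as FASTA, the annotation mask as
#' BED (0-based half-open), the pooled reads as FASTA and the truth tables
#' as TSV.
#'
#' @param sim an `srna_simulation`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- sim$reference
  paths <- c(genome = file.path(dir, "genome.fa"),
             mature = file.path(dir, "mature.fa"),
             mask = file.path(dir, "mask.bed"),
             reads = file.path(dir, "reads.fa"),
             truth_counts = file.path(dir, "truth_counts.tsv"),
             truth_inserts = file.path(dir, "truth_inserts.tsv"),
             libraries = file.path(dir, "libraries.tsv"))
  Biostrings::writeXStringSet(ref$genome, paths["genome"])
  mat <- Biostrings::DNAStringSet(
    stats::setNames(ref$mature$sequence, ref$mature$mirna_id))
  Biostrings::writeXStringSet(mat, paths["mature"])
  if (length(ref$mask) > 0) {
    bed <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(ref$mask)),
      start = GenomicRanges::start(ref$mask) - 1L,
      end = GenomicRanges::end(ref$mask),
      name = names(ref$mask), score = 0L,
      strand = as.character(GenomicRanges::strand(ref$mask)))
  } else {
    bed <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = integer(), strand = character())
  }
  utils::write.table(bed, paths["mask"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$reads),
                              paths["reads"])
  utils::write.table(data.frame(mirna_id = rownames(sim$truth_counts),
                                sim$truth_counts, check.names = FALSE),
                     paths["truth_counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth_inserts, paths["truth_inserts"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$config$library_specs, paths["libraries"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
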