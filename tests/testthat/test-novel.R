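test_that("perfect mapping agrees with a naive substring scan", {
  cfg <- test_config(seed = 120L)
  ref <- generate_reference(cfg)
  g <- as.character(ref$genome[[1]])
  grc <- oracle_revcomp(g)
  glen <- nchar(g)
  for (i in sample(nrow(ref$truth), 6L)) {
    s <- ref$truth$sequence[i]
    loci <- map_perfect(s, ref$genome)
    fwd <- gregexpr(s, g, fixed = TRUE)[[1]]
    fwd <- fwd[fwd > 0]
    rev <- gregexpr(s, grc, fixed = TRUE)[[1]]
    rev <- rev[rev > 0]
    expect_equal(nrow(loci), length(fwd) + length(rev))
    expect_equal(loci$start[loci$strand == "+"], fwd - 1L)
    # minus-strand hits in plus coordinates
    expect_equal(sort(loci$start[loci$strand == "-"]),
                 sort(glen - (rev - 1L) - nchar(s)))
    tr <- ref$truth[i, ]
    expect_equal(loci$start, tr$start)
    expect_equal(loci$strand, tr$strand)
  }
  expect_equal(nrow(map_perfect(strrep("ACGT", 6), ref$genome)), 0L)
})

test_that("candidate selection applies length, mapping, mask and CN rules", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("A", 30),
    "GCTTGATCGGTACCATGCAGT",          # unique locus, outside mask
    strrep("C", 30),
    "TTGACCGTAGGCATCAATGGA",          # unique locus, inside mask
    strrep("G", 28))))
  mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(82, 102))
  mk_tag <- function(seq, cn) data.frame(
    sequence = seq, length = nchar(seq), L1 = cn, cn = cn,
    stringsAsFactors = FALSE)
  tags <- rbind(
    mk_tag("GCTTGATCGGTACCATGCAGT", 10L),            # kept
    mk_tag("TTGACCGTAGGCATCAATGGA", 10L),            # masked
    mk_tag(paste0("GCTTGATCGGTACCATGCAGT", "CCC"), 10L),  # 24 nt
    mk_tag(strrep("A", 20), 10L),                    # multi-mapping
    mk_tag("GCTTGATCGGTACCATGCAG", 2L))              # CN not > 2
  cand <- select_candidates(tags, genome, mask)
  expect_equal(cand$sequence, "GCTTGATCGGTACCATGCAGT")
  expect_equal(cand$start, 30L)
  # CN boundary is strict: CN 3 passes
  cand3 <- select_candidates(mk_tag("GCTTGATCGGTACCATGCAG", 3L),
                             genome, mask)
  expect_equal(nrow(cand3), 1L)
})

test_that("filters commute: any application order yields the same candidates", {
  cfg <- test_config(seed = 130L, depth = 500L)
  sim <- simulate_srna_experiment(cfg)
  pre <- preprocess_reads(sim$reads, cfg$library_specs)
  ann <- assign_tags(pre$tags, sim$reference$mature)
  tags <- ann$unannotated
  genome <- sim$reference$genome
  mask <- sim$reference$mask
  joint <- select_candidates(tags, genome, mask)$sequence
  # apply the individual filters in a different order by pre-restricting
  by_len_first <- tags[tags$length >= 19 & tags$length <= 23, ]
  by_cn_first <- tags[tags$cn > 2, ]
  expect_setequal(select_candidates(by_len_first, genome, mask)$sequence,
                  joint)
  expect_setequal(select_candidates(by_cn_first, genome, mask)$sequence,
                  joint)
})

test_that("positional clustering groups overlapping loci single-linkage", {
  base <- data.frame(
    sequence = c("AAACCCGGGTTTAAACCCGGG", "AACCCGGGTTTAAACCCGGGT",
                 "TTTGGGCCCAAATTTGGGCCC"),
    length = 21L, L1 = c(16L, 3L, 9L), cn = c(16L, 3L, 9L),
    chrom = "chr1", start = c(100L, 101L, 300L),
    end = c(121L, 122L, 321L), strand = "+", stringsAsFactors = FALSE)
  cl <- cluster_by_locus(base)
  expect_length(cl, 2L)
  expect_equal(cl[[1]]$cn, 19L)
  expect_equal(cl[[1]]$reference_sequence, "AAACCCGGGTTTAAACCCGGG")
  # adjacent but non-overlapping loci stay separate
  base2 <- base
  base2$start[2] <- 121L
  base2$end[2] <- 142L
  expect_length(cluster_by_locus(base2), 3L)
  # opposite strands never merge
  base3 <- base
  base3$strand[2] <- "-"
  expect_length(cluster_by_locus(base3), 3L)
})

test_that("a cluster shaped like the Cl-38 candidate is assembled faithfully", {
  refseq <- "TCTCCGTTTGCCTGTTTTGCTGA"  # 23 nt, cluster CN 21, 3 isomiRs
  members <- data.frame(
    sequence = c(refseq,
                 substr(refseq, 1, 22),
                 paste0(substr(refseq, 2, 23), "A")),
    length = c(23L, 22L, 23L),
    L1 = c(15L, 4L, 2L), cn = c(15L, 4L, 2L),
    chrom = "chr3", start = c(500L, 500L, 501L),
    end = c(523L, 522L, 524L), strand = "-", stringsAsFactors = FALSE)
  cl <- cluster_by_locus(members)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$cn, 21L)
  expect_equal(cl[[1]]$isomir_count, 3L)
  expect_equal(cl[[1]]$reference_sequence, refseq)
  expect_equal(cl[[1]]$strand, "-")
})

test_that("precursor extraction is strand-aware and clips at boundaries", {
  g <- paste(rep(c("A", "C", "G", "T"), length.out = 400), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = g))
  cl <- list(chrom = "chr1", start = 100L, end = 121L, strand = "+")
  prec <- extract_precursor(cl, genome, flank = 50L)
  expect_equal(nchar(prec$sequence), 121L)
  expect_equal(c(prec$mature_start, prec$mature_end), c(51L, 71L))
  expect_equal(substr(prec$sequence, 51, 71), substr(g, 101, 121))

  # minus strand: oriented precursor is the reverse complement of the window
  clm <- list(chrom = "chr1", start = 100L, end = 121L, strand = "-")
  precm <- extract_precursor(clm, genome, flank = 50L)
  expect_equal(precm$sequence, oracle_revcomp(substr(g, 51, 171)))
  expect_equal(substr(precm$sequence, precm$mature_start, precm$mature_end),
               oracle_revcomp(substr(g, 101, 121)))

  # clipping near the chromosome start is reported
  cl0 <- list(chrom = "chr1", start = 10L, end = 31L, strand = "+")
  prec0 <- extract_precursor(cl0, genome, flank = 50L)
  expect_equal(prec0$clipped5, 40L)
  expect_equal(c(prec0$mature_start, prec0$mature_end), c(11L, 31L))
  expect_error(extract_precursor(list(chrom = "chrX", start = 1L, end = 20L,
                                      strand = "+"), genome),
               "missing chromosome")
})

test_that("hairpin folding passes inverted repeats and fails unstructured RNA", {
  set.seed(31)
  s <- random_seq(30)
  prec <- paste0(s, "GAAA", oracle_revcomp(s))
  fold <- fold_hairpin(prec, 5L, 26L)  # mature inside the 5' arm
  expect_gte(fold$mature_arm_pairs, 16L)
  expect_true(fold$pass)
  expect_true(fold$unbranched)

  flat <- fold_hairpin(strrep("A", 121), 51L, 71L)
  expect_equal(flat$n_pairs, 0L)
  expect_false(flat$pass)
  expect_error(fold_hairpin("ACGT", 1L, 20L), "shorter")
})

test_that("folding DP equals exhaustive structure enumeration on short RNAs", {
  set.seed(33)
  cases <- c(
    "GGGAAACCC", "GGGGAAAACCCC", "GCGCAAAAGCGC",
    vapply(1:8, function(i) random_seq(sample(12:20, 1)), character(1)))
  for (s in cases) {
    fold <- fold_hairpin(s, 1L, nchar(s))
    expect_equal(fold$n_pairs, oracle_max_pairs(s), info = s)
  }
})

test_that("Watson-Crick-only pair count is invariant under reverse complement", {
  # with G.U wobbles the invariance cannot hold exactly (the complement of
  # a G.U pair is C.A, which does not pair), so it is asserted for
  # Watson-Crick-only folding
  set.seed(34)
  for (i in 1:6) {
    s <- random_seq(60)
    a <- fold_hairpin(s, 20L, 40L, allow_gu = FALSE)$n_pairs
    b <- fold_hairpin(oracle_revcomp(s), 20L, 40L, allow_gu = FALSE)$n_pairs
    expect_equal(a, b)
  }
})

test_that("dot-bracket structure is balanced and consistent with pair count", {
  set.seed(35)
  s <- random_seq(100)
  fold <- fold_hairpin(s, 40L, 60L)
  chars <- strsplit(fold$structure, "")[[1]]
  expect_equal(sum(chars == "("), sum(chars == ")"))
  expect_equal(sum(chars == "("), fold$n_pairs)
  depth <- cumsum((chars == "(") - (chars == ")"))
  expect_true(all(depth >= 0))
  expect_equal(depth[length(depth)], 0)
  # minimum hairpin loop respected
  expect_true(all(fold$pairs[, 2] - fold$pairs[, 1] > 3L))
})

test_that("planted novel hairpins validate and decoys are mostly rejected", {
  cfg <- test_config(seed = 140L, depth = 900L, n_novel = 3L, n_decoys = 0L,
                     isomir_model = zero_noise_model)
  sim <- simulate_srna_experiment(cfg)
  pre <- preprocess_reads(sim$reads, cfg$library_specs)
  ann <- assign_tags(pre$tags, sim$reference$mature)
  nov <- discover_novel(ann$unannotated, sim$reference$genome,
                        sim$reference$mask)
  truth <- sim$reference$truth
  novel_seqs <- truth$sequence[truth$kind == "novel"]
  found <- nov$table$reference_sequence[nov$table$fold_pass]
  expect_setequal(found, novel_seqs)

  # non-hairpin loci: random precursors rarely satisfy the arm criteria
  set.seed(141)
  passes <- vapply(1:12, function(i) {
    fold_hairpin(random_seq(121), 51L, 71L)$pass
  }, logical(1))
  expect_lte(mean(passes), 0.25)
})
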