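mir23a_ref <- "ATCACATTGCCAGGGATTTCC"     # database mature
mir23a_top <- "ATCACATTGCCAGGGATTTCCA"    # most expressed variant (+1 nt 3')

test_that("end-tolerant matcher handles identity, end variants and overflow", {
  ref <- c("ssc-miR-23a" = mir23a_ref)
  m <- match_end_tolerant(mir23a_ref, ref)
  expect_equal(m$cost, 0L)
  expect_equal(c(m$n5, m$n3), c(0L, 0L))

  m2 <- match_end_tolerant(mir23a_top, ref)
  expect_equal(c(m2$n5, m2$n3), c(0L, 1L))

  # 5-nt 3' extension exceeds the 4-nt total tolerance
  q5 <- paste0(mir23a_ref, "ACGTA")
  expect_null(match_end_tolerant(q5, ref))
  expect_equal(oracle_match_cost(q5, mir23a_ref), Inf)

  expect_error(match_end_tolerant("", ref), "non-empty")
})

test_that("matcher agrees with the brute-force core-enumeration oracle", {
  set.seed(202)
  refs <- vapply(1:6, function(i) random_seq(sample(20:23, 1)), character(1))
  names(refs) <- sprintf("ssc-miR-t%d", 1:6)
  n_cases <- 400L
  for (case in seq_len(n_cases)) {
    # half the queries are perturbed copies of a reference, half random
    if (case %% 2 == 0) {
      base <- refs[[sample(length(refs), 1)]]
      t5 <- sample(0:3, 1); t3 <- sample(0:3, 1)
      q <- substr(base, 1 + t5, nchar(base) - t3)
      if (runif(1) < 0.5) q <- paste0(random_seq(sample(0:2, 1)), q)
      if (runif(1) < 0.5) q <- paste0(q, random_seq(sample(0:2, 1)))
      if (nchar(q) < 15) q <- paste0(q, random_seq(15 - nchar(q)))
      if (nchar(q) > 29) q <- substr(q, 1, 29)
    } else {
      q <- random_seq(sample(15:29, 1))
    }
    hits <- isomiRpipe:::match_candidates(q, refs)
    impl_costs <- rep(Inf, length(refs))
    if (!is.null(hits)) impl_costs[hits$mirna_index] <- hits$cost
    oracle_costs <- vapply(refs, function(r) oracle_match_cost(q, r),
                           numeric(1), USE.NAMES = FALSE)
    expect_equal(impl_costs, oracle_costs)
  }
})

test_that("raising the tolerance never loses annotated tags", {
  set.seed(77)
  refs <- stats::setNames(vapply(1:5, function(i) random_seq(21),
                                 character(1)),
                          sprintf("ssc-miR-m%d", 1:5))
  queries <- unlist(lapply(refs, function(r) {
    c(r, paste0("AC", r), substr(r, 1, nchar(r) - 3),
      paste0(substr(r, 3, nchar(r)), "GT"))
  }), use.names = FALSE)
  matched <- vapply(2:6, function(tol) {
    sum(vapply(queries, function(q)
      !is.null(match_end_tolerant(q, refs, tolerance = tol)), logical(1)))
  }, numeric(1))
  expect_true(all(diff(matched) >= 0))
})

test_that("assignment prefers lower cost, then the porcine reference", {
  refs <- data.frame(
    mirna_id = c("hsa-miR-x", "ssc-miR-x"),
    sequence = c("ACGTGGACTTAGCATCGATCA", "ACGTGGACTTAGCATCGATCA"),
    stringsAsFactors = FALSE)
  tags <- data.frame(sequence = "ACGTGGACTTAGCATCGATCA", length = 21L,
                     L1 = 5L, cn = 5L, stringsAsFactors = FALSE)
  ann <- assign_tags(tags, refs)
  expect_equal(names(ann$clusters), "ssc-miR-x")

  # a cheaper ortholog match beats a costlier porcine one
  refs2 <- data.frame(
    mirna_id = c("hsa-miR-y", "ssc-miR-y"),
    sequence = c("ACGTGGACTTAGCATCGATCA", "CGTGGACTTAGCATCGATC"),
    stringsAsFactors = FALSE)
  ann2 <- assign_tags(tags, refs2)
  expect_equal(names(ann2$clusters), "hsa-miR-y")
})

test_that("clusters report predominance and database divergence", {
  # counts shaped like the most extreme divergence case observed in kidney:
  # the +1 nt 3' variant outnumbers the database mature 3116 to 622
  refs <- c("ssc-miR-23a" = mir23a_ref)
  tags <- data.frame(
    sequence = c(mir23a_top, mir23a_ref),
    length = nchar(c(mir23a_top, mir23a_ref)),
    L1 = c(3116L, 622L), cn = c(3116L, 622L), stringsAsFactors = FALSE)
  ann <- assign_tags(tags, refs)
  cl <- ann$clusters[["ssc-miR-23a"]]
  expect_equal(cl$predominant, mir23a_top)
  expect_true(cl$diverges_from_reference)
  expect_equal(cl$cn, 3738L)
  expect_equal(cl$isomir_count, 2L)

  solo <- assign_tags(tags[2, ], refs)$clusters[["ssc-miR-23a"]]
  expect_false(solo$diverges_from_reference)
})

test_that("profile excludes clusters below the miRNA-level CN threshold", {
  refs <- c("ssc-miR-a" = "ACGTGGACTTAGCATCGATCA",
            "ssc-miR-b" = "TTTTGGGGCCCCAAAATTTTG")
  tags <- data.frame(
    sequence = c("ACGTGGACTTAGCATCGATCA", "TTTTGGGGCCCCAAAATTTTG"),
    length = 21L, L1 = c(10L, 2L), cn = c(10L, 2L), stringsAsFactors = FALSE)
  ann <- assign_tags(tags, refs)
  prof <- build_profile(ann$clusters, min_cluster_cn = 3L, grand_total = 100)
  expect_equal(prof$mirna_id, "ssc-miR-a")
  expect_equal(prof$share_pct, 10)
  empty <- build_profile(list())
  expect_equal(nrow(empty), 0L)
})

test_that("tag partition conserves copy number", {
  cfg <- test_config(seed = 88L, depth = 500L)
  sim <- simulate_srna_experiment(cfg)
  pre <- preprocess_reads(sim$reads, cfg$library_specs)
  ann <- assign_tags(pre$tags, sim$reference$mature)
  cluster_cn <- sum(vapply(ann$clusters, `[[`, numeric(1), "cn"))
  expect_equal(cluster_cn + sum(ann$unannotated$cn), sum(pre$tags$cn))
  # each tag sits in at most one cluster
  all_members <- unlist(lapply(ann$clusters,
                               function(cl) cl$members$sequence))
  expect_false(anyDuplicated(c(all_members,
                               ann$unannotated$sequence)) > 0)
  # predominant member CN bound
  for (cl in ann$clusters) {
    expect_gte(max(cl$members$cn), cl$cn / cl$isomir_count)
  }
})

test_that("zero-noise simulation is annotated back to its source miRNAs", {
  cfg <- test_config(seed = 91L, depth = 500L,
                     isomir_model = zero_noise_model)
  sim <- simulate_srna_experiment(cfg)
  pre <- preprocess_reads(sim$reads, cfg$library_specs)
  ann <- assign_tags(pre$tags, sim$reference$mature)
  truth <- sim$reference$truth
  known <- truth[truth$kind == "known", ]
  for (id in names(ann$clusters)) {
    expect_equal(ann$clusters[[id]]$predominant,
                 known$sequence[known$mirna_id == id])
  }
  # recovered per-library counts equal simulation truth for every cluster
  for (id in names(ann$clusters)) {
    expect_equal(ann$clusters[[id]]$per_library[colnames(sim$truth_counts)],
                 sim$truth_counts[id, ],
                 ignore_attr = TRUE)
  }
})

test_that("per-group predominance reflects group-specific isomiR skew", {
  groups <- c(L1 = "EU", L2 = "AS")
  totals <- c(L1 = 1000, L2 = 1000)
  cl <- list(members = data.frame(
    sequence = c("AAAACCCCGGGGTTTTAAAA", "AAAACCCCGGGGTTTTAAAAC"),
    L1 = c(50L, 5L), L2 = c(5L, 50L), stringsAsFactors = FALSE))
  pred <- per_group_predominance(cl, groups, totals)
  expect_equal(unname(pred["EU"]), "AAAACCCCGGGGTTTTAAAA")
  expect_equal(unname(pred["AS"]), "AAAACCCCGGGGTTTTAAAAC")

  cl0 <- list(members = data.frame(
    sequence = c("AAAACCCCGGGGTTTTAAAA"), L1 = 10L, L2 = 0L,
    stringsAsFactors = FALSE))
  pred0 <- per_group_predominance(cl0, groups, totals)
  expect_true(is.na(pred0["AS"]))
  expect_equal(unname(pred0["EU"]), "AAAACCCCGGGGTTTTAAAA")
})
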