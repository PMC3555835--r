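#' Normalize raw counts to counts per thousand (cpt)
#'
#' `cpt = raw / library_total * 1000`, where the library total is that
#' library's count of all length-filtered reads. Within one library the cpt
#' values of all tags therefore sum to exactly 1000.
#'
#' @param counts numeric matrix or data.frame (features x libraries).
#' @param library_totals named numeric vector of per-library totals; names
#'   must cover the columns of `counts`.
#' @return numeric matrix of cpt values.
#' @export
normalize_cpt <- function(counts, library_totals) {
  counts <- as.matrix(counts)
  totals <- library_totals[colnames(counts)]
  if (any(is.na(totals))) stop("missing library totals")
  if (any(totals == 0)) stop("library total of zero")
  sweep(counts, 2L, totals, "/") * 1000
}

#' Mean normalized expression per group
#'
#' Unweighted arithmetic mean of the member libraries' cpt values.
#'
#' @param cpt cpt matrix from [normalize_cpt()].
#' @param groups named character vector mapping library id to group label.
#' @return matrix (features x groups).
#' @export
group_means <- function(cpt, groups) {
  groups <- groups[colnames(cpt)]
  glabs <- unique(groups)
  out <- vapply(glabs, function(g)
    rowMeans(cpt[, names(groups)[groups == g], drop = FALSE]),
    numeric(nrow(cpt)))
  if (nrow(cpt) == 1L) out <- matrix(out, nrow = 1L,
                                     dimnames = list(rownames(cpt), glabs))
  colnames(out) <- glabs
  out
}

#' Signed fold change between two group means
#'
#' If `mean_a >= mean_b` the fold change is `+mean_a / mean_b`, otherwise
#' `-mean_b / mean_a`, so `|fc| >= 1` always and the sign says which group
#' is higher. If exactly one mean is zero the fold change is undefined
#' (`NA`) and an absence flag is set instead; if both are zero the
#' comparison is skipped with both flags set.
#'
#' @param mean_a,mean_b group mean expression values (cpt).
#' @return list with `fc`, `absent_in_a`, `absent_in_b`.
#' @export
signed_fold_change <- function(mean_a, mean_b) {
  absent_a <- mean_a == 0
  absent_b <- mean_b == 0
  if (absent_a || absent_b) {
    return(list(fc = NA_real_, absent_in_a = absent_a,
                absent_in_b = absent_b))
  }
  fc <- if (mean_a >= mean_b) mean_a / mean_b else -mean_b / mean_a
  list(fc = fc, absent_in_a = FALSE, absent_in_b = FALSE)
}

#' Differential-expression call
#'
#' DE iff `|fc| > threshold` (strict) or the feature is absent in exactly
#' one of the two groups.
#'
#' @param comparison list from [signed_fold_change()].
#' @param threshold fold-change threshold (default 1.5).
#' @return logical.
#' @export
call_de <- function(comparison, threshold = 1.5) {
  one_absent <- xor(isTRUE(comparison$absent_in_a),
                    isTRUE(comparison$absent_in_b))
  if (one_absent) return(TRUE)
  if (is.na(comparison$fc)) return(FALSE)
  abs(comparison$fc) > threshold
}

#' Percentage share of total reads
#'
#' @param cn cluster copy number(s).
#' @param grand_total total read count.
#' @return share in percent, rounded to 2 decimal places.
#' @export
abundance_share <- function(cn, grand_total) {
  if (grand_total <= 0) stop("grand total must be positive")
  round(cn / grand_total * 100, 2L)
}

#' Group-wise fold-change and DE table
#'
#' Normalizes a count matrix to cpt, averages within groups, and reports
#' the signed fold change, absence flags and DE call for every pair of
#' groups. "Not expressed" in a group means a zero raw count in every
#' library of that group.
#'
#' @param counts feature x library count matrix or data.frame with
#'   feature ids as rownames.
#' @param library_totals named per-library totals (see [normalize_cpt()]).
#' @param groups named character vector mapping library id to group label.
#' @param threshold DE fold-change threshold.
#' @return data.frame with one row per feature and, per group pair `A_B`,
#'   columns `fc_A_vs_B` and `de_A_vs_B`, plus per-group mean cpt columns.
#' @export
compare_groups <- function(counts, library_totals, groups, threshold = 1.5) {
  counts <- as.matrix(counts)
  cpt <- normalize_cpt(counts, library_totals)
  means <- group_means(cpt, groups)
  glabs <- colnames(means)
  out <- data.frame(mirna_id = rownames(counts), stringsAsFactors = FALSE)
  for (g in glabs) out[[paste0("mean_", g)]] <- means[, g]
  groups <- groups[colnames(counts)]
  raw_zero <- vapply(glabs, function(g)
    rowSums(counts[, names(groups)[groups == g], drop = FALSE]) == 0,
    logical(nrow(counts)))
  if (nrow(counts) == 1L) raw_zero <- matrix(raw_zero, nrow = 1L,
                                             dimnames = list(NULL, glabs))
  for (a_i in seq_len(length(glabs) - 1L)) {
    for (b_i in (a_i + 1L):length(glabs)) {
      a <- glabs[a_i]; b <- glabs[b_i]
      fc <- de <- numeric(nrow(counts))
      for (r in seq_len(nrow(counts))) {
        cmp <- list(fc = NA_real_, absent_in_a = raw_zero[r, a],
                    absent_in_b = raw_zero[r, b])
        if (!cmp$absent_in_a && !cmp$absent_in_b) {
          cmp <- signed_fold_change(means[r, a], means[r, b])
        }
        fc[r] <- cmp$fc
        de[r] <- call_de(cmp, threshold)
      }
      out[[sprintf("fc_%s_vs_%s", a, b)]] <- fc
      out[[sprintf("de_%s_vs_%s", a, b)]] <- as.logical(de)
    }
  }
  rownames(out) <- NULL
  out
}
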