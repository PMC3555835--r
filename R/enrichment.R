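#' Exact hypergeometric over/under-representation tails
#'
#' For a universe of `N` genes of which `K` belong to a category, and a
#' target set of `n` genes with `k` in the category:
#' `p_over = P(X >= k)` and `p_under = P(X <= k)` under
#' Hypergeometric(N, K, n). The two tails share `P(X = k)`, so they sum to
#' at least 1.
#'
#' @param N universe size.
#' @param K category size within the universe.
#' @param n target-set size.
#' @param k overlap between target set and category.
#' @return list with `p_over`, `p_under`.
#' @export
hypergeom_test <- function(N, K, n, k) {
  if (K > N || n > N || k > min(K, n) || k < max(0L, n - (N - K)) ||
      any(c(N, K, n, k) < 0)) {
    stop("inconsistent hypergeometric counts")
  }
  list(p_over = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
       p_under = stats::phyper(k, K, N - K, n))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min over j >= i of (m/j) * p_(j)`, returned in the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric category enrichment of a target gene set
#'
#' Tests each category for over- and under-representation among the
#' targets. By default the two directions are adjusted as separate BH
#' families (`joint = TRUE` pools them). A category is significant when its
#' smaller adjusted tail is below `alpha`.
#'
#' @param targets character vector of target gene ids (subset of the
#'   universe).
#' @param categories named list of character vectors (category id ->
#'   member gene ids), e.g. parsed from a GMT-like file with
#'   [read_gmt()].
#' @param universe background gene set; defaults to all genes appearing in
#'   the category map.
#' @param alpha significance threshold on the adjusted p-value.
#' @param joint adjust both tails as one BH family.
#' @return data.frame ranked by the smaller adjusted tail, with `category`,
#'   `N`, `K`, `n`, `k`, `p_over`, `p_under`, `q_over`, `q_under`,
#'   `direction`, `significant`.
#' @export
enrich <- function(targets, categories, universe = NULL, alpha = 0.05,
                   joint = FALSE) {
  if (is.null(universe)) {
    universe <- unique(unlist(categories, use.names = FALSE))
  }
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  targets <- unique(intersect(targets, universe))
  if (!all(targets %in% universe)) stop("targets must lie in the universe")
  N <- length(universe)
  n <- length(targets)
  rows <- lapply(names(categories), function(cid) {
    members <- intersect(categories[[cid]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(targets, members))
    ht <- hypergeom_test(N, K, n, k)
    data.frame(category = cid, N = N, K = K, n = n, k = k,
               p_over = ht$p_over, p_under = ht$p_under,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out) || nrow(out) == 0L) {
    stop("no testable categories")
  }
  if (joint) {
    q <- bh_adjust(c(out$p_over, out$p_under))
    out$q_over <- q[seq_len(nrow(out))]
    out$q_under <- q[nrow(out) + seq_len(nrow(out))]
  } else {
    out$q_over <- bh_adjust(out$p_over)
    out$q_under <- bh_adjust(out$p_under)
  }
  out$direction <- ifelse(out$q_over <= out$q_under, "over", "under")
  out$significant <- pmin(out$q_over, out$q_under) < alpha
  out <- out[order(pmin(out$q_over, out$q_under), out$category), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a GMT-like category map
#'
#' Tab-separated lines: category id, description, then member gene ids.
#'
#' @param path file path.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[[`, character(1), 1L))
}
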