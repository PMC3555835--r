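#' Fit a qPCR standard curve and compute amplification efficiency
#'
#' Ordinary least squares of Cq on log10(relative input) over a serial
#' dilution series. Efficiency is `10^(-1/slope) - 1`, so a slope of
#' about -3.32 corresponds to 100% (perfect doubling per cycle). QC passes
#' iff efficiency is within [0.90, 1.10] and r-squared is at least 0.99.
#'
#' @param dilution relative input amounts (e.g. 1, 0.1, 0.01 for 10-fold
#'   serial dilutions); at least 3 distinct levels.
#' @param cq observed quantification-cycle values, same length.
#' @return object of class `standard_curve`: list with `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `qc_pass` and the fitted
#'   `model`.
#' @export
fit_standard_curve <- function(dilution, cq) {
  stopifnot(length(dilution) == length(cq))
  if (length(unique(dilution)) < 3L) {
    stop("at least 3 dilution levels are required")
  }
  if (stats::var(log10(dilution)) == 0) stop("dilutions have zero variance")
  x <- log10(dilution)
  fit <- stats::lm(cq ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  # computed directly so an exact fit does not trigger summary.lm warnings
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((cq - mean(cq))^2)
  efficiency <- 10^(-1 / slope) - 1
  structure(list(
    slope = slope, intercept = intercept, r_squared = r2,
    efficiency = efficiency,
    qc_pass = !is.na(efficiency) && efficiency >= 0.90 &&
      efficiency <= 1.10 && r2 >= 0.99,
    model = fit
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: slope %.4f, efficiency %.1f%%, r2 %.4f (%s)\n",
              x$slope, 100 * x$efficiency, x$r_squared,
              if (x$qc_pass) "QC pass" else "QC fail"))
  invisible(x)
}

#' Quantity of a sample from a fitted standard curve
#'
#' Inverts the calibration line: `quantity = 10^((cq - intercept) / slope)`,
#' on the relative-input scale of the dilution series.
#'
#' @param curve a `standard_curve`.
#' @param cq Cq values.
#' @return numeric quantities.
#' @export
curve_quantity <- function(curve, cq) {
  10^((cq - curve$intercept) / curve$slope)
}

#' geNorm reference stability and normalization factor
#'
#' For each reference j, the stability measure M_j is the mean over all
#' other references k of the standard deviation across samples of
#' log2(q_j / q_k). References with `M >= m_threshold` are excluded; the
#' per-sample normalization factor (NF) is the geometric mean of the
#' retained references' quantities. With `iterative = TRUE` the original
#' stepwise variant is used instead: the least stable reference is removed
#' and M recomputed until all remaining references satisfy the threshold
#' (at least two are always retained).
#'
#' @param quantities numeric matrix, references x samples, all > 0.
#' @param m_threshold stability threshold (default 1.5).
#' @param iterative use stepwise worst-reference elimination.
#' @return object of class `genorm_result`: list with `m` (named stability
#'   values as first computed), `retained` (reference names), `nf` (named
#'   per-sample normalization factors).
#' @export
genorm_stability <- function(quantities, m_threshold = 1.5,
                             iterative = FALSE) {
  q <- as.matrix(quantities)
  if (nrow(q) < 2L || ncol(q) < 2L) {
    stop("need at least 2 references and 2 samples")
  }
  if (any(q <= 0)) stop("quantities must be strictly positive")
  if (is.null(rownames(q))) rownames(q) <- sprintf("ref%d", seq_len(nrow(q)))

  m_values <- function(qm) {
    lq <- log2(qm)
    vapply(seq_len(nrow(qm)), function(j) {
      mean(vapply(setdiff(seq_len(nrow(qm)), j), function(k)
        stats::sd(lq[j, ] - lq[k, ]), numeric(1)))
    }, numeric(1))
  }

  m0 <- stats::setNames(m_values(q), rownames(q))
  if (iterative) {
    keep <- q
    repeat {
      m <- m_values(keep)
      if (nrow(keep) <= 2L || max(m) < m_threshold) break
      keep <- keep[-which.max(m), , drop = FALSE]
    }
    retained <- rownames(keep)
  } else {
    retained <- rownames(q)[m0 < m_threshold]
  }
  if (length(retained) == 0L) {
    stop("no reference satisfies the stability threshold")
  }
  nf <- exp(colMeans(log(q[retained, , drop = FALSE])))
  structure(list(m = m0, retained = retained, nf = nf),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm stability M:\n")
  print(round(x$m, 4))
  cat("retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Normalized relative expression of a target assay
#'
#' Divides each sample's curve-derived quantity by its normalization
#' factor, expresses it relative to the lowest normalized value (so the
#' minimum sample has fold change 1) and log2-transforms.
#'
#' @param quantities named numeric vector of per-sample target quantities.
#' @param genorm a `genorm_result` whose `nf` covers the same samples.
#' @return data.frame with `sample`, `quantity`, `normalized`, `fc`,
#'   `log2_fc`.
#' @export
relative_expression <- function(quantities, genorm) {
  nf <- genorm$nf[names(quantities)]
  if (any(is.na(nf))) stop("missing normalization factor for some samples")
  normalized <- quantities / nf
  fc <- normalized / min(normalized)
  data.frame(sample = names(quantities), quantity = unname(quantities),
             normalized = unname(normalized), fc = unname(fc),
             log2_fc = unname(log2(fc)), stringsAsFactors = FALSE)
}
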