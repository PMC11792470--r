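#' Centered log-ratio transform
#'
#' `CLR(x)_d = log x_d - mean_d' log x_d'` per row, mapping compositions (or
#' positive abundances) to a zero-sum Euclidean representation.  Zeros are
#' only admissible with a positive pseudocount, which is added to every
#' entry before taking logs; for already-relative data pass `pseudocount = 0`
#' and resolve zeros upstream.
#'
#' @param x numeric matrix n x D with nonnegative entries.
#' @param pseudocount nonnegative value added to all entries when any zero is
#'   present (default 0.5, the usual half-count for count data).
#' @return n x D matrix whose rows sum to zero.
#' @examples
#' clr(matrix(c(exp(1), exp(2), exp(3)), 1))   # (-1, 0, 1)
#' @export
clr <- function(x, pseudocount = 0.5) {
  x <- as.matrix(x)
  if (any(x < 0)) abort("clr input must be nonnegative", "medipath_domain_error")
  if (any(x == 0)) {
    if (pseudocount <= 0) {
      abort("zero entries require a positive pseudocount", "medipath_domain_error")
    }
    x <- x + pseudocount
  }
  lx <- log(x)
  sweep(lx, 1, rowMeans(lx))
}

#' Elementwise log(1 + x) transform
#'
#' Order-preserving variance stabilization for nonnegative intensities;
#' zero maps to zero.
#'
#' @param x numeric matrix with nonnegative entries.
#' @return matrix of the same shape.
#' @export
log1p_transform <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) {
    abort("log1p_transform input must be nonnegative", "medipath_domain_error")
  }
  log1p(x)
}

filter_report <- function(d_in, d_out, rule, retained = NULL) {
  structure(list(features_in = d_in, features_out = d_out, rule = rule,
                 retained_fraction = retained),
            class = "feature_filter_report")
}

#' @export
print.feature_filter_report <- function(x, ...) {
  cat(sprintf("filter [%s]: %d -> %d features", x$rule,
              x$features_in, x$features_out))
  if (!is.null(x$retained_fraction)) {
    cat(sprintf(" | mean per-sample signal retained %.1f%%",
                100 * mean(x$retained_fraction)))
  }
  cat("\n")
  invisible(x)
}

#' Keep features whose mean transformed value exceeds a threshold
#'
#' Operates on an already-transformed matrix (CLR or log1p, per the caller);
#' a column survives iff its mean is strictly greater than `threshold`.
#'
#' @param x numeric matrix n x D (transformed scale).
#' @param threshold filtering threshold on the column mean.
#' @return list with the filtered `matrix` and a `report`.
#' @export
filter_by_mean <- function(x, threshold) {
  x <- as.matrix(x)
  keep <- colMeans(x) > threshold
  if (!any(keep)) {
    abort("threshold removes every feature", "medipath_empty_result")
  }
  list(matrix = x[, keep, drop = FALSE],
       report = filter_report(ncol(x), sum(keep),
                              sprintf("column mean > %g", threshold)))
}

#' Keep features present in at least a fraction of samples
#'
#' Presence means a strictly positive count.  Used to restrict to a core set
#' of taxa; the report carries the per-sample fraction of total counts the
#' retained features preserve.
#'
#' @param counts nonnegative matrix n x D.
#' @param min_fraction required prevalence in \\[0, 1\\].
#' @return list with the filtered `matrix` and a `report` whose
#'   `retained_fraction` gives the per-sample fraction of reads preserved.
#' @export
filter_by_prevalence <- function(counts, min_fraction) {
  if (min_fraction < 0 || min_fraction > 1) {
    abort("min_fraction must be in [0, 1]", "medipath_value_error")
  }
  counts <- as.matrix(counts)
  if (any(counts < 0)) {
    abort("counts must be nonnegative", "medipath_domain_error")
  }
  prev <- colMeans(counts > 0)
  keep <- prev >= min_fraction
  tot <- rowSums(counts)
  kept <- rowSums(counts[, keep, drop = FALSE])
  retained <- ifelse(tot > 0, kept / tot, 1)
  list(matrix = counts[, keep, drop = FALSE],
       report = filter_report(ncol(counts), sum(keep),
                              sprintf("prevalence >= %g", min_fraction),
                              retained))
}
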