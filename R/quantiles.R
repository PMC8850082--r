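#' Weighted quantile of the step-function type
#'
#' Returns, for each probability `p`, the smallest observed value whose
#' cumulative normalized weight is at least `p`.  With equal weights this is
#' the left-continuous inverse of the empirical CDF (quantile type 1).  All
#' tertile, quartile and median computations in this package use this one
#' definition so that scoring and descriptive statistics agree.
#'
#' @param x Numeric values (NA not allowed).
#' @param probs Probabilities in (0, 1].
#' @param w Optional positive weights, recycled to `length(x)`; `NULL` means
#'   equal weights.
#' @return Named numeric vector of quantiles, one per `probs`.
#' @export
weighted_quantile <- function(x, probs, w = NULL) {
  if (anyNA(x)) stop("x must not contain NA")
  if (length(x) == 0L) stop("x is empty")
  if (is.null(w)) w <- rep(1, length(x))
  w <- rep_len(w, length(x))
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and >= 0")
  tot <- sum(w)
  if (tot <= 0) stop("total weight must be positive")
  if (any(probs <= 0 | probs > 1)) stop("probs must lie in (0, 1]")
  o <- order(x)
  xs <- x[o]
  cw <- cumsum(w[o]) / tot
  q <- vapply(probs, function(p) xs[which(cw >= p)[1L]], numeric(1),
              USE.NAMES = FALSE)
  names(q) <- paste0(format(100 * probs, trim = TRUE), "%")
  q
}
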