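#' Linear T-score from reference mean and SD
#'
#' `T = 10 * (rs - M) / SD + 50`.
#'
#' @param rs Raw score(s).
#' @param ref_mean,ref_sd Reference-group mean and SD (SD > 0).
#' @return T-score(s).
#' @examples
#' linear_t(12, 61.72, 8.76)  # -6.76
#' @export
linear_t <- function(rs, ref_mean, ref_sd) {
  if (!is.finite(ref_sd) || ref_sd <= 0) stop_sw("ref_sd must be > 0")
  10 * (rs - ref_mean) / ref_sd + 50
}

#' Rank-based inverse normal (Rankit-family) transform
#'
#' Ties receive average ranks `r`, then each value maps to
#' `qnorm((r - k) / (n - 2k + 1))`. The offset `k` selects the plotting
#' position: `k = 0.5` is the Rankit position `(r - 0.5)/n`, `k = 0.375` the
#' Blom position, `k = 0` the van der Waerden position `r/(n + 1)`.
#'
#' @param values Numeric sample (length >= 1; NAs passed through).
#' @param offset Plotting-position offset `k` in `[0, 0.5]`. Default 0.5.
#' @return Z-scores, same length/order as input; order-preserving, identical
#'   values share identical output.
#' @examples
#' inverse_normal_rank(c(10, 20, 30, 40, 50))  # -1.2816 ... 1.2816
#' @export
inverse_normal_rank <- function(values, offset = 0.5) {
  if (length(values) == 0) stop_sw("empty input")
  if (offset < 0 || offset > 0.5) stop_sw("offset must be in [0, 0.5]")
  ok <- !is.na(values)
  n <- sum(ok)
  out <- rep(NA_real_, length(values))
  if (n == 0) return(out)
  r <- rank(values[ok], ties.method = "average")
  p <- (r - offset) / (n - 2 * offset + 1)
  stopifnot(all(p > 0 & p < 1))  # impossible to violate for k in [0, 0.5]
  out[ok] <- stats::qnorm(p)
  out
}

#' Rankit-based T-score for a raw score against a reference sample
#'
#' Each raw score maps to the inverse-normal-rank Z shared by all reference
#' members with that score, then `T = 10 * Z + 50`. A raw score not observed
#' in the reference has no rank and returns `NA` (interpolation is the
#' crosswalk module's job).
#'
#' @param rs Raw score(s) to convert.
#' @param reference Reference sample of raw scores.
#' @param offset Plotting-position offset, as in [inverse_normal_rank()].
#' @return T-score(s); `NA` where `rs` is unobserved in the reference.
#' @examples
#' rankit_t(2, c(1, 1, 2, 3, 5))  # 50
#' @export
rankit_t <- function(rs, reference, offset = 0.5) {
  z <- inverse_normal_rank(reference, offset)
  u <- !duplicated(reference) & !is.na(reference)
  lookup <- stats::setNames(z[u], reference[u])
  out <- 10 * unname(lookup[as.character(rs)]) + 50
  if (anyNA(out[!is.na(rs)])) {
    attr(out, "unobserved") <- unique(rs[!is.na(rs) & is.na(out)])
  }
  out
}
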