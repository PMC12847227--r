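#' Round half away from zero
#'
#' Commercial rounding: 0.5 always moves away from zero, unlike [base::round()]
#' which rounds half to even. Crosswalk exports use this rule so that published
#' tables (rounded by conventional software) are reproduced.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5), 0)   # 1, 2, -1
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# item columns are "item01".."itemNN" by convention; fall back to everything
# that is not a reserved metadata column
item_columns <- function(data) {
  nm <- names(data)
  items <- grep("^item[0-9]+$", nm, value = TRUE)
  if (length(items) == 0) {
    items <- setdiff(nm, c("group", "age", "gender", "education", "id"))
  }
  items
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sw <- function(...) stop(..., call. = FALSE)
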