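#' Standard error of measurement
#'
#' `S_E = SD * sqrt(1 - r_xx)`.
#'
#' @param sd Reference-group SD (>= 0).
#' @param r_xx Test reliability in `[0, 1]`.
#' @return Standard error of measurement in score units.
#' @examples
#' standard_error_measurement(8.86, 0.88)  # 3.069
#' @export
standard_error_measurement <- function(sd, r_xx) {
  if (sd < 0) stop_sw("sd must be >= 0")
  if (r_xx < 0 || r_xx > 1) stop_sw("r_xx must be in [0, 1]")
  sd * sqrt(1 - r_xx)
}

.rci_z <- c(`80` = 1.282, `90` = 1.645, `95` = 1.960)

#' Jacobson-Truax reliable change index
#'
#' Minimum change exceeding measurement error at the given confidence:
#' `RCI = z * sqrt(2 * S_E^2)` with z = 1.282 / 1.645 / 1.960 for 80 / 90 /
#' 95%.
#'
#' @param se Standard error of measurement (>= 0).
#' @param level Confidence level: 80, 90, or 95.
#' @return Minimum reliable change in score units.
#' @examples
#' rci(standard_error_measurement(8.86, 0.88), 95)  # 8.51
#' @export
rci <- function(se, level = 95) {
  if (se < 0) stop_sw("se must be >= 0")
  key <- as.character(level)
  if (!key %in% names(.rci_z)) stop_sw("level must be one of 80, 90, 95")
  .rci_z[[key]] * sqrt(2 * se^2)
}

#' Jacobson-Truax clinical-significance cutoff (criterion c)
#'
#' SD-weighted midpoint of the clinical and normative means:
#' `CS = (sd_norm * M_clin + sd_clin * M_norm) / (sd_clin + sd_norm)` --
#' each mean weighted by the *other* group's SD, placing the cutoff where the
#' two normal densities cross.
#'
#' @param clinical,normative Lists (or `descriptive_stats`) with `M` and `SD`
#'   (both SDs > 0).
#' @return Cutoff in score units, strictly between the two means when they
#'   differ.
#' @examples
#' cs_cutoff(list(M = 37.98, SD = 15.69), list(M = 50.06, SD = 8.86))  # 45.7
#' @export
cs_cutoff <- function(clinical, normative) {
  if (clinical$SD <= 0 || normative$SD <= 0) stop_sw("both SDs must be > 0")
  (normative$SD * clinical$M + clinical$SD * normative$M) /
    (clinical$SD + normative$SD)
}

#' Bundle of change thresholds for an instrument
#'
#' @param sd Reference SD used for the standard error.
#' @param r_xx Reliability.
#' @param clinical,normative Group summaries (`M`, `SD`) for the cutoff.
#' @param higher_is_better Direction flag (default `TRUE`: higher score =
#'   better functioning, as for quality-of-life scales).
#' @return List of class `change_thresholds`: `se`, `rci` (named 80/90/95),
#'   `cs`, `higher_is_better`.
#' @export
change_thresholds <- function(sd, r_xx, clinical, normative,
                              higher_is_better = TRUE) {
  se <- standard_error_measurement(sd, r_xx)
  structure(list(
    se = se,
    rci = vapply(c(80, 90, 95), function(l) rci(se, l), numeric(1)) |>
      stats::setNames(c("80", "90", "95")),
    cs = cs_cutoff(clinical, normative),
    higher_is_better = higher_is_better
  ), class = "change_thresholds")
}

#' @export
print.change_thresholds <- function(x, ...) {
  cat(sprintf("S_E = %.3f; RCI80 = %.2f, RCI90 = %.2f, RCI95 = %.2f; CS = %.2f (%s)\n",
              x$se, x$rci[["80"]], x$rci[["90"]], x$rci[["95"]], x$cs,
              if (x$higher_is_better) "higher is better" else "lower is better"))
  invisible(x)
}

#' Classify pre/post change into five outcome categories
#'
#' Jacobson-Truax end-state classification. With higher-is-better direction
#' and change `D = post - pre`:
#' * Reliable improvement: `D >= RCI(level)`; *Recovered* if additionally the
#'   pre-score lay on the dysfunctional side of the cutoff and the post-score
#'   on the functional side, else *Reliably Improved*.
#' * `|D| < RCI`: *Unchanged*.
#' * Reliable deterioration: `D <= -RCI`; *Relapsed* if additionally the
#'   pre-score was functional and the post-score dysfunctional, else
#'   *Reliably Deteriorated*.
#' Scores exactly on the cutoff count as functional for higher-is-better
#' instruments (boundary equality counts as crossing).
#'
#' @param pre,post Score vectors (same length or scalar).
#' @param thresholds A [change_thresholds()] object.
#' @param level RCI confidence level (80, 90, 95). Default 95.
#' @return Factor with levels Recovered, Reliably Improved, Unchanged,
#'   Reliably Deteriorated, Relapsed.
#' @examples
#' th <- change_thresholds(8.86, 0.88, list(M = 37.98, SD = 15.69),
#'                         list(M = 50.06, SD = 8.86))
#' classify_change(40, 50, th)  # Recovered
#' @export
classify_change <- function(pre, post, thresholds, level = 95) {
  stopifnot(inherits(thresholds, "change_thresholds"))
  rc <- thresholds$rci[[as.character(level)]]
  if (is.null(rc)) stop_sw("level must be one of 80, 90, 95")
  n <- max(length(pre), length(post))
  pre <- rep_len(pre, n); post <- rep_len(post, n)
  if (thresholds$higher_is_better) {
    delta <- post - pre
    functional <- function(s) s >= thresholds$cs
  } else {
    delta <- pre - post
    functional <- function(s) s <= thresholds$cs
  }
  lev <- c("Recovered", "Reliably Improved", "Unchanged",
           "Reliably Deteriorated", "Relapsed")
  out <- character(n)
  improved <- delta >= rc
  deteriorated <- delta <= -rc
  out[!improved & !deteriorated] <- "Unchanged"
  out[improved & !functional(pre) & functional(post)] <- "Recovered"
  out[improved & !(!functional(pre) & functional(post))] <- "Reliably Improved"
  out[deteriorated & functional(pre) & !functional(post)] <- "Relapsed"
  out[deteriorated & !(functional(pre) & !functional(post))] <-
    "Reliably Deteriorated"
  factor(out, levels = lev)
}

#' Severity band lookup for T-scores
#'
#' Half-open interval lookup over ordered cutpoints. A score exactly on a
#' cutpoint is assigned to the worse-severity side: for higher-is-better
#' instruments the lower interval, otherwise the upper. Default bands follow
#' the PROMIS-style display for quality of life, with the
#' average/below-average boundary at the clinical-significance cutoff 45.7.
#'
#' @param t T-score(s).
#' @param cutpoints Strictly increasing numeric cutpoints.
#' @param labels One more label than cutpoints, ordered worst to best for
#'   higher-is-better.
#' @param higher_is_better Direction flag (default `TRUE`).
#' @return Factor of band labels.
#' @examples
#' severity_band(50)       # Average
#' severity_band(45.7)     # Below Average (boundary goes to the worse side)
#' @export
severity_band <- function(t,
                          cutpoints = c(40, 45.7, 55, 60),
                          labels = c("Poor", "Below Average", "Average",
                                     "Above Average", "Excellent"),
                          higher_is_better = TRUE) {
  if (any(diff(cutpoints) <= 0)) stop_sw("cutpoints must be strictly ordered")
  if (length(labels) != length(cutpoints) + 1) {
    stop_sw("need one more label than cutpoints")
  }
  idx <- if (higher_is_better) {
    # boundary to the lower (worse) interval: intervals (c_i, c_{i+1}]
    findInterval(t, cutpoints, left.open = TRUE) + 1L
  } else {
    findInterval(t, cutpoints) + 1L
  }
  factor(labels[idx], levels = labels)
}
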