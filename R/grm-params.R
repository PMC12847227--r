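#' Graded response model parameter set
#'
#' Container for item parameters of a logistic graded response model (GRM)
#' together with per-group latent-trait moments. Each item has a positive
#' discrimination `a` and `K - 1` strictly increasing thresholds `b`, so that
#' the boundary probability of responding in category `k` or above is
#' `P*(k) = logistic(a * (theta - b[k - 1]))` and category probabilities are
#' successive differences of boundary curves. The latent scale is anchored by
#' fixing the reference group at mean 0, SD 1.
#'
#' @param a Numeric vector of item discriminations (> 0), one per item.
#' @param b Numeric matrix of thresholds, items x (K - 1), strictly
#'   increasing within each row.
#' @param groups Data frame with columns `group`, `mean`, `sd`; first row is
#'   the reference group and must be exactly (0, 1).
#' @param items Optional character vector of item identifiers.
#' @param loglik,iterations,converged Optional fit metadata.
#' @return An object of class `grm_parameters`.
#' @export
grm_parameters <- function(a, b, groups = NULL, items = NULL,
                           loglik = NA_real_, iterations = NA_integer_,
                           converged = NA) {
  b <- as.matrix(b)
  if (length(a) != nrow(b)) {
    stop_sw("'a' must have one entry per row of 'b'")
  }
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop_sw("discriminations must be positive and finite")
  }
  bad <- which(apply(b, 1, function(x) any(diff(x) <= 0)))
  if (length(bad)) {
    stop_sw("thresholds must be strictly increasing; offending item(s): ",
            paste(bad, collapse = ", "))
  }
  if (is.null(groups)) {
    groups <- data.frame(group = "population", mean = 0, sd = 1,
                         stringsAsFactors = FALSE)
  }
  if (groups$mean[1] != 0 || groups$sd[1] != 1) {
    stop_sw("reference group (first row of 'groups') must be mean 0, sd 1")
  }
  if (any(groups$sd <= 0)) stop_sw("group SDs must be positive")
  if (is.null(items)) items <- sprintf("item%02d", seq_along(a))
  structure(
    list(items = items, a = as.numeric(a), b = b, groups = groups,
         n_categories = ncol(b) + 1L,
         loglik = loglik, iterations = iterations, converged = converged),
    class = "grm_parameters"
  )
}

#' @export
print.grm_parameters <- function(x, ...) {
  cat(sprintf("Graded response model: %d items, %d categories\n",
              length(x$a), x$n_categories))
  tab <- data.frame(item = x$items, a = round(x$a, 3),
                    round(x$b, 3), check.names = FALSE)
  names(tab)[-(1:2)] <- paste0("b", seq_len(ncol(x$b)))
  print(tab, row.names = FALSE)
  cat("Groups:\n")
  print(x$groups, row.names = FALSE)
  if (!is.na(x$loglik)) {
    cat(sprintf("logLik %.4f after %d EM cycles (converged: %s)\n",
                x$loglik, x$iterations, x$converged))
  }
  invisible(x)
}

#' Category probabilities under a graded response model
#'
#' @param a Single item discrimination.
#' @param b Vector of K - 1 increasing thresholds for that item.
#' @param theta Vector of latent trait values.
#' @return Matrix `length(theta)` x K of category probabilities, rows
#'   summing to 1.
#' @export
grm_category_probs <- function(a, b, theta) {
  K <- length(b) + 1L
  # boundary curves P(X >= k), k = 2..K; pad with 1 and 0
  bound <- vapply(b, function(bk) stats::plogis(a * (theta - bk)),
                  numeric(length(theta)))
  bound <- cbind(1, matrix(bound, nrow = length(theta)), 0)
  probs <- bound[, 1:K, drop = FALSE] - bound[, 2:(K + 1), drop = FALSE]
  probs
}

#' Write / read GRM parameters as delimited text
#'
#' Round-trip stable at 12 significant digits. The file carries one row per
#' item (`item, a, b1..b{K-1}`) followed by group rows
#' (`group:<label>, mean, sd`), plus a comment header with fit metadata.
#'
#' @param params A `grm_parameters` object.
#' @param path File path.
#' @return `write_grm_parameters` returns `path` invisibly;
#'   `read_grm_parameters` returns a `grm_parameters` object.
#' @export
write_grm_parameters <- function(params, path) {
  fmt <- function(x) trimws(formatC(x, digits = 12, format = "g"))
  lines <- c(
    "# scorewalk grm_parameters v1",
    sprintf("# loglik=%s iterations=%s converged=%s",
            fmt(params$loglik), params$iterations, params$converged),
    paste(c("item", "a", paste0("b", seq_len(ncol(params$b)))), collapse = ","),
    vapply(seq_along(params$a), function(i) {
      paste(c(params$items[i], fmt(params$a[i]), fmt(params$b[i, ])),
            collapse = ",")
    }, character(1)),
    vapply(seq_len(nrow(params$groups)), function(g) {
      paste(c(paste0("group:", params$groups$group[g]),
              fmt(params$groups$mean[g]), fmt(params$groups$sd[g])),
            collapse = ",")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_grm_parameters
#' @export
read_grm_parameters <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# loglik=", lines, value = TRUE)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[-1]  # column header
  grp <- startsWith(lines, "group:")
  item_rows <- strsplit(lines[!grp], ",", fixed = TRUE)
  group_rows <- strsplit(lines[grp], ",", fixed = TRUE)
  a <- vapply(item_rows, function(r) as.numeric(r[2]), numeric(1))
  b <- t(vapply(item_rows, function(r) as.numeric(r[-(1:2)]),
                numeric(length(item_rows[[1]]) - 2L)))
  groups <- data.frame(
    group = vapply(group_rows, function(r) sub("^group:", "", r[1]), character(1)),
    mean = vapply(group_rows, function(r) as.numeric(r[2]), numeric(1)),
    sd = vapply(group_rows, function(r) as.numeric(r[3]), numeric(1)),
    stringsAsFactors = FALSE
  )
  loglik <- NA_real_; iterations <- NA_integer_; converged <- NA
  if (length(meta)) {
    m <- regmatches(meta, regexec(
      "loglik=([^ ]+) iterations=([^ ]+) converged=([^ ]+)", meta))[[1]]
    loglik <- suppressWarnings(as.numeric(m[2]))
    iterations <- suppressWarnings(as.integer(m[3]))
    converged <- as.logical(m[4])
  }
  grm_parameters(a = a, b = b, groups = groups,
                 items = vapply(item_rows, `[`, character(1), 1),
                 loglik = loglik, iterations = iterations,
                 converged = converged)
}
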