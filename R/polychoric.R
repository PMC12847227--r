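# Two-step maximum-likelihood polychoric correlations.
#
# Step 1: thresholds per item from the inverse-normal of cumulative marginal
# proportions. Step 2: the correlation maximizing the bivariate-normal
# likelihood of the observed contingency table, thresholds held fixed.
# Bivariate normal rectangle probabilities come from one-dimensional
# Gauss-Legendre quadrature of phi(x) * Phi((b - rho x)/sqrt(1 - rho^2)).

gauss_legendre <- function(n) {
  # Golub-Welsch via symmetric tridiagonal eigendecomposition on [-1, 1]
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

.poly_cache <- new.env(parent = emptyenv())
gl64 <- function() {
  if (is.null(.poly_cache$gl64)) .poly_cache$gl64 <- gauss_legendre(64)
  .poly_cache$gl64
}

# P(X <= a, Y <= b) for standard bivariate normal with correlation rho
pbvn <- function(a, b, rho) {
  if (is.infinite(a) && a > 0) return(stats::pnorm(b))
  if (is.infinite(b) && b > 0) return(stats::pnorm(a))
  if (is.infinite(a) || is.infinite(b)) return(0)
  lo <- -8.5
  if (a <= lo) return(0)
  g <- gl64()
  x <- (a + lo) / 2 + (a - lo) / 2 * g$nodes
  w <- (a - lo) / 2 * g$weights
  s <- sqrt(1 - rho^2)
  sum(w * stats::dnorm(x) * stats::pnorm((b - rho * x) / s))
}

# cell probabilities for one item pair given thresholds and rho
polychoric_cell_probs <- function(t1, t2, rho) {
  a <- c(-Inf, t1, Inf)
  b <- c(-Inf, t2, Inf)
  Fab <- outer(a, b, Vectorize(function(ai, bi) pbvn(ai, bi, rho)))
  n1 <- length(t1) + 1L
  n2 <- length(t2) + 1L
  P <- Fab[2:(n1 + 1), 2:(n2 + 1)] - Fab[1:n1, 2:(n2 + 1)] -
    Fab[2:(n1 + 1), 1:n2] + Fab[1:n1, 1:n2]
  pmax(P, 0)
}

# two-step ML polychoric for a pair of ordinal vectors
polychoric_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  lx <- sort(unique(x)); ly <- sort(unique(y))
  tab <- table(factor(x, levels = lx), factor(y, levels = ly))
  if (length(lx) < 2 || length(ly) < 2) {
    warning("degenerate contingency table; falling back to Pearson r")
    return(stats::cor(x, y))
  }
  t1 <- stats::qnorm(cumsum(rowSums(tab))[-length(lx)] / sum(tab))
  t2 <- stats::qnorm(cumsum(colSums(tab))[-length(ly)] / sum(tab))
  negll <- function(rho) {
    P <- polychoric_cell_probs(t1, t2, rho)
    -sum(tab * log(pmax(P, 1e-12)))
  }
  stats::optimize(negll, c(-0.9999, 0.9999), tol = 1e-6)$minimum
}

#' Polychoric correlation matrix of ordinal items
#'
#' Two-step maximum-likelihood estimates for every item pair. Pairs with a
#' degenerate contingency table (an item observed in fewer than two
#' categories within the pairwise-complete cases) fall back to the Pearson
#' correlation of the integer scores, with a warning.
#'
#' @param data Response data frame with >= 2 item columns.
#' @return Symmetric correlation matrix.
#' @export
polychoric_matrix <- function(data) {
  items <- item_columns(data)
  if (length(items) < 2) stop_sw("need at least 2 items")
  x <- as.matrix(data[, items, drop = FALSE])
  p <- ncol(x)
  R <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      R[i, j] <- R[j, i] <- polychoric_pair(x[, i], x[, j])
    }
  }
  dimnames(R) <- list(items, items)
  R
}

#' Eigenvalue screen of the polychoric correlation matrix
#'
#' Descending eigenvalues of the two-step ML polychoric correlation matrix --
#' the usual first look at unidimensionality of an ordinal item set (a
#' dominant first eigenvalue with the rest near or below 1).
#'
#' @param data Response data frame with >= 2 item columns.
#' @return Numeric vector of eigenvalues, descending; the polychoric matrix is
#'   attached as attribute `"R"`.
#' @export
polychoric_eigen_screen <- function(data) {
  R <- polychoric_matrix(data)
  ev <- sort(eigen(R, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  attr(ev, "R") <- R
  ev
}
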