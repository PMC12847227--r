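# Multigroup graded response model by marginal maximum likelihood.
#
# Bock-Aitkin EM over a fixed, equally spaced quadrature grid with
# normal-density weights (spectrally accurate for smooth integrands on a
# grid this fine). Item parameters are constrained equal across groups;
# the reference group prior is fixed at N(0,1) and the remaining groups'
# latent means/SDs are estimated in the M-step. The M-step maximizes the
# expected complete-data log-likelihood per item (quasi-Newton on an
# order-preserving reparameterization), so the marginal log-likelihood is
# monotone non-decreasing across cycles.

quadrature_grid <- function(n_nodes = 81L, range = c(-8, 8)) {
  list(nodes = seq(range[1], range[2], length.out = n_nodes))
}

# prior weights on the grid for one group: normalized normal density
prior_weights <- function(nodes, mean, sd) {
  w <- stats::dnorm(nodes, mean, sd)
  w / sum(w)
}

# (a, b) <-> unconstrained: (log a, b1, log diff(b))
grm_par_pack <- function(a, b) c(log(a), b[1], log(diff(b)))
grm_par_unpack <- function(par) {
  a <- exp(par[1])
  b <- cumsum(c(par[2], exp(par[-(1:2)])))
  list(a = a, b = b)
}

# expected complete-data negative log-likelihood for one item:
# r is a K x Q matrix of expected counts per category and node
grm_item_negll <- function(par, r, nodes) {
  p <- grm_par_unpack(par)
  probs <- t(grm_category_probs(p$a, p$b, nodes))  # K x Q
  probs <- pmax(probs, 1e-300)
  -sum(r * log(probs))
}

# analytic gradient of grm_item_negll in the packed parameterization
grm_item_grad <- function(par, r, nodes) {
  p <- grm_par_unpack(par)
  a <- p$a; b <- p$b
  K <- length(b) + 1L
  Q <- length(nodes)
  Fk <- rbind(1, vapply(b, function(bk) stats::plogis(a * (nodes - bk)),
                        numeric(Q)) |> t(), 0)       # (K+1) x Q boundaries
  P <- pmax(Fk[1:K, , drop = FALSE] - Fk[2:(K + 1), , drop = FALSE], 1e-300)
  w <- r / P                                          # K x Q
  # dF_k/da and dF_k/db_{k-1} for interior boundaries k = 2..K
  dFda <- matrix(0, K + 1, Q)
  dFdb <- matrix(0, K + 1, Q)    # derivative wrt its own threshold
  for (k in 2:K) {
    fk <- Fk[k, ] * (1 - Fk[k, ])
    dFda[k, ] <- fk * (nodes - b[k - 1])
    dFdb[k, ] <- -a * fk
  }
  # dP_k = dF_k - dF_{k+1}
  g_a <- -sum(w * (dFda[1:K, , drop = FALSE] - dFda[2:(K + 1), , drop = FALSE]))
  # wrt each threshold b_m: appears in F_{m+1} only: P_m gains +dF, P_{m+1} -dF
  g_b <- vapply(seq_len(K - 1), function(m) {
    sum((w[m, ] - w[m + 1, ]) * dFdb[m + 1, ])
  }, numeric(1))
  # chain rule to packed scale: log a, b1, log diffs
  J_b <- c(sum(g_b), if (K > 2)
    vapply(2:(K - 1), function(j) sum(g_b[j:(K - 1)]) * exp(par[j + 1]),
           numeric(1)))
  c(g_a * a, J_b)
}

#' Fit a multigroup graded response model
#'
#' Marginal maximum likelihood via Bock-Aitkin EM on a fixed quadrature grid.
#' Item discriminations and thresholds are common to all groups; the first
#' (reference) group's latent distribution is fixed at N(0,1) and other
#' groups' means and SDs are estimated. Respondents with all items missing
#' are excluded; partially missing patterns contribute their observed items.
#'
#' @param data Response data frame with item columns (`item01...`) and,
#'   optionally, a `group` column (single group assumed otherwise).
#' @param n_quad Number of quadrature nodes (default 81).
#' @param quad_range Node range (default `c(-8, 8)`).
#' @param tol EM stops when the largest absolute parameter change is below
#'   this (default 1e-4).
#' @param max_iter Maximum EM cycles (default 500); hitting it flags
#'   `converged = FALSE` but parameters are still returned.
#' @param reference Reference group label; defaults to `"population"` when
#'   present, else the first group encountered.
#' @return A [grm_parameters] object with fit metadata, plus attribute
#'   `"loglik_trace"` (per-cycle marginal log-likelihoods).
#' @export
fit_grm_multigroup <- function(data, n_quad = 81L, quad_range = c(-8, 8),
                               tol = 1e-4, max_iter = 500L,
                               reference = NULL) {
  items <- item_columns(data)
  if (length(items) < 2) stop_sw("need at least 2 items")
  x <- as.matrix(data[, items, drop = FALSE])
  storage.mode(x) <- "integer"
  keep <- rowSums(!is.na(x)) > 0
  x <- x[keep, , drop = FALSE]
  group <- if ("group" %in% names(data)) as.character(data$group[keep]) else
    rep("all", nrow(x))
  K <- max(x, na.rm = TRUE)
  n_items <- ncol(x)
  for (j in seq_len(n_items)) {
    obs <- sort(unique(x[!is.na(x[, j]), j]))
    if (length(obs) < 2) {
      stop_sw("item '", items[j], "' has fewer than 2 observed categories")
    }
  }

  glev <- unique(group)
  if (is.null(reference)) {
    reference <- if ("population" %in% glev) "population" else glev[1]
  }
  glev <- c(reference, setdiff(glev, reference))
  gidx <- match(group, glev)
  G <- length(glev)

  grid <- quadrature_grid(n_quad, quad_range)
  nodes <- grid$nodes
  Q <- length(nodes)

  # starting values: a = 1, thresholds from inverse-normal cumulative props
  a <- rep(1, n_items)
  b <- matrix(NA_real_, n_items, K - 1)
  for (j in seq_len(n_items)) {
    tab <- tabulate(x[, j], nbins = K)
    cum <- cumsum(tab) / sum(tab)              # P(X <= k), k = 1..K
    q <- stats::qnorm(pmin(pmax(cum[-K], 1e-4), 1 - 1e-4))
    q <- sort(q)
    for (k in seq_along(q)[-1]) q[k] <- max(q[k], q[k - 1] + 1e-3)
    b[j, ] <- q
  }
  gmean <- rep(0, G); gsd <- rep(1, G)

  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L

  # per-item index matrices once (categories per respondent)
  xl <- lapply(seq_len(n_items), function(j) x[, j])

  repeat {
    iter <- iter + 1L
    # E-step -------------------------------------------------------------
    # likelihood of each respondent at each node: n x Q
    L <- matrix(1, nrow(x), Q)
    for (j in seq_len(n_items)) {
      P <- grm_category_probs(a[j], b[j, ], nodes)    # Q x K
      xj <- xl[[j]]
      ok <- which(!is.na(xj))
      L[ok, ] <- L[ok, ] * t(P[, xj[ok], drop = FALSE])
    }

    W <- t(vapply(seq_len(G), function(g) prior_weights(nodes, gmean[g], gsd[g]),
                  numeric(Q)))                        # G x Q
    prior_mat <- W[gidx, , drop = FALSE]              # n x Q
    joint <- L * prior_mat
    marg <- rowSums(joint)
    ll <- sum(log(marg))
    ll_trace <- c(ll_trace, ll)
    post <- joint / marg                              # n x Q posteriors

    # expected counts
    old <- c(a, b, gmean[-1], gsd[-1])

    # M-step: items ------------------------------------------------------
    for (j in seq_len(n_items)) {
      xj <- xl[[j]]
      ok <- which(!is.na(xj))
      r <- matrix(0, K, Q)
      pj <- post[ok, , drop = FALSE]
      xo <- xj[ok]
      for (k in seq_len(K)) {
        rows <- xo == k
        if (any(rows)) r[k, ] <- colSums(pj[rows, , drop = FALSE])
      }
      par0 <- grm_par_pack(a[j], b[j, ])
      opt <- stats::optim(par0, grm_item_negll, grm_item_grad,
                          r = r, nodes = nodes, method = "BFGS",
                          control = list(maxit = 50, reltol = 1e-9))
      p <- grm_par_unpack(opt$par)
      a[j] <- p$a
      b[j, ] <- p$b
    }

    # M-step: non-reference group moments ---------------------------------
    if (G > 1) {
      for (g in 2:G) {
        ng <- which(gidx == g)
        nbar <- colSums(post[ng, , drop = FALSE])
        negq <- function(par) {
          w <- prior_weights(nodes, par[1], exp(par[2]))
          -sum(nbar * log(pmax(w, 1e-300)))
        }
        opt <- stats::optim(c(gmean[g], log(gsd[g])), negq, method = "BFGS",
                            control = list(maxit = 100, reltol = 1e-12))
        gmean[g] <- opt$par[1]
        gsd[g] <- exp(opt$par[2])
      }
    }

    delta <- max(abs(c(a, b, gmean[-1], gsd[-1]) - old))
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }

  # final marginal log-likelihood at the converged parameters
  L <- matrix(1, nrow(x), Q)
  for (j in seq_len(n_items)) {
    P <- grm_category_probs(a[j], b[j, ], nodes)
    xj <- xl[[j]]
    ok <- which(!is.na(xj))
    L[ok, ] <- L[ok, ] * t(P[, xj[ok], drop = FALSE])
  }
  W <- t(vapply(seq_len(G), function(g) prior_weights(nodes, gmean[g], gsd[g]),
                numeric(Q)))
  ll <- sum(log(rowSums(L * W[gidx, , drop = FALSE])))
  ll_trace <- c(ll_trace, ll)

  if (!converged) {
    warning("EM did not converge in ", max_iter, " cycles (last delta ",
            format(delta), ")")
  }
  out <- grm_parameters(
    a = a, b = b,
    groups = data.frame(group = glev, mean = gmean, sd = gsd,
                        stringsAsFactors = FALSE),
    items = items, loglik = ll, iterations = iter, converged = converged
  )
  attr(out, "loglik_trace") <- ll_trace
  attr(out, "quadrature") <- list(n_quad = n_quad, range = quad_range)
  out
}

#' Expected-a-posteriori latent trait scores
#'
#' Posterior mean and SD of theta for each response pattern under the group's
#' normal prior, evaluated on the same fixed quadrature grid used for fitting;
#' the IRT T-score is `10 * theta + 50`.
#'
#' @param data Response data frame (or a single pattern as a numeric vector).
#' @param params A [grm_parameters] object.
#' @param group Group label(s) selecting the prior; defaults to the `group`
#'   column when present, else the reference group.
#' @param n_quad,quad_range Quadrature spec; defaults to the one stored in
#'   `params` (81 nodes on [-8, 8] otherwise).
#' @return Data frame with columns `theta`, `se`, `t_irt`.
#' @export
eap_score <- function(data, params, group = NULL, n_quad = NULL,
                      quad_range = NULL) {
  if (is.numeric(data) && is.null(dim(data))) {
    data <- as.data.frame(as.list(stats::setNames(data, params$items)))
  }
  items <- intersect(params$items, names(data))
  if (length(items) == 0) stop_sw("no item columns matching the parameter set")
  x <- as.matrix(data[, items, drop = FALSE])
  storage.mode(x) <- "integer"
  if (any(rowSums(!is.na(x)) == 0)) {
    stop_sw("response pattern with all items missing")
  }
  if (any(x < 1 | x > params$n_categories, na.rm = TRUE)) {
    stop_sw("responses outside the declared category range")
  }
  qspec <- attr(params, "quadrature")
  n_quad <- n_quad %||% (qspec$n_quad %||% 81L)
  quad_range <- quad_range %||% (qspec$range %||% c(-8, 8))
  nodes <- quadrature_grid(n_quad, quad_range)$nodes
  Q <- length(nodes)

  if (is.null(group)) {
    group <- if ("group" %in% names(data)) as.character(data$group) else
      params$groups$group[1]
  }
  group <- rep_len(group, nrow(x))
  gi <- match(group, params$groups$group)
  if (anyNA(gi)) stop_sw("unknown group label")

  jmap <- match(items, params$items)
  L <- matrix(1, nrow(x), Q)
  for (jj in seq_along(items)) {
    j <- jmap[jj]
    P <- grm_category_probs(params$a[j], params$b[j, ], nodes)
    xj <- x[, jj]
    ok <- which(!is.na(xj))
    L[ok, ] <- L[ok, ] * t(P[, xj[ok], drop = FALSE])
  }
  W <- t(vapply(seq_len(nrow(params$groups)), function(g) {
    prior_weights(nodes, params$groups$mean[g], params$groups$sd[g])
  }, numeric(Q)))
  joint <- L * W[gi, , drop = FALSE]
  post <- joint / rowSums(joint)
  theta <- as.numeric(post %*% nodes)
  m2 <- as.numeric(post %*% nodes^2)
  se <- sqrt(pmax(m2 - theta^2, 0))
  data.frame(theta = theta, se = se, t_irt = theta_to_t(theta))
}

#' Affine map from latent trait to the T metric
#'
#' @param theta Latent trait value(s).
#' @return `10 * theta + 50`.
#' @export
theta_to_t <- function(theta) 10 * theta + 50
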