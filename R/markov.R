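#' Parameters of a mixture of first-order Markov chains over network paths
#'
#' Each of the `M` mixture components is a first-order Markov chain through
#' the network: component `m` assigns every edge `t` a transition
#' probability `theta[t, m]`, the probability of traversing edge `t` given
#' the path currently sits at `t`'s source compound.  Transition
#' probabilities of the edges leaving any one compound therefore sum to 1
#' within each component, and with a single start node the initial-state
#' probability is identically 1, so the probability of a complete path is
#' just the product of the traversed-edge probabilities.
#'
#' @param network A [gene_network()].
#' @param pi Numeric length-`M` vector of component priors; must sum to 1.
#' @param theta Numeric `P x M` matrix of per-edge transition probabilities
#'   (rows ordered as the network's edges).
#'
#' @return An object of class `markov_mix`.
#' @export
markov_mix <- function(network, pi, theta) {
  stopifnot(inherits(network, "gene_network"))
  theta <- as.matrix(theta)
  P <- nrow(network$edges)
  M <- length(pi)
  if (nrow(theta) != P || ncol(theta) != M) {
    stop("theta must be P x M", call. = FALSE)
  }
  obj <- structure(
    list(network = network, pi = as.numeric(pi), theta = theta, M = M),
    class = "markov_mix"
  )
  validate_markov_mix(obj)
  obj
}

# Invariant checks: simplex prior and per-source-node normalization.
validate_markov_mix <- function(obj, tol = 1e-8) {
  if (any(obj$pi < -tol) || abs(sum(obj$pi) - 1) > tol) {
    stop("component priors must form a probability simplex", call. = FALSE)
  }
  if (any(obj$theta < -tol)) stop("theta must be nonnegative", call. = FALSE)
  groups <- out_edge_index(obj$network)
  for (g in groups) {
    if (length(g) == 0L) next
    s <- colSums(obj$theta[g, , drop = FALSE])
    if (any(abs(s - 1) > 1e-6)) {
      stop("out-edge transition probabilities must sum to 1 per compound",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.markov_mix <- function(x, ...) {
  cat("<markov_mix> ", x$M, " Markov-chain component(s) over ",
      nrow(x$network$edges), " edges\n", sep = "")
  cat("pi:", format(x$pi, digits = 4), "\n")
  invisible(x)
}

#' Probability of one path under one Markov-chain component
#'
#' The product over traversed edges of the component's transition
#' probabilities (the single start node contributes probability 1).
#'
#' @param theta_m Numeric length-`P` vector of one component's transition
#'   probabilities.
#' @param x Binary path vector of length `P`.
#' @return A probability in `[0, 1]`.
#' @export
component_path_probability <- function(theta_m, x) {
  stopifnot(length(theta_m) == length(x))
  prod(theta_m[x == 1])
}

# N x M matrix of log p(x_i | theta_m); log(0) guarded to -Inf cleanly.
component_log_prob <- function(X, theta) {
  lt <- log(theta)
  lt[theta == 0] <- -Inf
  L <- matrix(0, nrow(X), ncol(theta))
  for (m in seq_len(ncol(theta))) {
    col <- lt[, m]
    fin <- is.finite(col)
    L[, m] <- X[, fin, drop = FALSE] %*% col[fin]
    if (any(!fin)) {
      hit <- X[, !fin, drop = FALSE] %*% rep(1, sum(!fin))
      L[hit > 0, m] <- -Inf
    }
  }
  L
}

#' Mixture probability of a path
#'
#' @param params A [markov_mix()].
#' @param x Binary path vector.
#' @return `sum_m pi_m * p(x | theta_m)`.
#' @export
mixture_path_probability <- function(params, x) {
  stopifnot(inherits(params, "markov_mix"))
  sum(params$pi * vapply(
    seq_len(params$M),
    function(m) component_path_probability(params$theta[, m], x),
    numeric(1)
  ))
}

#' Posterior component memberships of paths
#'
#' Bayes rule over the mixture: `p(m | x) = pi_m p(x|theta_m) / sum_k
#' pi_k p(x|theta_k)`, computed in log space.  A path assigned probability 0
#' by every component falls back to the uniform distribution with a warning.
#'
#' @param params A [markov_mix()].
#' @param X Binary path matrix (`N x P`) or a pathway-data tibble containing
#'   the network's edge columns; a single path vector is also accepted.
#' @return An `N x M` matrix with rows summing to 1.
#' @export
posterior_component_probability <- function(params, X) {
  stopifnot(inherits(params, "markov_mix"))
  X <- as_path_matrix(X, params$network)
  L <- component_log_prob(X, params$theta)
  L <- sweep(L, 2L, log(params$pi), "+")
  dead <- !is.finite(apply(L, 1L, max))
  if (any(dead)) {
    warning(sum(dead), " path(s) have zero probability under every ",
            "component; uniform posterior used")
    L[dead, ] <- 0
  }
  H <- exp(L - row_logsumexp(L))
  H / rowSums(H)
}

as_path_matrix <- function(X, network) {
  if (is.data.frame(X)) {
    X <- pathway_matrix(X, network, require_y = FALSE)$X
  } else if (is.null(dim(X))) {
    X <- matrix(X, nrow = 1)
  }
  storage.mode(X) <- "double"
  X
}

#' Maximization step for the Markov mixture
#'
#' Given responsibilities `H`, re-estimates the component priors as the mean
#' responsibility and each transition probability as the
#' responsibility-weighted count of paths traversing that edge, normalized
#' over the edges sharing its source compound.  A small pseudocount `eps` is
#' added to every edge before normalization so that no observed path is
#' assigned probability 0 mid-fit; a compound whose out-edges receive no
#' weight at all thereby gets a uniform distribution.
#'
#' @param X Binary path matrix or pathway-data tibble.
#' @param H `N x M` responsibility matrix; rows must sum to 1.
#' @param network A [gene_network()].
#' @param eps Pseudocount added to weighted edge counts (default `1e-6`).
#' @return A [markov_mix()].
#' @export
mixture_m_step <- function(X, H, network, eps = 1e-6) {
  X <- as_path_matrix(X, network)
  H <- as.matrix(H)
  if (nrow(H) != nrow(X)) stop("X and H disagree on N", call. = FALSE)
  if (any(abs(rowSums(H) - 1) > 1e-6)) {
    stop("responsibility rows must sum to 1", call. = FALSE)
  }
  pi <- colMeans(H)
  counts <- crossprod(X, H) + eps # P x M weighted traversal counts
  theta <- counts
  for (g in out_edge_index(network)) {
    if (length(g) == 0L) next
    s <- colSums(counts[g, , drop = FALSE])
    theta[g, ] <- sweep(counts[g, , drop = FALSE], 2L, s, "/")
  }
  markov_mix(network, pi, theta)
}

#' Fit a mixture of Markov chains by (unsupervised) EM
#'
#' Alternates [posterior_component_probability()] (E-step) and
#' [mixture_m_step()] (M-step) to maximize the mixture log-likelihood of the
#' observed paths.  This is the unsupervised gating model on its own; inside
#' the full classifier the responsibilities additionally involve the expert
#' likelihoods.
#'
#' @param data Pathway-data tibble (edge columns; any `y` column is
#'   ignored) or a binary matrix.
#' @param network A [gene_network()].
#' @param M Number of components.
#' @param max_iter,tol EM iteration cap and absolute log-likelihood
#'   convergence tolerance.
#' @param seed Optional integer controlling the random initialization.
#' @param n_restarts Random initializations tried; the highest-likelihood
#'   fit is kept (mixture likelihoods are multimodal).
#'
#' @return An object of class `markov_mix_fit` with elements `params`
#'   ([markov_mix()]), `logLik` (final value), `trace` (per-iteration
#'   log-likelihood), `H` (final responsibilities), `n_iter`, `converged`.
#' @export
fit_markov_mixture <- function(data, network, M = 2, max_iter = 200,
                               tol = 1e-8, seed = NULL, n_restarts = 3) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- markov_mixture_em(data, network, M, max_iter, tol,
                             seed = derive_seed(seed, r))
    if (is.null(best) || fit$logLik > best$logLik) best <- fit
  }
  best
}

markov_mixture_em <- function(data, network, M, max_iter, tol, seed) {
  X <- as_path_matrix(data, network)
  N <- nrow(X)
  if (M < 1 || M > N) stop("need 1 <= M <= N", call. = FALSE)
  H <- with_seed(seed, {
    G <- matrix(stats::rgamma(N * M, shape = 1), N, M)
    G / rowSums(G)
  })
  params <- mixture_m_step(X, H, network)
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    L <- sweep(component_log_prob(X, params$theta), 2L, log(params$pi), "+")
    ll <- sum(row_logsumexp(L))
    trace <- c(trace, ll)
    H <- exp(L - row_logsumexp(L))
    H <- H / rowSums(H)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    params <- mixture_m_step(X, H, network)
  }
  structure(
    list(
      params = params, logLik = trace[length(trace)], trace = trace,
      H = H, n_iter = length(trace), converged = converged, M = M
    ),
    class = "markov_mix_fit"
  )
}

#' @export
print.markov_mix_fit <- function(x, ...) {
  cat("<markov_mix_fit> M = ", x$M, ", logLik = ",
      format(x$logLik, digits = 6), ", ", x$n_iter, " EM iteration(s)",
      if (x$converged) " (converged)" else "", "\n", sep = "")
  invisible(x)
}
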