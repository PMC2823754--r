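#' Fit the supervised Markov mixture of experts
#'
#' Fits a two-layer hierarchical mixture of experts to labeled binary path
#' observations.  The gating layer is a mixture of `M` first-order Markov
#' chains over start-to-end paths of the supplied network, so each
#' component concentrates on a dominant pathway; the expert attached to
#' each component is a ridge-penalized logistic regression fitted on the
#' binary path vectors with observations weighted by the component
#' responsibilities.  The model likelihood is
#' `prod_i sum_m pi_m p(x_i | theta_m) p(y_i | x_i, beta_m)`
#' and is maximized by an EM algorithm:
#'
#' * E-step: responsibilities
#'   `h_im = pi_m p(x_i|theta_m) p(y_i|x_i,beta_m) / sum_k (...)`.
#' * M-step: the mixture update of [mixture_m_step()] followed by one damped
#'   penalized-IRLS fit per expert ([fit_plr()]) with weights `h_im`.
#'
#' The expert step is damped by the learning rate `alpha` (with step
#' halving as a safeguard), making the procedure a generalized EM.  Because
#' the experts carry a ridge penalty, the quantity the EM provably ascends
#' is the penalized observed-data objective (log-likelihood minus the
#' penalty terms); that objective is monitored for convergence and returned
#' as `trace`, while the raw observed-data log-likelihood is returned
#' alongside as `ll_trace`.  Experts are warm-started from the previous EM
#' iteration by default.
#'
#' @param data Pathway dataset: a tibble with one 0/1 column per network
#'   edge and a 0/1 response column `y` (e.g. from [simulate_pathways()] or
#'   [build_pathway_dataset()]).
#' @param network The [gene_network()] the paths live on; supplies the
#'   per-compound grouping that normalizes the transition probabilities.
#' @param M Number of mixture components (dominant paths sought).
#' @param lambda Ridge penalty of each expert (`lambda = 1` in the
#'   simulation protocol).
#' @param alpha Expert learning rate in `(0, 1]` (`alpha = 0.5` in the
#'   simulation protocol).
#' @param max_em_iter,em_tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param n_restarts Number of random initializations; the highest
#'   log-likelihood fit is returned.
#' @param seed Optional integer making the fit fully reproducible.
#' @param plr_max_iter,plr_tol Inner iteration controls of the expert
#'   fits.  The default of a single damped update per EM iteration is the
#'   classic generalized M-step: each expert takes one ascent step of its
#'   penalized objective per outer iteration, which is cheap, keeps the EM
#'   objective monotone, and converges to the same fixed point as fully
#'   refitting the experts every iteration.
#' @param warm_start Warm-start experts across EM iterations (default
#'   `TRUE`).
#'
#' @return An object of class `hme3m`: gate parameters (`pi`, `theta` as a
#'   [markov_mix()] in `$gate`), `experts` (list of `plr_fit`), `H` (final
#'   responsibilities), `logLik` and `ll_trace` (observed-data
#'   log-likelihood), `objective` and `trace` (penalized EM objective),
#'   `n_iter`, `converged`, and `config`.
#'
#' @examples
#' net <- make_network("small")
#' d <- simulate_pathways(net, n_per_class = 40, noise = 0.1, seed = 1)
#' fit <- fit_hme3m(d, net, M = 2, seed = 1)
#' glance(fit)
#' @export
fit_hme3m <- function(data, network, M = 2, lambda = 1, alpha = 0.5,
                      max_em_iter = 100, em_tol = 1e-6, n_restarts = 3,
                      seed = NULL, plr_max_iter = 1, plr_tol = 1e-6,
                      warm_start = TRUE) {
  pm <- pathway_matrix(data, network)
  X <- pm$X
  y <- pm$y
  N <- nrow(X)
  if (M < 1 || M > N) {
    stop("need 1 <= M <= number of observations", call. = FALSE)
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- hme3m_em(
      X, y, network, M, lambda, alpha, max_em_iter, em_tol,
      seed = derive_seed(seed, r), plr_max_iter = plr_max_iter,
      plr_tol = plr_tol, warm_start = warm_start
    )
    if (is.null(best) || fit$objective > best$objective) best <- fit
  }
  best$config <- list(
    M = M, lambda = lambda, alpha = alpha, max_em_iter = max_em_iter,
    em_tol = em_tol, n_restarts = n_restarts, seed = seed,
    plr_max_iter = plr_max_iter, plr_tol = plr_tol, warm_start = warm_start
  )
  best$call <- match.call()
  best
}

# One EM run from one random initialization.
hme3m_em <- function(X, y, network, M, lambda, alpha, max_em_iter, em_tol,
                     seed, plr_max_iter, plr_tol, warm_start) {
  N <- nrow(X)
  P <- ncol(X)
  H <- with_seed(seed, {
    G <- matrix(stats::rgamma(N * M, shape = 1), N, M)
    G / rowSums(G)
  })
  experts <- vector("list", M)
  frozen <- rep(FALSE, M)
  gate <- NULL
  m_step <- function() {
    gate <<- mixture_m_step(X, H, network)
    for (m in seq_len(M)) {
      if (frozen[m]) next
      init <- if (warm_start && !is.null(experts[[m]])) experts[[m]]$beta
      experts[[m]] <<- plr_irls(
        X, y, h = H[, m], lambda = lambda, alpha = alpha,
        max_iter = plr_max_iter, tol = plr_tol, beta_init = init
      )
    }
  }
  m_step()
  trace <- numeric(0) # penalized EM objective: the quantity EM ascends
  ll_trace <- numeric(0) # observed-data log-likelihood, for reporting
  ll_prev <- -Inf
  converged <- FALSE
  L <- NULL
  for (it in seq_len(max_em_iter)) {
    L <- joint_log_prob(X, y, gate, experts) # N x M, includes log pi
    lse <- row_logsumexp(L)
    pen <- lambda / 2 *
      sum(vapply(experts, function(e) sum(e$beta[-1]^2), numeric(1)))
    ll <- sum(lse) - pen
    trace <- c(trace, ll)
    ll_trace <- c(ll_trace, sum(lse))
    H <- exp(L - lse)
    dead <- rowSums(H) == 0 | !is.finite(rowSums(H))
    if (any(dead)) {
      warning("degenerate responsibilities for ", sum(dead),
              " row(s); uniform fallback")
      H[dead, ] <- 1 / M
    }
    H <- H / rowSums(H)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < em_tol * (abs(ll_prev) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    collapse <- !frozen & colMeans(H) < 1e-8
    if (any(collapse)) {
      warning("component(s) ", paste(which(collapse), collapse = ", "),
              " collapsed (pi < 1e-8); frozen")
      frozen[collapse] <- TRUE
    }
    m_step()
  }
  structure(
    list(
      gate = gate, experts = experts, H = H, network = network, M = M,
      logLik = ll_trace[length(ll_trace)], objective = trace[length(trace)],
      trace = trace, ll_trace = ll_trace, n_iter = length(trace),
      converged = converged, n_obs = N, P = P
    ),
    class = "hme3m"
  )
}

# log( pi_m p(x|theta_m) p(y|x,beta_m) ) for every row and component.
joint_log_prob <- function(X, y, gate, experts) {
  L <- component_log_prob(X, gate$theta)
  L <- sweep(L, 2L, log(gate$pi), "+")
  X1 <- cbind(1, X)
  sgn <- ifelse(y == 1, 1, -1) # log p(y | eta) = log sigmoid(+-eta)
  for (m in seq_along(experts)) {
    eta <- drop(X1 %*% experts[[m]]$beta)
    L[, m] <- L[, m] + stats::plogis(sgn * eta, log.p = TRUE)
  }
  L
}

#' Responsibilities of a fitted model on labeled data
#'
#' The E-step of the EM algorithm: the posterior probability that each
#' labeled path belongs to each component, combining the gate probability
#' of the path with the expert probability of its label.
#'
#' @param model A fitted [fit_hme3m()] object.
#' @param data Pathway dataset with edge columns and `y`.
#' @return An `N x M` matrix with rows summing to 1.
#' @export
e_step <- function(model, data) {
  stopifnot(inherits(model, "hme3m"))
  pm <- pathway_matrix(data, model$network)
  L <- joint_log_prob(pm$X, pm$y, model$gate, model$experts)
  lse <- row_logsumexp(L)
  H <- exp(L - lse)
  dead <- rowSums(H) == 0 | !is.finite(rowSums(H))
  if (any(dead)) {
    warning("degenerate responsibilities for ", sum(dead),
            " row(s); uniform fallback")
    H[dead, ] <- 1
  }
  H / rowSums(H)
}

#' Predict from a fitted supervised Markov mixture of experts
#'
#' The ensemble prediction gates the experts by the posterior component
#' probabilities of the path under the Markov mixture (labels play no
#' role): `P(y = 1 | x) = sum_m p(m | x, theta) p(y = 1 | x, beta_m)`.
#'
#' @param object A fitted `hme3m` model.
#' @param newdata Pathway data tibble (edge columns; `y` not required).
#' @param type `"prob"` for `P(y = 1)`, `"class"` for 0/1 labels at the 0.5
#'   threshold, `"gate"` for the `N x M` gate posterior matrix.
#' @param ... Unused.
#' @return A numeric vector, or a matrix for `type = "gate"`.
#' @export
predict.hme3m <- function(object, newdata,
                          type = c("prob", "class", "gate"), ...) {
  type <- match.arg(type)
  X <- as_path_matrix(newdata, object$network)
  G <- suppressWarnings(posterior_component_probability(object$gate, X))
  if (type == "gate") {
    return(G)
  }
  X1 <- cbind(1, X)
  probs <- vapply(
    seq_len(object$M),
    function(m) clip01(sigmoid(drop(X1 %*% object$experts[[m]]$beta))),
    numeric(nrow(X))
  )
  p <- rowSums(G * matrix(probs, nrow = nrow(X)))
  if (type == "class") as.integer(p > 0.5) else p
}

#' Per-component expert scores for ROC analysis
#'
#' Returns the raw expert probability `p(y = 1 | x, beta_m)` for ranking
#' observations in a per-component ROC curve.  Set `gated = TRUE` to weight
#' the expert probability by the component's gate posterior instead.
#'
#' @param model A fitted `hme3m` model.
#' @param data Pathway data tibble.
#' @param m Component index.
#' @param gated Multiply by the gate posterior `p(m | x)` (default `FALSE`).
#' @return Numeric score vector.
#' @export
component_scores <- function(model, data, m, gated = FALSE) {
  stopifnot(inherits(model, "hme3m"))
  if (m < 1 || m > model$M) stop("component index out of range", call. = FALSE)
  X <- as_path_matrix(data, model$network)
  s <- drop(sigmoid(cbind(1, X) %*% model$experts[[m]]$beta))
  if (gated) {
    G <- suppressWarnings(posterior_component_probability(model$gate, X))
    s <- s * G[, m]
  }
  s
}

#' Report the dominant path of a component
#'
#' Lists the edges whose transition probability under component `m` meets
#' `threshold`, ordered by a topological sort of their source compounds so
#' the listing reads along the path direction.
#'
#' @param model A fitted `hme3m` model (or a [markov_mix()]).
#' @param m Component index.
#' @param threshold Minimum transition probability to report (default 0.5;
#'   0 reports every edge).
#' @return A tibble with columns `edge`, `source`, `target`, `gene`,
#'   `label`, `theta`.
#' @export
dominant_path_report <- function(model, m = 1, threshold = 0.5) {
  gate <- if (inherits(model, "hme3m")) model$gate else model
  stopifnot(inherits(gate, "markov_mix"))
  if (m < 1 || m > gate$M) stop("component index out of range", call. = FALSE)
  ed <- gate$network$edges
  ed$theta <- gate$theta[, m]
  ord <- topo_order(gate$network)
  ed <- ed[order(match(ed$source, ord), ed$edge), ]
  tibble::as_tibble(ed[ed$theta >= threshold,
                       c("edge", "source", "target", "gene", "label", "theta")])
}

# Kahn topological order; falls back to first-seen order on cyclic graphs.
topo_order <- function(network) {
  ed <- network$edges
  nodes <- network$nodes
  indeg <- table(factor(ed$target, levels = nodes))
  queue <- nodes[indeg == 0]
  ord <- character(0)
  indeg <- as.integer(indeg)
  names(indeg) <- nodes
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    ord <- c(ord, v)
    for (w in ed$target[ed$source == v]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L && !(w %in% ord) && !(w %in% queue)) {
        queue <- c(queue, w)
      }
    }
  }
  c(ord, setdiff(nodes, ord))
}

#' @export
print.hme3m <- function(x, ...) {
  cat("<hme3m> supervised Markov mixture of experts\n")
  cat("  M = ", x$M, ", P = ", x$P, " edges, N = ", x$n_obs, " paths\n",
      sep = "")
  cat("  logLik = ", format(x$logLik, digits = 7), " after ", x$n_iter,
      " EM iteration(s)", if (x$converged) " (converged)" else "", "\n",
      sep = "")
  cat("  pi:", format(sort(x$gate$pi, decreasing = TRUE), digits = 3), "\n")
  invisible(x)
}

#' Tidy a fitted supervised Markov mixture of experts
#'
#' @param x A fitted `hme3m` model.
#' @param what `"experts"` for one row per component and coefficient;
#'   `"gate"` for one row per component and edge with its transition
#'   probability.  Components are numbered in decreasing-prior order.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hme3m <- function(x, what = c("experts", "gate"), ...) {
  what <- match.arg(what)
  ord <- order(x$gate$pi, decreasing = TRUE)
  if (what == "experts") {
    purrr::map_dfr(seq_along(ord), function(k) {
      b <- x$experts[[ord[k]]]$beta
      tibble::tibble(component = k, pi = x$gate$pi[ord[k]],
                     term = names(b), estimate = unname(b))
    })
  } else {
    ed <- x$network$edges
    purrr::map_dfr(seq_along(ord), function(k) {
      tibble::tibble(
        component = k, pi = x$gate$pi[ord[k]], edge = ed$edge,
        source = ed$source, target = ed$target, gene = ed$gene,
        label = ed$label, theta = x$gate$theta[, ord[k]]
      )
    })
  }
}

#' One-row summary of a fitted model
#'
#' @param x A fitted `hme3m` model.
#' @param ... Unused.
#' @return A one-row tibble with the model size, fit configuration,
#'   log-likelihood and convergence state.
#' @export
glance.hme3m <- function(x, ...) {
  tibble::tibble(
    M = x$M, P = x$P, n_obs = x$n_obs,
    lambda = x$config$lambda %||% NA_real_,
    alpha = x$config$alpha %||% NA_real_,
    logLik = x$logLik, n_iter = x$n_iter, converged = x$converged
  )
}

#' Observed-data log-likelihood of a fitted model
#' @param object A fitted `hme3m` model.
#' @param ... Unused.
#' @return An object of class `logLik`.
#' @export
logLik.hme3m <- function(object, ...) {
  structure(object$logLik, df = length(object$gate$pi) - 1 +
              sum(lengths(lapply(object$experts, `[[`, "beta"))) +
              length(object$gate$theta),
            nobs = object$n_obs, class = "logLik")
}
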