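#' Fit a ridge-penalized logistic regression by damped IRLS
#'
#' Maximizes the observation-weighted logistic log-likelihood subject to a
#' ridge penalty `lambda/2 * |beta|^2` on the non-intercept coefficients,
#' using damped iteratively reweighted ridge regression: each iteration
#' moves `beta` a fraction `alpha` of the way to the solution of the
#' penalized weighted normal equations,
#' `beta <- beta + alpha * ((X'WX + Lambda)^-1 X'W z - beta)`,
#' with IRLS weights `W_ii = h_i * p_i * (1 - p_i)` combining the logistic
#' curvature with the supplied observation weights `h`, and `z` the working
#' response.  The damping factor `alpha` slows the experts' learning when
#' the fit is embedded in an EM loop, which keeps the outer likelihood from
#' oscillating; the fixed point is the same as undamped IRLS.
#'
#' @param data A data frame with a 0/1 response column `y` and binary
#'   predictor columns (a pathway dataset), or a plain numeric matrix when
#'   `y` is given.  Provenance columns starting with `.` are ignored.
#' @param y Response vector, required only when `data` is a matrix.
#' @param weights Nonnegative per-observation weights `h` (default all 1).
#' @param lambda Ridge penalty, `lambda >= 0`; values outside the
#'   conventional `[0, 2]` range are accepted with a warning.  The intercept
#'   is never penalized.
#' @param alpha Learning rate in `(0, 1]`.
#' @param max_iter,tol Iteration cap and sup-norm convergence tolerance on
#'   the damped step.
#' @param beta_init Optional warm-start coefficient vector
#'   (intercept first).
#'
#' @return An object of class `plr_fit`: coefficients `beta` (named,
#'   intercept first), `lambda`, `alpha`, `n_iter`, `converged`, and the
#'   penalized weighted log-likelihood `objective`.
#'
#' @examples
#' d <- tibble::tibble(a = c(0, 0, 1, 1), b = c(1, 0, 1, 0),
#'                     y = c(0, 0, 1, 1))
#' fit <- fit_plr(d, lambda = 0.5)
#' predict(fit, d)
#' @export
fit_plr <- function(data, y = NULL, weights = NULL, lambda = 1, alpha = 1,
                    max_iter = 50, tol = 1e-6, beta_init = NULL) {
  if (is.data.frame(data)) {
    if (!"y" %in% names(data)) {
      stop("`data` must contain a response column `y`", call. = FALSE)
    }
    y <- as.numeric(data$y)
    keep <- setdiff(names(data), "y")
    keep <- keep[!startsWith(keep, ".")]
    X <- as.matrix(data[keep])
  } else {
    X <- as.matrix(data)
    if (is.null(y)) stop("`y` is required with matrix input", call. = FALSE)
    y <- as.numeric(y)
  }
  storage.mode(X) <- "double"
  fit <- plr_irls(X, y, h = weights, lambda = lambda, alpha = alpha,
                  max_iter = max_iter, tol = tol, beta_init = beta_init)
  fit$terms <- colnames(X)
  fit
}

# Matrix-level workhorse; X has no intercept column.
plr_irls <- function(X, y, h = NULL, lambda = 1, alpha = 1, max_iter = 50,
                     tol = 1e-6, beta_init = NULL) {
  N <- nrow(X)
  P <- ncol(X)
  if (is.null(h)) h <- rep(1, N)
  h <- as.numeric(h)
  if (length(h) != N || any(h < 0)) {
    stop("weights must be nonnegative and of length nrow(X)", call. = FALSE)
  }
  if (all(h == 0)) stop("weights must not be all zero", call. = FALSE)
  if (lambda < 0) stop("lambda must be nonnegative", call. = FALSE)
  if (lambda > 2) {
    warning("lambda = ", lambda, " is outside the conventional [0, 2] range")
  }
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  X1 <- cbind(`(Intercept)` = 1, X)
  Ld <- c(0, rep(lambda, P)) # intercept unpenalized
  beta <- if (is.null(beta_init)) rep(0, P + 1) else as.numeric(beta_init)
  stopifnot(length(beta) == P + 1)
  eta <- drop(X1 %*% beta)
  obj <- weighted_loglik(eta, y, h) - lambda / 2 * sum(beta[-1]^2)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    p <- clip01(stats::plogis(eta))
    w <- h * p * (1 - p)
    grad <- drop(crossprod(X1, h * (y - p))) - Ld * beta
    Hm <- crossprod(X1, X1 * w)
    diag(Hm) <- diag(Hm) + Ld
    step <- tryCatch(
      solve(Hm, grad),
      error = function(e) {
        stop("penalized normal equations are singular; use lambda > 0 ",
             "for rank-deficient binary designs", call. = FALSE)
      }
    )
    # damped step, halved until the penalized objective does not decrease
    # (the logistic log-likelihood is concave but a Newton step can still
    # overshoot; backtracking keeps every update an ascent step, which the
    # surrounding EM relies on)
    dstep <- drop(X1 %*% step)
    scale <- alpha
    repeat {
      cand <- beta + scale * step
      eta_c <- eta + scale * dstep
      obj_c <- weighted_loglik(eta_c, y, h) - lambda / 2 * sum(cand[-1]^2)
      if (obj_c >= obj - 1e-12 || scale < alpha / 1024) break
      scale <- scale / 2
    }
    beta <- cand
    eta <- eta_c
    obj <- obj_c
    if (max(abs(scale * step)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!all(is.finite(beta))) {
    stop("PLR coefficients diverged; increase lambda or decrease alpha",
         call. = FALSE)
  }
  names(beta) <- colnames(X1)
  structure(
    list(
      beta = beta, lambda = lambda, alpha = alpha, n_iter = it,
      converged = converged, objective = obj
    ),
    class = "plr_fit"
  )
}

# Weighted Bernoulli log-likelihood, numerically stable for large |eta|:
# sum h * (y * eta - log(1 + exp(eta))).
weighted_loglik <- function(eta, y, h) {
  sum(h * (y * eta + stats::plogis(-eta, log.p = TRUE)))
}

# Weighted penalized log-likelihood of a coefficient vector (used by the
# ascent-property tests; the fitter tracks the same quantity incrementally).
plr_objective <- function(X1, y, h, beta, lambda) {
  weighted_loglik(drop(X1 %*% beta), y, h) - lambda / 2 * sum(beta[-1]^2)
}

#' Predicted success probabilities from a penalized logistic fit
#'
#' @param object A `plr_fit`.
#' @param newdata Data frame with the fit's predictor columns, or a numeric
#'   matrix in the same column order (no intercept column).
#' @param ... Unused.
#' @return Numeric vector of `P(y = 1)` in `(0, 1)`.
#' @export
predict.plr_fit <- function(object, newdata, ...) {
  X <- plr_design(object, newdata)
  drop(sigmoid(cbind(1, X) %*% object$beta))
}

plr_design <- function(object, newdata) {
  if (is.data.frame(newdata)) {
    terms <- object$terms %||% setdiff(names(object$beta), "(Intercept)")
    if (!all(terms %in% names(newdata))) {
      stop("newdata is missing predictor columns", call. = FALSE)
    }
    X <- as.matrix(newdata[terms])
  } else {
    X <- as.matrix(newdata)
  }
  storage.mode(X) <- "double"
  if (ncol(X) != length(object$beta) - 1) {
    stop("newdata has the wrong number of predictors", call. = FALSE)
  }
  X
}

#' @export
print.plr_fit <- function(x, ...) {
  cat("<plr_fit> lambda = ", x$lambda, ", alpha = ", x$alpha, ", ",
      x$n_iter, " iteration(s)",
      if (x$converged) " (converged)" else "", "\n", sep = "")
  print(x$beta, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.plr_fit <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta))
}

#' @importFrom generics glance
#' @export
glance.plr_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, alpha = x$alpha, n_iter = x$n_iter,
    converged = x$converged, objective = x$objective
  )
}
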