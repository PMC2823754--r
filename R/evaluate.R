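#' Correct classification rate
#'
#' @param y_true,y_pred 0/1 vectors of equal length.
#' @return Percentage of agreeing positions, in `[0, 100]`.
#' @export
ccr <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  100 * mean(y_true == y_pred)
}

#' Classifier specifications for cross-validation
#'
#' Lightweight descriptions of the classifiers compared in the benchmark,
#' all consuming the same binary pathway matrix.  Each spec bundles a label
#' with fit/predict closures so the cross-validation drivers can treat the
#' Markov mixture of experts, the standalone penalized logistic regression,
#' and the support-vector-machine baselines identically.
#'
#' @param M,lambda,alpha,n_restarts,... Model parameters; `...` is passed
#'   through to the underlying fit function ([fit_hme3m()], [fit_plr()] or
#'   [e1071::svm()]).
#' @param kernel SVM kernel: `"linear"`, `"polynomial"` (degree 3) or
#'   `"radial"`.
#' @return An object of class `path_classifier_spec`.
#' @name classifier_specs
NULL

#' @rdname classifier_specs
#' @export
hme3m_spec <- function(M = 2, lambda = 1, alpha = 0.5, n_restarts = 3, ...) {
  new_spec(
    label = sprintf("HME3M (M=%d)", M),
    fit = function(data, network, seed) {
      fit_hme3m(data, network, M = M, lambda = lambda, alpha = alpha,
                n_restarts = n_restarts, seed = seed, ...)
    },
    predict = function(fit, data, network) {
      predict(fit, data, type = "prob")
    }
  )
}

#' @rdname classifier_specs
#' @export
plr_spec <- function(lambda = 1, alpha = 1, ...) {
  new_spec(
    label = "PLR",
    fit = function(data, network, seed) {
      fit_plr(strip_provenance(data), lambda = lambda, alpha = alpha, ...)
    },
    predict = function(fit, data, network) {
      predict(fit, strip_provenance(data))
    }
  )
}

#' @rdname classifier_specs
#' @export
svm_spec <- function(kernel = c("linear", "polynomial", "radial"), ...) {
  kernel <- match.arg(kernel)
  label <- sprintf("SVM (%s)", kernel)
  new_spec(
    label = label,
    fit = function(data, network, seed) {
      d <- strip_provenance(data)
      X <- as.matrix(d[setdiff(names(d), "y")])
      with_seed(seed, e1071::svm(
        x = X, y = factor(d$y, levels = c(0, 1)), kernel = kernel,
        degree = 3, probability = TRUE, ...
      ))
    },
    predict = function(fit, data, network) {
      d <- strip_provenance(data)
      X <- as.matrix(d[setdiff(names(d), "y")])
      pr <- attr(
        predict(fit, X, probability = TRUE), "probabilities"
      )
      pr[, "1"]
    }
  )
}

new_spec <- function(label, fit, predict) {
  structure(list(label = label, fit = fit, predict = predict),
            class = "path_classifier_spec")
}

#' @export
print.path_classifier_spec <- function(x, ...) {
  cat("<path_classifier_spec>", x$label, "\n")
  invisible(x)
}

strip_provenance <- function(data) {
  data[!startsWith(names(data), ".")]
}

#' Stratified cross-validation fold assignments
#'
#' Assigns each observation to one of `folds` folds within each of `runs`
#' independent runs, stratifying by class so every fold preserves the class
#' balance, while keeping overall fold sizes within one of each other.
#'
#' @param y 0/1 response vector.
#' @param folds,runs Number of folds per run and number of runs.
#' @param seed Optional integer.
#' @return An `N x runs` integer matrix of fold labels.
#' @export
make_cv_folds <- function(y, folds = 10, runs = 10, seed = NULL) {
  N <- length(y)
  if (N < folds) stop("need at least `folds` observations", call. = FALSE)
  with_seed(seed, {
    sapply(seq_len(runs), function(r) {
      assign <- integer(N)
      offset <- 0L
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        assign[idx] <- ((offset + seq_along(idx) - 1L) %% folds) + 1L
        offset <- offset + length(idx)
      }
      assign
    })
  })
}

#' Repeated stratified k-fold cross-validation
#'
#' Runs `runs` independent rounds of `folds`-fold stratified
#' cross-validation of a classifier specification on a pathway dataset and
#' records the test-set correct classification rate of every fold.
#'
#' @param spec A [classifier_specs] object.
#' @param data Pathway dataset with edge columns and `y`.
#' @param network The [gene_network()] behind the edge columns.
#' @param folds,runs Cross-validation geometry (default 10 x 10).
#' @param seed Optional integer; fold assignment and every model fit derive
#'   from it.
#' @param fold_table Optional precomputed `N x runs` fold matrix (from
#'   [make_cv_folds()]) so competing models can be evaluated on identical
#'   partitions for paired testing.
#' @return An object of class `cv_result`; `tidy()` gives the per-fold
#'   CCRs, `glance()` the median and range.
#' @export
cross_validate <- function(spec, data, network, folds = 10, runs = 10,
                           seed = NULL, fold_table = NULL) {
  stopifnot(inherits(spec, "path_classifier_spec"))
  y <- data$y
  if (is.null(fold_table)) {
    fold_table <- make_cv_folds(y, folds, runs, seed = derive_seed(seed, 101))
  }
  runs <- ncol(fold_table)
  res <- purrr::map_dfr(seq_len(runs), function(r) {
    assign <- fold_table[, r]
    purrr::map_dfr(sort(unique(assign)), function(f) {
      test <- assign == f
      if (length(unique(y[!test])) < 2) {
        warning("training split lost a class in run ", r, " fold ", f)
      }
      fit <- spec$fit(data[!test, , drop = FALSE], network,
                      seed = derive_seed(seed, 1000 * r + f))
      p <- spec$predict(fit, data[test, , drop = FALSE], network)
      tibble::tibble(
        model = spec$label, run = r, fold = f,
        n_test = sum(test), ccr = ccr(y[test], as.integer(p > 0.5))
      )
    })
  })
  new_cv_result(res, spec$label, fold_table)
}

new_cv_result <- function(res, label, fold_table) {
  structure(
    list(results = res, label = label, fold_table = fold_table),
    class = "cv_result"
  )
}

#' Inverse k-fold cross-validation
#'
#' Splits the data into `folds` stratified groups and, for each group,
#' trains on that group alone and tests on the union of the remaining
#' groups — stressing generalization from small training sets.
#'
#' @inheritParams cross_validate
#' @return A `cv_result` with one CCR per training group.
#' @export
inverse_cross_validate <- function(spec, data, network, folds = 20,
                                   seed = NULL) {
  stopifnot(inherits(spec, "path_classifier_spec"))
  y <- data$y
  fold_table <- make_cv_folds(y, folds, runs = 1,
                              seed = derive_seed(seed, 101))
  assign <- fold_table[, 1]
  res <- purrr::map_dfr(sort(unique(assign)), function(f) {
    train <- assign == f
    fit <- spec$fit(data[train, , drop = FALSE], network,
                    seed = derive_seed(seed, 2000 + f))
    p <- spec$predict(fit, data[!train, , drop = FALSE], network)
    tibble::tibble(
      model = spec$label, run = 1L, fold = f, n_test = sum(!train),
      ccr = ccr(y[!train], as.integer(p > 0.5))
    )
  })
  new_cv_result(res, spec$label, fold_table)
}

#' @export
print.cv_result <- function(x, ...) {
  g <- glance(x)
  cat("<cv_result> ", x$label, ": median CCR ",
      format(g$median_ccr, digits = 4), "%, range ",
      format(g$ccr_range, digits = 3), " over ", g$n_folds, " fold(s)\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$results

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    model = x$label,
    median_ccr = stats::median(x$results$ccr),
    ccr_range = max(x$results$ccr) - min(x$results$ccr),
    mean_ccr = mean(x$results$ccr),
    n_folds = nrow(x$results)
  )
}

#' Paired comparison of per-fold classification rates
#'
#' Two-sided paired t-test of two per-fold CCR vectors produced under
#' identical fold assignments.  When the paired differences have zero
#' variance the test statistic is undefined; `p_value` is reported as 1
#' with `zero_variance = TRUE`.
#'
#' @param ccr_a,ccr_b Equal-length numeric vectors paired by fold.
#' @return One-row tibble: `statistic`, `p_value`, `mean_diff`,
#'   `significant` (at 0.05), `zero_variance`.
#' @export
paired_ccr_test <- function(ccr_a, ccr_b) {
  if (length(ccr_a) != length(ccr_b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  d <- ccr_a - ccr_b
  if (stats::sd(d) == 0) {
    return(tibble::tibble(
      statistic = 0, p_value = 1, mean_diff = mean(d),
      significant = FALSE, zero_variance = TRUE
    ))
  }
  tt <- stats::t.test(ccr_a, ccr_b, paired = TRUE)
  tibble::tibble(
    statistic = unname(tt$statistic), p_value = tt$p.value,
    mean_diff = mean(d), significant = tt$p.value < 0.05,
    zero_variance = FALSE
  )
}

#' Rank-based ROC curve and AUC
#'
#' Computes the area under the ROC curve as the normalized Mann-Whitney
#' statistic (ties counted half) together with the curve's
#' (false positive rate, true positive rate) points.
#'
#' @param y_true 0/1 labels containing both classes.
#' @param scores Numeric scores; larger means more class-1-like.
#' @return An object of class `roc_result` with elements `auc` and `curve`
#'   (a tibble with columns `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) {
    stop("labels and scores must have equal length", call. = FALSE)
  }
  if (length(unique(y_true)) < 2) {
    stop("ROC is undefined for single-class labels", call. = FALSE)
  }
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  r <- rank(scores) # average ranks handle ties
  auc <- (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- purrr::map_dfr(th, function(t) {
    tibble::tibble(
      threshold = t,
      fpr = sum(scores >= t & y_true == 0) / n0,
      tpr = sum(scores >= t & y_true == 1) / n1
    )
  })
  structure(list(auc = auc, curve = curve), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC =", format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Compare classifiers under identical fold assignments
#'
#' Evaluates several classifier specifications with shared stratified folds
#' (so per-fold CCRs are paired) and tests each against the first,
#' reference specification with [paired_ccr_test()].
#'
#' @param specs Named list of [classifier_specs]; the first is the
#'   reference.
#' @param data,network,folds,runs,seed As in [cross_validate()].
#' @return A list with `results` (long per-fold tibble), `summary` (one
#'   row per model: median, range, p-value vs the reference and a `*`
#'   marker at p < 0.05), and the individual `cv` objects.
#' @export
compare_classifiers <- function(specs, data, network, folds = 10, runs = 10,
                                seed = NULL) {
  stopifnot(length(specs) >= 1)
  fold_table <- make_cv_folds(data$y, folds, runs,
                              seed = derive_seed(seed, 101))
  cvs <- purrr::map(specs, function(s) {
    cross_validate(s, data, network, seed = seed, fold_table = fold_table)
  })
  ref <- cvs[[1]]$results$ccr
  summary <- purrr::imap_dfr(cvs, function(cv, nm) {
    g <- glance(cv)
    if (identical(cv$label, cvs[[1]]$label)) {
      g$p_value <- NA_real_
      g$flag <- ""
    } else {
      tt <- paired_ccr_test(ref, cv$results$ccr)
      g$p_value <- tt$p_value
      g$flag <- if (tt$significant) "*" else ""
    }
    g
  })
  list(
    results = purrr::map_dfr(cvs, tidy),
    summary = summary,
    cv = cvs
  )
}

#' Run the standard baseline panel
#'
#' Convenience wrapper running the supervised Markov mixture of experts
#' against the standalone penalized logistic regression and the linear,
#' polynomial (degree 3) and radial-kernel SVMs, all on the same binary
#' path matrix and identical folds.
#'
#' @param data,network,folds,runs,seed As in [cross_validate()].
#' @param M,lambda,alpha Mixture-of-experts parameters (benchmark defaults
#'   `M = 2`, `lambda = 1`, `alpha = 0.5`).
#' @return See [compare_classifiers()].
#' @export
run_baselines <- function(data, network, M = 2, lambda = 1, alpha = 0.5,
                          folds = 10, runs = 10, seed = NULL) {
  specs <- list(
    hme3m = hme3m_spec(M = M, lambda = lambda, alpha = alpha),
    plr = plr_spec(lambda = lambda),
    svm_linear = svm_spec("linear"),
    svm_polynomial = svm_spec("polynomial"),
    svm_radial = svm_spec("radial")
  )
  compare_classifiers(specs, data, network, folds, runs, seed)
}

#' Simulation benchmark grid driver
#'
#' Runs the full simulation benchmark: for every combination of network
#' size, noise fraction and model, simulates a fresh dataset (200 paths
#' per class by default), evaluates the model with repeated stratified
#' cross-validation, and returns the per-fold results in long format.
#'
#' @param sizes Character vector of network sizes.
#' @param noises Noise fractions.
#' @param specs Named list of model-spec factories taking no arguments, or
#'   ready [classifier_specs]; defaults to the full benchmark panel with
#'   `M` in `{2, 3}`.
#' @param n_per_class,folds,runs,seed,lambda,alpha Protocol parameters.
#' @return A list with `results` (tibble: graph, model, noise, run, fold,
#'   ccr) and `summary` (median and range per cell).
#' @export
simulation_grid <- function(sizes = c("small", "medium", "large"),
                            noises = c(0.1, 0.2, 0.3, 0.4, 0.5),
                            specs = NULL, n_per_class = 200, folds = 10,
                            runs = 10, seed = 1, lambda = 1, alpha = 0.5) {
  if (is.null(specs)) {
    specs <- list(
      `HME3M (M=2)` = hme3m_spec(M = 2, lambda = lambda, alpha = alpha),
      `HME3M (M=3)` = hme3m_spec(M = 3, lambda = lambda, alpha = alpha),
      PLR = plr_spec(lambda = lambda),
      `SVM (linear)` = svm_spec("linear"),
      `SVM (polynomial)` = svm_spec("polynomial"),
      `SVM (radial)` = svm_spec("radial")
    )
  }
  cells <- expand.grid(size = sizes, noise = noises,
                       stringsAsFactors = FALSE)
  results <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    size <- cells$size[i]
    noise <- cells$noise[i]
    net <- make_network(size)
    cell_seed <- derive_seed(seed, i)
    d <- simulate_pathways(net, n_per_class = n_per_class, noise = noise,
                           seed = cell_seed)
    cmp <- compare_classifiers(specs, d, net, folds = folds, runs = runs,
                               seed = cell_seed)
    dplyr::mutate(cmp$results, graph = size, noise = noise,
                  .before = 1)
  })
  summary <- results |>
    dplyr::group_by(.data$graph, .data$noise, .data$model) |>
    dplyr::summarise(
      median_ccr = stats::median(.data$ccr),
      ccr_range = max(.data$ccr) - min(.data$ccr),
      .groups = "drop"
    )
  list(results = results, summary = summary)
}
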