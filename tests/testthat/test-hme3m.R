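# Assemble a model object with prescribed gate and expert parameters.
manual_model <- function(net, pi, theta, betas) {
  experts <- lapply(betas, function(b) {
    names(b) <- c("(Intercept)", edge_labels(net))
    structure(list(beta = b, lambda = 1, alpha = 1,
                   terms = edge_labels(net)),
              class = "plr_fit")
  })
  structure(
    list(gate = markov_mix(net, pi, theta), experts = experts,
         network = net, M = length(pi), P = nrow(net$edges)),
    class = "hme3m"
  )
}

test_that("responsibilities follow Bayes rule over gate and experts", {
  net <- fig_network()
  theta <- cbind(
    c(0.9, 0.1, 1, 0.7, 0.3),
    c(0.2, 0.8, 1, 0.4, 0.6)
  )
  b1 <- c(0.5, 1, -1, 0.3, 0, 0.2)
  b2 <- c(-0.4, 0, 0.6, -0.2, 0.1, 0)
  model <- manual_model(net, c(0.35, 0.65), theta, list(b1, b2))
  d <- enumerate_paths(net)[c(1, 3, 2), ]
  d$y <- c(1, 0, 1)
  H <- e_step(model, d)
  expect_equal(rowSums(H), rep(1, 3), tolerance = 1e-12)
  X <- as.matrix(d[edge_labels(net)])
  for (i in 1:3) {
    num <- numeric(2)
    for (m in 1:2) {
      px <- component_path_probability(theta[, m], X[i, ])
      eta <- model$experts[[m]]$beta[1] +
        sum(model$experts[[m]]$beta[-1] * X[i, ])
      py <- if (d$y[i] == 1) 1 / (1 + exp(-eta)) else 1 / (1 + exp(eta))
      num[m] <- c(0.35, 0.65)[m] * px * py
    }
    expect_equal(unname(H[i, ]), num / sum(num), tolerance = 1e-12)
  }
  # M = 1 is a single all-ones column
  m1 <- manual_model(net, 1, theta[, 1, drop = FALSE], list(b1))
  expect_equal(drop(e_step(m1, d)), rep(1, 3))
  # identical components: rows equal the prior
  same <- manual_model(net, c(0.3, 0.7), cbind(theta[, 1], theta[, 1]),
                       list(b1, b1))
  Hs <- e_step(same, d)
  expect_equal(unname(Hs[2, ]), c(0.3, 0.7), tolerance = 1e-12)
})

test_that("gated predictions mix experts by the path posterior", {
  net <- fig_network()
  theta <- cbind(c(0.9, 0.1, 1, 0.7, 0.3), c(0.2, 0.8, 1, 0.4, 0.6))
  b1 <- c(0.5, 1, -1, 0.3, 0, 0.2)
  b2 <- c(-0.4, 0, 0.6, -0.2, 0.1, 0)
  model <- manual_model(net, c(0.35, 0.65), theta, list(b1, b2))
  d <- enumerate_paths(net)
  p <- predict(model, d)
  X <- as.matrix(d)
  for (i in seq_len(nrow(d))) {
    px <- c(component_path_probability(theta[, 1], X[i, ]),
            component_path_probability(theta[, 2], X[i, ]))
    gate <- c(0.35, 0.65) * px
    gate <- gate / sum(gate)
    pm <- vapply(1:2, function(m) {
      eta <- model$experts[[m]]$beta[1] +
        sum(model$experts[[m]]$beta[-1] * X[i, ])
      1 / (1 + exp(-eta))
    }, numeric(1))
    expect_equal(p[i], sum(gate * pm), tolerance = 1e-12)
  }
  expect_true(all(p > 0 & p < 1))
  # zero experts predict exactly one half everywhere
  zero <- manual_model(net, c(0.5, 0.5), theta, list(rep(0, 6), rep(0, 6)))
  expect_equal(predict(zero, d), rep(0.5, nrow(d)))
  expect_equal(predict(zero, d, type = "class"), rep(0L, nrow(d)))
  # gate posterior is returned on request
  G <- predict(model, d, type = "gate")
  expect_equal(rowSums(G), rep(1, nrow(d)), tolerance = 1e-12)
})

test_that("noise-free planted paths are recovered perfectly", {
  net <- make_network("small")
  d <- simulate_pathways(net, n_per_class = 60, noise = 0, seed = 4)
  dom <- attr(d, "dominant_paths")
  fit <- fit_hme3m(d, net, M = 2, seed = 1)
  p <- predict(fit, d, type = "class")
  expect_equal(ccr(d$y, p), 100)
  # the recovered transition mass sits on the generating edges: every row
  # of the data is one of the four planted paths, so each component's
  # probability mass over those paths must be (near) exhaustive
  labs <- edge_labels(net)
  for (m in 1:2) {
    tot <- sum(vapply(1:4, function(k) {
      component_path_probability(fit$gate$theta[, m],
                                 as.numeric(dom[k, labs]))
    }, numeric(1)))
    expect_gt(tot, 0.99)
  }
})

test_that("a single-component model degenerates to weighted PLR", {
  net <- make_network("small")
  d <- simulate_pathways(net, n_per_class = 50, noise = 0.2, seed = 2)
  f1 <- fit_hme3m(d, net, M = 1, lambda = 1, alpha = 0.5, seed = 1,
                  em_tol = 1e-12, max_em_iter = 3000)
  fp <- fit_plr(d[c(edge_labels(net), "y")], lambda = 1, alpha = 0.5,
                max_iter = 5000, tol = 1e-12)
  expect_equal(predict(f1, d), predict(fp, d), tolerance = 1e-6)
})

test_that("the EM objective trace is monotone and convergence is flagged", {
  net <- make_network("small")
  d <- simulate_pathways(net, n_per_class = 50, noise = 0.3, seed = 6)
  fit <- fit_hme3m(d, net, M = 2, seed = 3)
  expect_true(all(diff(fit$trace) > -1e-8))
  expect_equal(length(fit$trace), fit$n_iter)
  expect_equal(length(fit$ll_trace), fit$n_iter)
  # the raw likelihood differs from the objective by the ridge penalty
  pen <- 0.5 * sum(vapply(fit$experts,
                          function(e) sum(e$beta[-1]^2), numeric(1)))
  expect_equal(fit$objective, fit$logLik - pen, tolerance = 1e-10)
})

test_that("relabeling the response flips predictions exactly", {
  net <- make_network("small")
  d <- simulate_pathways(net, n_per_class = 40, noise = 0.25, seed = 8)
  d2 <- d
  d2$y <- 1 - d$y
  f <- fit_hme3m(d, net, M = 2, seed = 5, n_restarts = 1)
  f2 <- fit_hme3m(d2, net, M = 2, seed = 5, n_restarts = 1)
  expect_equal(predict(f2, d), 1 - predict(f, d), tolerance = 1e-8)
})

test_that("component scores are the raw expert probabilities", {
  net <- make_network("small")
  d <- simulate_pathways(net, n_per_class = 40, noise = 0.2, seed = 9)
  fit <- fit_hme3m(d, net, M = 2, seed = 2)
  X1 <- cbind(1, as.matrix(d[edge_labels(net)]))
  for (m in 1:2) {
    s <- component_scores(fit, d, m)
    expect_equal(s, drop(1 / (1 + exp(-X1 %*% fit$experts[[m]]$beta))),
                 tolerance = 1e-12)
  }
  gated <- component_scores(fit, d, 1, gated = TRUE)
  G <- predict(fit, d, type = "gate")
  expect_equal(gated, component_scores(fit, d, 1) * G[, 1],
               tolerance = 1e-12)
  expect_error(component_scores(fit, d, 3), "out of range")
  # a constant expert ranks nothing: AUC is exactly one half
  zero <- manual_model(net, 1, mixture_m_step(
    enumerate_paths(net),
    matrix(1, count_paths(net), 1), net
  )$theta, list(rep(0, nrow(net$edges) + 1)))
  r <- roc_auc(d$y, component_scores(zero, d, 1))
  expect_equal(r$auc, 0.5)
})

test_that("the dominant-path report lists high-probability edges in order", {
  net <- make_network("small")
  labs <- edge_labels(net)
  # two planted chains crossing at L2N1 (see the recovery test for why
  # crossing matters for identifiability)
  x1 <- as.numeric(seq_len(12) %in% c(1, 3, 7, 11))
  x2 <- as.numeric(seq_len(12) %in% c(2, 5, 8, 12))
  dom <- tibble::as_tibble(rbind(x1, x2), .name_repair = ~labs)
  d <- dom[rep(1:2, each = 60), ]
  fit <- fit_markov_mixture(d, net, M = 2, seed = 1)$params
  # match each planted path to its component; at a high threshold the
  # report must contain the path's edges, and at compounds offering a
  # choice it must contain nothing else (single-exit compounds always
  # carry probability 1, whether or not the path visits them)
  out_degree <- table(net$edges$source)
  for (k in 1:2) {
    x <- as.numeric(dom[k, labs])
    m <- which.max(apply(fit$theta, 2, component_path_probability,
                         x = x))
    rep_k <- dominant_path_report(fit, m, threshold = 0.9)
    expect_true(all(which(x == 1) %in% rep_k$edge))
    branching <- rep_k$edge[out_degree[rep_k$source] > 1]
    expect_setequal(branching, intersect(which(x == 1),
                                         which(out_degree[net$edges$source] > 1)))
    # edges are listed along the traversal direction
    ord <- match(rep_k$source, c("S", "L1N1", "L1N2", "L2N1", "L2N2",
                                 "L3N1", "L3N2", "E"))
    expect_true(all(diff(ord) >= 0))
  }
  expect_equal(nrow(dominant_path_report(fit, 1, threshold = 0)),
               nrow(net$edges))
  expect_error(dominant_path_report(fit, 5), "out of range")
})

test_that("model configuration is validated", {
  net <- make_network("small")
  d <- simulate_pathways(net, n_per_class = 10, noise = 0, seed = 1)
  expect_error(fit_hme3m(d, net, M = 0), "1 <= M")
  expect_error(fit_hme3m(d, net, M = 1000), "1 <= M")
  expect_error(fit_hme3m(d[edge_labels(net)], net, M = 2), "response")
})

test_that("tidy and glance summarize a fit in decreasing-prior order", {
  net <- make_network("small")
  d <- simulate_pathways(net, n_per_class = 40, noise = 0.2, seed = 3)
  fit <- fit_hme3m(d, net, M = 2, seed = 1)
  te <- tidy(fit, what = "experts")
  expect_equal(nrow(te), 2 * (nrow(net$edges) + 1))
  tg <- tidy(fit, what = "gate")
  expect_equal(nrow(tg), 2 * nrow(net$edges))
  expect_true(all(diff(unique(tg$pi)) <= 0))
  g <- glance(fit)
  expect_equal(g$M, 2)
  expect_equal(g$lambda, 1)
  expect_true(g$logLik <= 0)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_likelihood_trace(fit), "ggplot")
})
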