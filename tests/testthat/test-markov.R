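# Build a valid parameter set for a network by running the M-step on
# random responsibilities over the full path set.
random_markov_params <- function(net, M, seed) {
  X <- enumerate_paths(net)
  set.seed(seed)
  H <- matrix(stats::rgamma(nrow(X) * M, 1), nrow(X), M)
  H <- H / rowSums(H)
  mixture_m_step(X, H, net)
}

test_that("component path probability is the product over traversed edges", {
  theta <- c(1, 1, 1, 1, 1)
  expect_equal(component_path_probability(theta, c(1, 0, 1, 1, 0)), 1)
  theta2 <- c(1, 1, 0, 1, 1)
  expect_equal(component_path_probability(theta2, c(1, 0, 1, 1, 0)), 0)
  # two-branch first hop at 0.5/0.5, deterministic second hop
  net <- gene_network(
    data.frame(source = c("A", "A", "B", "C"), target = c("B", "C", "D", "D"),
               gene = c("g1", "g2", "g3", "g4")), "A", "D"
  )
  expect_equal(
    component_path_probability(c(0.5, 0.5, 1, 1), c(1, 0, 1, 0)), 0.5
  )
  # hand product on arbitrary values
  th <- c(0.3, 0.7, 0.2, 0.9, 1)
  expect_equal(component_path_probability(th, c(0, 1, 0, 1, 0)), 0.7 * 0.9)
})

test_that("each component's distribution sums to 1 over all paths", {
  for (spec in list("small", c(2, 3), c(3, 2, 2))) {
    net <- make_network(spec)
    params <- random_markov_params(net, M = 3, seed = 7)
    X <- enumerate_paths(net)
    for (m in 1:3) {
      tot <- sum(vapply(seq_len(nrow(X)), function(i) {
        component_path_probability(params$theta[, m], as.numeric(X[i, ]))
      }, numeric(1)))
      expect_equal(tot, 1, tolerance = 1e-10)
    }
    # and therefore the mixture sums to 1 too
    mix <- sum(vapply(seq_len(nrow(X)), function(i) {
      mixture_path_probability(params, as.numeric(X[i, ]))
    }, numeric(1)))
    expect_equal(mix, 1, tolerance = 1e-10)
  }
})

test_that("mixture probability degenerates correctly", {
  net <- make_network("small")
  p1 <- random_markov_params(net, M = 1, seed = 3)
  x <- as.numeric(enumerate_paths(net)[2, ])
  expect_equal(mixture_path_probability(p1, x),
               component_path_probability(p1$theta[, 1], x))
  # two identical components under any prior equal the single component
  p2 <- markov_mix(net, c(0.3, 0.7), cbind(p1$theta, p1$theta))
  expect_equal(mixture_path_probability(p2, x),
               mixture_path_probability(p1, x))
})

test_that("posterior memberships follow Bayes rule", {
  net <- make_network("small")
  params <- random_markov_params(net, M = 2, seed = 11)
  X <- enumerate_paths(net)
  H <- posterior_component_probability(params, X)
  expect_equal(rowSums(H), rep(1, nrow(X)), tolerance = 1e-12)
  for (i in seq_len(nrow(X))) {
    x <- as.numeric(X[i, ])
    num <- params$pi * c(
      component_path_probability(params$theta[, 1], x),
      component_path_probability(params$theta[, 2], x)
    )
    expect_equal(unname(H[i, ]), num / sum(num), tolerance = 1e-12)
  }
  # M = 1: membership is always certain
  p1 <- random_markov_params(net, M = 1, seed = 5)
  expect_equal(drop(posterior_component_probability(p1, X)),
               rep(1, nrow(X)))
  # symmetric components: membership mirrors the prior
  p2 <- markov_mix(net, c(0.4, 0.6),
                   cbind(p1$theta, p1$theta))
  H2 <- posterior_component_probability(p2, X)
  expect_equal(unname(H2[1, ]), c(0.4, 0.6), tolerance = 1e-12)
})

test_that("the M-step reproduces hand-normalized weighted counts", {
  net <- fig_network()
  X <- rbind(
    c(1, 0, 1, 1, 0), # A-B-C-D via e4
    c(1, 0, 1, 1, 0),
    c(0, 1, 0, 1, 0), # A-C-D via e4
    c(0, 1, 0, 0, 1)  # A-C-D via e5
  )
  H <- rbind(c(1, 0), c(0.5, 0.5), c(0.2, 0.8), c(0, 1))
  fit <- mixture_m_step(X, H, net, eps = 0)
  expect_equal(fit$pi, colMeans(H))
  # component 1: A out-edges e1 gets 1.5, e2 gets 0.2 -> 0.882/0.118
  expect_equal(fit$theta[1, 1], 1.5 / 1.7, tolerance = 1e-12)
  expect_equal(fit$theta[2, 1], 0.2 / 1.7, tolerance = 1e-12)
  # component 2: C out-edges e4 = 0.5 + 0.8, e5 = 1 -> 1.3/2.3, 1/2.3
  expect_equal(fit$theta[4, 2], 1.3 / 2.3, tolerance = 1e-12)
  expect_equal(fit$theta[5, 2], 1 / 2.3, tolerance = 1e-12)
  # all mass on one component with a single repeated path: that component
  # concentrates on the path's edges (up to the smoothing pseudocount)
  H1 <- cbind(rep(1, 2), rep(0, 2))
  f1 <- mixture_m_step(X[1:2, ], H1, net)
  expect_equal(f1$theta[c(1, 3, 4), 1], c(1, 1, 1), tolerance = 1e-5)
  expect_equal(f1$theta[c(2, 5), 1], c(0, 0), tolerance = 1e-5)
  # uniform responsibilities make identical components
  Hu <- matrix(0.5, 4, 2)
  fu <- mixture_m_step(X, Hu, net)
  expect_equal(fu$theta[, 1], fu$theta[, 2])
})

test_that("M-step output always satisfies the mixture invariants", {
  net <- make_network("medium")
  X <- enumerate_paths(net)
  groups <- split(net$edges$edge, net$edges$source)
  for (s in 1:20) {
    set.seed(s)
    H <- matrix(stats::rgamma(nrow(X) * 2, 1), nrow(X), 2)
    H <- H / rowSums(H)
    params <- mixture_m_step(X[sample(nrow(X), 15, replace = TRUE), ],
                             H[sample(nrow(X), 15, replace = TRUE), ], net)
    expect_equal(sum(params$pi), 1, tolerance = 1e-10)
    expect_true(all(params$theta >= 0))
    for (g in groups) {
      expect_equal(unname(colSums(params$theta[g, , drop = FALSE])),
                   c(1, 1), tolerance = 1e-10)
    }
  }
})

test_that("responsibility rows must sum to one", {
  net <- fig_network()
  X <- enumerate_paths(net)
  H_bad <- matrix(1, nrow(X), 2)
  expect_error(mixture_m_step(X, H_bad, net), "sum to 1")
})

test_that("unsupervised EM increases the likelihood and recovers chains", {
  net <- make_network("small")
  labs <- edge_labels(net)
  # two generating chains crossing at a shared compound (L2N1): a single
  # Markov chain cannot represent their 60/40 mixture without leaking
  # probability onto crossover paths, so the two-component fit is
  # identifiable and must separate them
  x1 <- as.numeric(seq_len(12) %in% c(1, 3, 7, 11))
  x2 <- as.numeric(seq_len(12) %in% c(2, 5, 8, 12))
  dom <- tibble::as_tibble(rbind(x1, x2), .name_repair = ~labs)
  X <- dom[rep(1:2, c(60, 40)), ]
  fit <- fit_markov_mixture(X, net, M = 2, seed = 1)
  expect_true(all(diff(fit$trace) > -1e-8))
  expect_true(fit$converged)
  # posterior cleanly separates the two generating paths
  expect_equal(dim(fit$H), c(100, 2))
  # match components to generating paths and check recovery
  x1 <- as.numeric(dom[1, labs])
  x2 <- as.numeric(dom[2, labs])
  m1 <- which.max(apply(fit$params$theta, 2, component_path_probability,
                        x = x1))
  m2 <- setdiff(1:2, m1)
  expect_gt(min(fit$params$theta[x1 == 1, m1]), 0.99)
  expect_gt(min(fit$params$theta[x2 == 1, m2]), 0.99)
  # mixing proportions reflect the 60/40 split
  expect_equal(sort(fit$params$pi), c(0.4, 0.6), tolerance = 0.02)
  # correlation with the generating one-hot transition structure,
  # restricted to edges leaving compounds the generating chains visit
  # (transitions out of unvisited compounds are unidentified)
  fitted <- fit$params$theta[, c(m1, m2)]
  gen_vec <- numeric(0)
  fit_vec <- numeric(0)
  for (k in 1:2) {
    x <- list(x1, x2)[[k]]
    keep <- net$edges$source %in% net$edges$source[x == 1]
    gen_vec <- c(gen_vec, x[keep])
    fit_vec <- c(fit_vec, fitted[keep, k])
  }
  expect_gt(stats::cor(gen_vec, fit_vec), 0.95)
})
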