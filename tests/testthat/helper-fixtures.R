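# Shared fixtures: the worked 4-node example network, an independent
# path-enumeration oracle built on igraph, and random DAG generators.

# Four compounds A-D, five gene-labeled edges (two parallel C->D edges),
# four simple A->D paths; the path traversing edges 1, 3, 4 has binary
# representation [1, 0, 1, 1, 0].
fig_network <- function() {
  gene_network(
    data.frame(
      source = c("A", "A", "B", "C", "C"),
      target = c("B", "C", "C", "D", "D"),
      gene   = c("g1", "g2", "g3", "g4", "g5")
    ),
    start = "A", end = "D"
  )
}

# Canonical key of a binary path row: sorted traversed edge indices.
path_key <- function(X) {
  apply(as.matrix(X), 1L, function(r) paste(which(r == 1), collapse = "-"))
}

# Independent enumeration oracle: igraph::all_simple_paths on the collapsed
# node graph, then expansion over parallel active edges per hop.  Returns
# the set of path keys.
oracle_path_set <- function(network, active_edges = NULL) {
  skip_if_not_installed("igraph")
  ed <- network$edges
  if (is.null(active_edges)) active_edges <- ed$edge
  ed <- ed[ed$edge %in% active_edges, , drop = FALSE]
  if (nrow(ed) == 0) {
    return(character(0))
  }
  g <- igraph::graph_from_data_frame(
    unique(ed[, c("source", "target")]), directed = TRUE,
    vertices = data.frame(name = network$nodes)
  )
  nps <- igraph::all_simple_paths(g, from = network$start,
                                  to = network$end, mode = "out")
  keys <- character(0)
  for (np in nps) {
    nodes <- names(np)
    hop_edges <- lapply(seq_len(length(nodes) - 1), function(i) {
      ed$edge[ed$source == nodes[i] & ed$target == nodes[i + 1]]
    })
    combos <- expand.grid(hop_edges)
    keys <- c(keys, apply(combos, 1L, function(r) {
      paste(sort(as.integer(r)), collapse = "-")
    }))
  }
  sort(unique(keys))
}

# Random DAG over at most `n` topologically ordered nodes, with occasional
# parallel edges; node 1 is the start, node n the end.
random_dag <- function(n = 8, p = 0.35, seed = 1) {
  set.seed(seed)
  src <- character(0)
  tgt <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      k <- stats::rbinom(1, 2, p / 2) # 0, 1 or 2 parallel edges
      if (i == 1 && j == 2) k <- max(k, 1L)
      if (i == n - 1 && j == n) k <- max(k, 1L)
      if (k > 0) {
        src <- c(src, rep(paste0("n", i), k))
        tgt <- c(tgt, rep(paste0("n", j), k))
      }
    }
  }
  gene_network(
    data.frame(source = src, target = tgt,
               gene = sprintf("g%02d", seq_along(src))),
    start = "n1", end = paste0("n", n)
  )
}

# Small labeled expression fixture consistent with fig_network(): 5 genes,
# 6 samples, clear over/under-expression structure.
fig_expression <- function() {
  set.seed(404)
  genes <- c("g1", "g2", "g3", "g4", "g5")
  vals <- matrix(stats::rnorm(30, mean = 5), nrow = 5,
                 dimnames = list(NULL, paste0("s", 1:6)))
  vals[1, 1:3] <- vals[1, 1:3] + 4 # g1 over-expressed in s1-s3
  vals[2, 4:6] <- vals[2, 4:6] + 4 # g2 over-expressed in s4-s6
  vals[4, ] <- vals[4, ] + c(3, 3, 3, 3, -3, -3)
  dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(vals))
}

fig_labels <- function() {
  tibble::tibble(sample = paste0("s", 1:6), label = c(0, 0, 0, 1, 1, 1))
}
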