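#' Construct a gene-labeled directed network
#'
#' A `gene_network` represents a directed (multi)graph of metabolic compounds
#' whose edges are labeled by the genes catalyzing the corresponding
#' reactions, together with a designated start and end compound.  The order
#' of the rows of `edges` is fixed at construction and defines the
#' coordinates of every binary path vector: coordinate `t` of a path is 1
#' exactly when the path traverses the `t`-th edge.  Parallel edges between
#' the same pair of compounds (one per catalyzing gene) are permitted and are
#' distinct coordinates.
#'
#' @param edges A data frame with columns `source`, `target` and `gene`
#'   (character).  Row order is preserved and defines edge indices `1..P`.
#' @param start,end Node identifiers; every enumerated path runs from
#'   `start` to `end`.
#'
#' @return An object of class `gene_network`: a list with elements `edges`
#'   (a tibble with columns `edge`, `source`, `target`, `gene`, `label`),
#'   `nodes`, `start` and `end`.  `label` is the unique column name used for
#'   this coordinate in pathway data (`"e<index>_<gene>"`).
#'
#' @examples
#' net <- gene_network(
#'   data.frame(
#'     source = c("A", "A", "B", "C", "C"),
#'     target = c("B", "C", "C", "D", "D"),
#'     gene   = c("g1", "g2", "g3", "g4", "g5")
#'   ),
#'   start = "A", end = "D"
#' )
#' count_paths(net)
#' @export
gene_network <- function(edges, start, end) {
  stopifnot(is.data.frame(edges))
  need <- c("source", "target", "gene")
  if (!all(need %in% names(edges))) {
    stop("`edges` must have columns source, target and gene.", call. = FALSE)
  }
  edges <- tibble::as_tibble(edges[need])
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$gene <- as.character(edges$gene)
  if (nrow(edges) == 0L) stop("network has no edges", call. = FALSE)
  if (anyDuplicated(edges$gene)) {
    # distinct coordinates may share a catalyzing gene; labels stay unique
    # because they carry the edge index.
    message("duplicated gene labels present; coordinates remain distinct edges")
  }
  nodes <- unique(c(edges$source, edges$target))
  if (!start %in% nodes || !end %in% nodes) {
    stop("start and end must be nodes of the network", call. = FALSE)
  }
  edges$edge <- seq_len(nrow(edges))
  edges$label <- sprintf("e%02d_%s", edges$edge, edges$gene)
  structure(
    list(
      edges = edges[, c("edge", "source", "target", "gene", "label")],
      nodes = nodes,
      start = as.character(start),
      end = as.character(end)
    ),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat(
    "<gene_network> ", length(x$nodes), " compounds, ", nrow(x$edges),
    " gene-labeled edges, ", x$start, " -> ", x$end, "\n",
    sep = ""
  )
  print(x$edges, ...)
  invisible(x)
}

#' Coordinate labels of a network's edges
#'
#' @param network A [gene_network()].
#' @return Character vector of length `P` naming the path-vector coordinates.
#' @export
edge_labels <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  network$edges$label
}

# Adjacency list: for each node, the indices of its out-edges in edge order.
out_edge_index <- function(network) {
  split(network$edges$edge, factor(network$edges$source, levels = network$nodes))
}

#' Enumerate simple start-to-end paths
#'
#' Performs an exhaustive depth-first enumeration of every simple directed
#' path (no repeated compound) from the network's start node to its end node
#' that uses only the given active edges.  Paths are returned in
#' lexicographic order of their edge-index sequences.
#'
#' @param network A [gene_network()].
#' @param active_edges Integer vector of edge indices that may be traversed;
#'   `NULL` (default) activates every edge.
#'
#' @return A tibble with one row per path and one 0/1 column per network
#'   edge, named by [edge_labels()].  Zero rows when no path exists.
#' @export
enumerate_paths <- function(network, active_edges = NULL) {
  seqs <- path_edge_sequences(network, active_edges)
  P <- nrow(network$edges)
  X <- matrix(0L, nrow = length(seqs), ncol = P,
              dimnames = list(NULL, edge_labels(network)))
  for (i in seq_along(seqs)) X[i, seqs[[i]]] <- 1L
  tibble::as_tibble(X)
}

# Core DFS shared by enumeration and counting.  Returns a list of integer
# edge-index sequences, lexicographically ordered because out-edges are
# explored in increasing index order.
path_edge_sequences <- function(network, active_edges = NULL) {
  stopifnot(inherits(network, "gene_network"))
  P <- nrow(network$edges)
  active <- rep(FALSE, P)
  if (is.null(active_edges)) {
    active[] <- TRUE
  } else {
    active_edges <- as.integer(active_edges)
    if (length(active_edges) > 0 &&
        (min(active_edges) < 1L || max(active_edges) > P)) {
      stop("active_edges out of range", call. = FALSE)
    }
    active[active_edges] <- TRUE
  }
  adj <- out_edge_index(network)
  target <- network$edges$target
  found <- list()
  visited <- character(0)
  walk <- function(node, trail) {
    if (node == network$end) {
      found[[length(found) + 1L]] <<- trail
      return(invisible(NULL))
    }
    visited <<- c(visited, node)
    for (e in adj[[node]]) {
      if (active[e] && !(target[e] %in% visited)) {
        walk(target[e], c(trail, e))
      }
    }
    visited <<- visited[-length(visited)]
    invisible(NULL)
  }
  # the end node may not be re-entered mid-path; simple paths stop there
  walk(network$start, integer(0))
  found
}

#' Count simple start-to-end paths
#'
#' @param network A [gene_network()].
#' @return The number of simple directed paths from start to end with all
#'   edges active; equals `nrow(enumerate_paths(network))`.
#' @export
count_paths <- function(network) {
  length(path_edge_sequences(network))
}

#' Replay a binary path vector against its network
#'
#' Checks that a 0/1 vector encodes a connected simple walk from the
#' network's start to its end node: starting at `start`, exactly one marked
#' out-edge must leave every visited node until `end` is reached, every
#' marked edge must be used, and no compound may be revisited.
#'
#' @param network A [gene_network()].
#' @param x Numeric/integer 0/1 vector of length `P`, ordered as
#'   [edge_labels()].
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_path <- function(network, x) {
  P <- nrow(network$edges)
  if (length(x) != P || !all(x %in% c(0, 1))) {
    return(FALSE)
  }
  sel <- which(x == 1)
  if (length(sel) == 0L) {
    return(FALSE)
  }
  node <- network$start
  seen <- character(0)
  used <- integer(0)
  src <- network$edges$source
  tgt <- network$edges$target
  while (node != network$end) {
    if (node %in% seen) {
      return(FALSE)
    }
    seen <- c(seen, node)
    out <- sel[src[sel] == node]
    if (length(out) != 1L) {
      return(FALSE)
    }
    used <- c(used, out)
    node <- tgt[out]
  }
  setequal(used, sel)
}

#' Z-score and threshold a gene-expression matrix into binary activity
#'
#' Each gene's values are standardized across samples to mean 0 and standard
#' deviation 1; an observation is called active (1) when its z-score is
#' strictly above `tolerance`, otherwise inactive (0).  Genes with zero
#' variance cannot be standardized and are set inactive everywhere with a
#' warning.
#'
#' @param expr A data frame whose first column (`gene`) holds gene
#'   identifiers and whose remaining columns hold one numeric expression
#'   value per sample.
#' @param tolerance Activity threshold on the z-score scale (the values used
#'   with real microarray data are small, e.g. -0.1, 0, 0.1).
#'
#' @return A tibble of the same shape as `expr` with 0/1 activity calls.
#' @export
binarize_expression <- function(expr, tolerance = 0) {
  stopifnot(is.data.frame(expr), ncol(expr) >= 3)
  gene <- as.character(expr[[1]])
  vals <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  mu <- rowMeans(vals)
  sdv <- apply(vals, 1L, stats::sd)
  flat <- sdv == 0 | is.na(sdv)
  if (any(flat)) {
    warning(
      "zero-variance gene(s) set inactive everywhere: ",
      paste(gene[flat], collapse = ", ")
    )
    sdv[flat] <- 1
  }
  z <- (vals - mu) / sdv
  act <- (z > tolerance) * 1L
  act[flat, ] <- 0L
  out <- tibble::as_tibble(as.data.frame(act))
  dplyr::bind_cols(tibble::tibble(gene = gene), out)
}

#' Extract labeled binary pathway observations from expression data
#'
#' Turns each expression sample into a set of binary path observations: the
#' sample's expression is binarized ([binarize_expression()]), a network
#' edge is active when its catalyzing gene is active, every simple
#' start-to-end path through the active edges is enumerated, and each
#' resulting path is labeled with the sample's response.  Samples yielding
#' no path are skipped with a warning.
#'
#' @param network A [gene_network()]; every gene labeling an edge must
#'   appear exactly once in `expr`.
#' @param expr Expression data frame (first column `gene`, then samples).
#' @param labels A data frame with columns `sample` and `label` (0/1), one
#'   row per expression sample column.
#' @param tolerance Z-score activity threshold passed to
#'   [binarize_expression()].
#'
#' @return A pathway dataset: a tibble with one 0/1 column per network edge
#'   (named by [edge_labels()]), a response column `y`, and a provenance
#'   column `.sample`.
#' @export
build_pathway_dataset <- function(network, expr, labels, tolerance = 0) {
  stopifnot(inherits(network, "gene_network"))
  genes <- as.character(expr[[1]])
  missing <- setdiff(unique(network$edges$gene), genes)
  if (length(missing) > 0) {
    stop(
      "network gene(s) absent from expression data: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(genes[genes %in% network$edges$gene])) {
    stop("network genes must appear exactly once in `expr`", call. = FALSE)
  }
  stopifnot(all(c("sample", "label") %in% names(labels)))
  samples <- setdiff(names(expr), names(expr)[1])
  lab <- labels$label[match(samples, as.character(labels$sample))]
  if (anyNA(lab)) {
    stop("every expression sample needs a row in `labels`", call. = FALSE)
  }
  if (!all(lab %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)

  act <- binarize_expression(expr, tolerance)
  blocks <- vector("list", length(samples))
  for (j in seq_along(samples)) {
    gene_on <- act[[samples[j]]] == 1L
    on_genes <- genes[gene_on]
    active <- network$edges$edge[network$edges$gene %in% on_genes]
    paths <- enumerate_paths(network, active)
    if (nrow(paths) == 0L) {
      warning("sample ", samples[j], " yields no start-to-end path; skipped")
      next
    }
    paths$y <- lab[j]
    paths$.sample <- samples[j]
    blocks[[j]] <- paths
  }
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  if (length(blocks) == 0L) {
    out <- enumerate_paths(network, integer(0))
    out$y <- integer(0)
    out$.sample <- character(0)
    return(out)
  }
  dplyr::bind_rows(blocks)
}

# Split a pathway dataset into the numeric X matrix (edge columns in network
# order) and the response vector; shared by the model-fitting code.
pathway_matrix <- function(data, network, require_y = TRUE) {
  labs <- edge_labels(network)
  if (!all(labs %in% names(data))) {
    stop("data is missing edge columns for this network", call. = FALSE)
  }
  X <- as.matrix(data[labs])
  storage.mode(X) <- "double"
  if (!all(X %in% c(0, 1))) {
    stop("pathway columns must be binary 0/1", call. = FALSE)
  }
  y <- NULL
  if ("y" %in% names(data)) {
    y <- as.numeric(data$y)
    if (!all(y %in% c(0, 1))) stop("response `y` must be 0/1", call. = FALSE)
  } else if (require_y) {
    stop("data must contain a 0/1 response column `y`", call. = FALSE)
  }
  list(X = X, y = y)
}
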