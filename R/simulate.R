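#' Build a layered benchmark network
#'
#' Constructs the layered directed networks used by the simulation
#' benchmark: a single start compound feeds every node of the first
#' intermediate layer, consecutive layers are fully connected, and the last
#' layer feeds a single end compound.  Each edge carries its own gene
#' label, so the number of simple start-to-end paths is the product of the
#' layer widths.
#'
#' @param size `"small"` (3 layers of 2 nodes, 8 paths), `"medium"` (3 x 3,
#'   27 paths), `"large"` (3 x 4, 64 paths), or an integer vector of layer
#'   widths.
#' @return A [gene_network()].  Networks with fewer than 4 distinct paths
#'   (too few to plant two dominant paths per class) are rejected.
#' @export
make_network <- function(size = c("small", "medium", "large")) {
  if (is.character(size)) {
    size <- match.arg(size)
    widths <- switch(size, small = c(2, 2, 2), medium = c(3, 3, 3),
                     large = c(4, 4, 4))
  } else {
    widths <- as.integer(size)
    if (length(widths) < 1 || any(widths < 1)) {
      stop("layer widths must be positive integers", call. = FALSE)
    }
  }
  if (prod(widths) < 4) {
    stop("layer spec yields fewer than 4 start-to-end paths; ",
         "too few to plant two dominant paths per class", call. = FALSE)
  }
  layers <- c(
    list("S"),
    lapply(seq_along(widths), function(l) {
      sprintf("L%dN%d", l, seq_len(widths[l]))
    }),
    list("E")
  )
  src <- character(0)
  tgt <- character(0)
  for (l in seq_len(length(layers) - 1)) {
    grid <- expand.grid(s = layers[[l]], t = layers[[l + 1]],
                        stringsAsFactors = FALSE)
    # order by source then target for a stable, readable edge numbering
    grid <- grid[order(grid$s, grid$t), ]
    src <- c(src, grid$s)
    tgt <- c(tgt, grid$t)
  }
  edges <- data.frame(
    source = src, target = tgt,
    gene = sprintf("g%03d", seq_along(src))
  )
  gene_network(edges, start = "S", end = "E")
}

#' Plant dominant paths in a network
#'
#' Samples `2 * per_class` mutually distinct simple start-to-end paths
#' uniformly without replacement from the enumerated path set and assigns
#' the first `per_class` of them to class 0 and the rest to class 1.
#'
#' @param network A [gene_network()].
#' @param per_class Dominant paths per response class (default 2).
#' @param seed Optional integer for reproducible selection.
#' @return A tibble with one row per dominant path: edge columns, the
#'   class column `y`, and a path identifier `.path`.
#' @export
plant_dominant_paths <- function(network, per_class = 2, seed = NULL) {
  paths <- enumerate_paths(network)
  need <- 2L * per_class
  if (nrow(paths) < need) {
    stop("network has only ", nrow(paths), " distinct paths; ", need,
         " are required", call. = FALSE)
  }
  pick <- with_seed(seed, sample.int(nrow(paths), need))
  out <- paths[pick, ]
  out$y <- rep(c(0L, 1L), each = per_class)
  out$.path <- sprintf("dominant_%d_%d", out$y, rep(seq_len(per_class), 2))
  out
}

#' Simulate a labeled pathway benchmark dataset
#'
#' Generates the simulation benchmark: for each response class,
#' `round(n_per_class * (1 - noise))` observations are split equally across
#' that class's planted dominant paths, and the remaining observations are
#' noise paths drawn uniformly (with replacement) from the valid
#' start-to-end paths that are not dominant for either class.  Both classes
#' share the same noise distribution, so noise rows carry no class signal
#' and an ideal classifier's accuracy is about
#' `(1 - noise) + noise / 2`.  Rows are shuffled.
#'
#' @param network A [gene_network()], typically from [make_network()]; a
#'   size keyword (`"small"`, `"medium"`, `"large"`) is also accepted.
#' @param n_per_class Observations per response class (default 200).
#' @param noise Fraction of each class's observations that are noise paths,
#'   in `[0, 1)`.
#' @param dominant_per_class Dominant paths planted per class (default 2).
#' @param seed Optional integer; the network planting and all sampling
#'   derive from it, so the dataset is exactly reproducible.
#' @return A tibble with one 0/1 column per edge, the response `y`, and a
#'   provenance column `.path` (`"dominant_<class>_<k>"` or `"noise"`).
#'   The planted paths are attached as attribute `dominant_paths`.
#' @export
simulate_pathways <- function(network = "small", n_per_class = 200,
                              noise = 0.1, dominant_per_class = 2,
                              seed = NULL) {
  if (is.character(network)) network <- make_network(network)
  stopifnot(inherits(network, "gene_network"))
  if (noise < 0 || noise >= 1) stop("noise must be in [0, 1)", call. = FALSE)
  if (n_per_class < dominant_per_class) {
    stop("n_per_class must cover the dominant paths", call. = FALSE)
  }
  dom <- plant_dominant_paths(network, dominant_per_class,
                              seed = derive_seed(seed, 1))
  all_paths <- enumerate_paths(network)
  labs <- edge_labels(network)
  dom_keys <- apply(as.matrix(dom[labs]), 1L, paste, collapse = "")
  all_keys <- apply(as.matrix(all_paths), 1L, paste, collapse = "")
  noise_pool <- which(!(all_keys %in% dom_keys))
  n_noise <- n_per_class - round(n_per_class * (1 - noise))
  if (n_noise > 0 && length(noise_pool) == 0) {
    stop("network has no non-dominant path to use as noise", call. = FALSE)
  }
  rows <- with_seed(derive_seed(seed, 2), {
    per_class <- lapply(c(0L, 1L), function(cls) {
      dom_cls <- dom[dom$y == cls, ]
      n_dom <- n_per_class - n_noise
      # equal expression levels across the class's dominant paths
      reps <- rep(n_dom %/% nrow(dom_cls), nrow(dom_cls))
      extra <- n_dom - sum(reps)
      if (extra > 0) reps[seq_len(extra)] <- reps[seq_len(extra)] + 1L
      dom_rows <- dom_cls[rep(seq_len(nrow(dom_cls)), reps), ]
      noise_rows <- NULL
      if (n_noise > 0) {
        idx <- sample(noise_pool, n_noise, replace = TRUE)
        noise_rows <- all_paths[idx, ]
        noise_rows$y <- cls
        noise_rows$.path <- "noise"
      }
      dplyr::bind_rows(dom_rows, noise_rows)
    })
    out <- dplyr::bind_rows(per_class)
    out[sample.int(nrow(out)), ]
  })
  attr(rows, "dominant_paths") <- dom
  rows
}
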