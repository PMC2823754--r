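#' Read and write gene-network edge lists
#'
#' Networks are stored as tab-separated edge lists with a mandatory header
#' `source  target  gene`.  The start and end compounds are written as
#' comment lines (`# start=...`, `# end=...`) so a file round-trips without
#' extra arguments; explicit `start`/`end` arguments override them.
#'
#' @param path File path.
#' @param network A [gene_network()].
#' @param start,end Optional node ids overriding the file's comments.
#' @return `read_network_tsv()` returns a [gene_network()];
#'   `write_network_tsv()` returns `path` invisibly.
#' @name network_io
NULL

#' @rdname network_io
#' @export
write_network_tsv <- function(network, path) {
  stopifnot(inherits(network, "gene_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# start=", network$start),
    paste0("# end=", network$end)
  ), con)
  utils::write.table(
    network$edges[, c("source", "target", "gene")], con,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname network_io
#' @export
read_network_tsv <- function(path, start = NULL, end = NULL) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "="), meta, value = TRUE)
    if (length(hit) == 0) NULL else sub(paste0("^#\\s*", key, "="), "", hit[1])
  }
  start <- start %||% get_meta("start")
  end <- end %||% get_meta("end")
  if (is.null(start) || is.null(end)) {
    stop("start/end must be given as arguments or # comments in the file",
         call. = FALSE)
  }
  body <- lines[!grepl("^#", lines)]
  edges <- utils::read.table(
    text = body, header = TRUE, sep = "\t",
    colClasses = "character", quote = ""
  )
  gene_network(edges, start = start, end = end)
}

#' Read and write pathway datasets
#'
#' A pathway dataset is stored as a TSV of 0/1 edge columns followed by the
#' response column `y` and any provenance columns (names starting with
#' `.`); the round-trip is lossless.
#'
#' @param data Pathway dataset tibble.
#' @param path File path.
#' @return `read_pathway_tsv()` returns a tibble;
#'   `write_pathway_tsv()` returns `path` invisibly.
#' @name pathway_io
NULL

#' @rdname pathway_io
#' @export
write_pathway_tsv <- function(data, path) {
  ord <- c(setdiff(names(data), c("y", names(data)[startsWith(names(data), ".")])),
           "y", names(data)[startsWith(names(data), ".")])
  utils::write.table(data[ord], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pathway_io
#' @export
read_pathway_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  tibble::as_tibble(d)
}

#' Read expression and label tables
#'
#' Expression TSVs hold one gene per row: the first column is the gene
#' identifier, the remaining columns one numeric value per sample.  Label
#' TSVs have columns `sample` and `label` (0/1).
#'
#' @param path File path.
#' @return A tibble.
#' @name expression_io
NULL

#' @rdname expression_io
#' @export
read_expression_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  names(d)[1] <- "gene"
  tibble::as_tibble(d)
}

#' @rdname expression_io
#' @export
read_labels_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample", "label") %in% names(d))) {
    stop("labels file needs columns `sample` and `label`", call. = FALSE)
  }
  d$sample <- as.character(d$sample)
  tibble::as_tibble(d)
}

#' Serialize a fitted model to JSON and back
#'
#' Writes every parameter of a fitted model (gate priors and transition
#' probabilities, expert coefficients, network edge list, configuration and
#' likelihood trace) to a JSON file at full double precision, so the
#' reloaded model reproduces predictions exactly.
#'
#' @param model A fitted [fit_hme3m()] object.
#' @param path File path.
#' @return `read_hme3m_json()` returns an `hme3m` object;
#'   `write_hme3m_json()` returns `path` invisibly.
#' @name model_io
NULL

#' @rdname model_io
#' @export
write_hme3m_json <- function(model, path) {
  stopifnot(inherits(model, "hme3m"))
  net <- model$network
  obj <- list(
    format = "hme3m-model",
    version = 1L,
    network = list(
      edges = as.data.frame(net$edges[, c("source", "target", "gene")]),
      start = net$start, end = net$end
    ),
    pi = model$gate$pi,
    theta = model$gate$theta,
    beta = do.call(rbind, lapply(model$experts, function(e) unname(e$beta))),
    M = model$M,
    logLik = model$logLik,
    objective = model$objective,
    trace = model$trace,
    ll_trace = model$ll_trace,
    n_iter = model$n_iter,
    converged = model$converged,
    n_obs = model$n_obs,
    config = model$config
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname model_io
#' @export
read_hme3m_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "hme3m-model")) {
    stop("not an hme3m model file", call. = FALSE)
  }
  network <- gene_network(obj$network$edges, obj$network$start,
                          obj$network$end)
  theta <- as.matrix(obj$theta)
  gate <- markov_mix(network, as.numeric(obj$pi), theta)
  beta_mat <- matrix(as.numeric(as.matrix(obj$beta)), nrow = obj$M)
  experts <- lapply(
    seq_len(obj$M),
    function(m) {
      b <- beta_mat[m, ]
      names(b) <- c("(Intercept)", edge_labels(network))
      structure(
        list(beta = b, lambda = obj$config$lambda,
             alpha = obj$config$alpha, n_iter = NA_integer_,
             converged = NA, objective = NA_real_,
             terms = edge_labels(network)),
        class = "plr_fit"
      )
    }
  )
  structure(
    list(
      gate = gate, experts = experts, H = NULL, network = network,
      M = as.integer(obj$M), logLik = obj$logLik,
      objective = obj$objective, trace = obj$trace,
      ll_trace = obj$ll_trace,
      n_iter = obj$n_iter, converged = obj$converged, n_obs = obj$n_obs,
      P = nrow(network$edges), config = obj$config
    ),
    class = "hme3m"
  )
}

#' Export fitted transition probabilities as GraphML or DOT
#'
#' Writes the network with each component's fitted transition
#' probabilities attached as edge attributes (`theta_1`, `theta_2`, ...)
#' and the gene as the edge label, ready for rendering the dominant-path
#' figures with standard graph tools.
#'
#' @param model A fitted `hme3m` model or a [markov_mix()].
#' @param path Output file path.
#' @param component For DOT output, which component's probability to print
#'   in the edge label (default 1).
#' @return `path`, invisibly.
#' @name gate_export
NULL

#' @rdname gate_export
#' @export
export_gate_graphml <- function(model, path) {
  gate <- if (inherits(model, "hme3m")) model$gate else model
  stopifnot(inherits(gate, "markov_mix"))
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("GraphML export requires the igraph package", call. = FALSE)
  }
  ed <- as.data.frame(gate$network$edges[, c("source", "target", "gene")])
  for (m in seq_len(gate$M)) {
    ed[[paste0("theta_", m)]] <- gate$theta[, m]
  }
  g <- igraph::graph_from_data_frame(
    ed, directed = TRUE,
    vertices = data.frame(name = gate$network$nodes)
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname gate_export
#' @export
export_gate_dot <- function(model, path, component = 1) {
  gate <- if (inherits(model, "hme3m")) model$gate else model
  stopifnot(inherits(gate, "markov_mix"))
  if (component < 1 || component > gate$M) {
    stop("component index out of range", call. = FALSE)
  }
  ed <- gate$network$edges
  th <- gate$theta[, component]
  lines <- c(
    "digraph pathway {",
    "  rankdir=LR;",
    sprintf('  "%s" [shape=doublecircle];', gate$network$start),
    sprintf('  "%s" [shape=doublecircle];', gate$network$end),
    sprintf('  "%s" -> "%s" [label="%s (%.3f)", penwidth=%.2f];',
            ed$source, ed$target, ed$gene, th, 0.5 + 4 * th),
    "}"
  )
  writeLines(lines, path)
  invisible(path)
}
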