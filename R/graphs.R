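#' Latent graphs underlying the stimulus sequence
#'
#' Constructors for the two 10-node, degree-4 latent graphs used to generate
#' stimulus sequences: a modular graph (two communities of five nodes joined
#' by two boundary edges) and a ring lattice (each node connected to its
#' nearest and next-nearest neighbours around a ring). The only difference
#' between the two lies in their higher-order structure; degree sequences are
#' identical.
#'
#' The modular graph connects all pairs within each five-node module except
#' the pair of boundary nodes, and adds the two cross-module edges (5,6) and
#' (10,1). This is the minimal-cross-edge, degree-4, two-module topology on
#' 10 nodes.
#'
#' @param n_nodes Number of nodes. The canonical design uses 10; the lattice
#'   generalises to any even `n_nodes >= 5`, the modular graph is fixed at 10.
#' @return An object of class `graph_spec`: a list with elements
#'   `n_nodes`, `adjacency` (symmetric binary matrix, zero diagonal),
#'   `kind` (`"modular"` or `"lattice"`), and `module_labels`
#'   (integer vector, modular graph only; `NULL` for the lattice).
#' @examples
#' g <- build_modular_graph()
#' rowSums(g$adjacency)  # every node has degree 4
#' @export
build_modular_graph <- function() {
  n <- 10L
  adj <- matrix(0L, n, n)
  modules <- rep(c(1L, 2L), each = 5L)
  # within-module: all pairs except the boundary pair (1,5) / (6,10)
  for (m in 1:2) {
    idx <- which(modules == m)
    for (i in idx) for (j in idx) if (i != j) adj[i, j] <- 1L
    adj[idx[1], idx[5]] <- adj[idx[5], idx[1]] <- 0L
  }
  # cross-module boundary edges
  adj[5, 6] <- adj[6, 5] <- 1L
  adj[10, 1] <- adj[1, 10] <- 1L
  new_graph_spec(adj, kind = "modular", module_labels = modules)
}

#' @rdname build_modular_graph
#' @export
build_lattice_graph <- function(n_nodes = 10L) {
  n <- as.integer(n_nodes)
  if (n < 5L) stop("ring lattice needs at least 5 nodes")
  i <- matrix(seq_len(n), n, n)
  d <- (i - t(i)) %% n
  adj <- ifelse(d %in% c(1L, 2L, n - 1L, n - 2L), 1L, 0L)
  dim(adj) <- c(n, n)
  new_graph_spec(adj, kind = "lattice", module_labels = NULL)
}

new_graph_spec <- function(adjacency, kind, module_labels = NULL) {
  stopifnot(isSymmetric(unname(adjacency)), all(diag(adjacency) == 0))
  structure(
    list(
      n_nodes = nrow(adjacency),
      adjacency = adjacency,
      kind = kind,
      module_labels = module_labels
    ),
    class = "graph_spec"
  )
}

#' @export
print.graph_spec <- function(x, ...) {
  cat(sprintf("<graph_spec: %s, %d nodes, %d edges>\n",
              x$kind, x$n_nodes, sum(x$adjacency) / 2L))
  invisible(x)
}

#' Uniform random-walk transition matrix of a latent graph
#'
#' Normalises each adjacency row by its degree, giving the row-stochastic
#' transition matrix of the unbiased random walk on the graph. For the
#' canonical degree-4 graphs every nonzero entry equals 1/4.
#'
#' @param g A `graph_spec`.
#' @return A row-stochastic `n_nodes x n_nodes` matrix.
#' @export
transition_matrix <- function(g) {
  stopifnot(inherits(g, "graph_spec"))
  deg <- rowSums(g$adjacency)
  if (any(deg == 0)) stop("graph has a zero-degree node; cannot normalize")
  g$adjacency / deg
}

#' Random walk on a latent graph
#'
#' Draws a node sequence from the Markov chain defined by a row-stochastic
#' transition matrix. The start node is uniform over nodes.
#'
#' @param A Row-stochastic transition matrix (e.g. from [transition_matrix()]).
#' @param n_steps Length of the walk (number of trials), at least 1.
#' @param seed Optional integer seed for reproducibility.
#' @return Integer vector of node indices (1-based), length `n_steps`.
#' @export
random_walk <- function(A, n_steps, seed = NULL) {
  if (n_steps < 1) stop("n_steps must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(A)
  stopifnot(all(abs(rowSums(A) - 1) < 1e-8))
  x <- integer(n_steps)
  x[1] <- sample.int(n, 1L)
  for (t in seq_len(n_steps - 1L)) {
    x[t + 1L] <- sample.int(n, 1L, prob = A[x[t], ])
  }
  x
}

#' Read or write a graph as JSON
#'
#' Graphs are serialized as an edge list plus module labels, a plain-text
#' format convenient for provenance tracking.
#'
#' @param g A `graph_spec`.
#' @param path File path.
#' @return `read_graph_json` returns a `graph_spec`; `write_graph_json`
#'   returns `path` invisibly.
#' @export
write_graph_json <- function(g, path) {
  stopifnot(inherits(g, "graph_spec"))
  e <- which(upper.tri(g$adjacency) & g$adjacency == 1L, arr.ind = TRUE)
  obj <- list(
    n_nodes = g$n_nodes,
    kind = g$kind,
    edges = unname(apply(e, 1L, function(r) as.integer(r), simplify = FALSE)),
    module_labels = g$module_labels
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- as.integer(obj$n_nodes)
  adj <- matrix(0L, n, n)
  edges <- obj$edges
  if (is.list(edges)) edges <- do.call(rbind, edges)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[i, j] <- adj[j, i] <- 1L
  }
  labels <- obj$module_labels
  if (!is.null(labels)) labels <- as.integer(labels)
  new_graph_spec(adj, kind = obj$kind, module_labels = labels)
}

#' Write or read a node sequence as single-column CSV
#'
#' @param x Integer node sequence.
#' @param path File path.
#' @export
write_walk_csv <- function(x, path) {
  utils::write.csv(data.frame(node = as.integer(x)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_walk_csv
#' @export
read_walk_csv <- function(path) {
  as.integer(utils::read.csv(path)$node)
}
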