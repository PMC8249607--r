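#' Construct a network layer
#'
#' A layer bundles one weighted adjacency matrix with its coupling strength
#' and transmission delay. The adjacency is oriented receiver-row /
#' sender-column: `adjacency[i, j]` is the weight of the arrow going from
#' node `j` to node `i`.
#'
#' @param adjacency square numeric matrix of finite link weights.
#' @param sigma coupling strength of this link type.
#' @param delay transmission delay (seconds, nonnegative).
#' @param label optional layer name.
#' @return an object of class `network_layer`.
#' @export
layer <- function(adjacency, sigma = 1, delay = 0, label = "") {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency))
    stop("layer adjacency must be square")
  if (!all(is.finite(adjacency)))
    stop("layer adjacency must have finite entries")
  if (!is.numeric(delay) || length(delay) != 1 || delay < 0)
    stop("layer delay must be a single nonnegative number")
  dimnames(adjacency) <- NULL
  structure(list(adjacency = adjacency, sigma = as.numeric(sigma),
                 delay = as.numeric(delay), label = as.character(label)),
            class = "network_layer")
}

#' Construct a directed weighted delayed multilayer network
#'
#' @param n_nodes number of nodes N.
#' @param node_types character vector of length N giving the dynamical type
#'   of each node; nodes of the same type share the same isolated vector
#'   field.
#' @param layers list of [layer()] objects, one per link type.
#' @return an object of class `multilayer_network`.
#' @export
multilayer_network <- function(n_nodes,
                               node_types = rep("node", n_nodes),
                               layers) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 1) stop("n_nodes must be positive")
  node_types <- as.character(node_types)
  if (length(node_types) != n_nodes)
    stop("node_types must have length n_nodes")
  if (inherits(layers, "network_layer")) layers <- list(layers)
  if (length(layers) < 1) stop("at least one layer is required")
  for (k in seq_along(layers)) {
    if (!inherits(layers[[k]], "network_layer"))
      stop("layers must be a list of layer() objects")
    if (nrow(layers[[k]]$adjacency) != n_nodes)
      stop(sprintf("layer %d adjacency is %dx%d but n_nodes is %d",
                   k, nrow(layers[[k]]$adjacency),
                   ncol(layers[[k]]$adjacency), n_nodes))
  }
  structure(list(n_nodes = n_nodes, node_types = node_types,
                 layers = layers),
            class = "multilayer_network")
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat(sprintf("multilayer network: %d nodes, %d types, %d layer(s)\n",
              x$n_nodes, length(unique(x$node_types)), length(x$layers)))
  for (k in seq_along(x$layers)) {
    ly <- x$layers[[k]]
    cat(sprintf("  layer %d%s: %d arrows, sigma = %g, delay = %g\n",
                k, if (nzchar(ly$label)) paste0(" (", ly$label, ")") else "",
                sum(ly$adjacency != 0), ly$sigma, ly$delay))
  }
  invisible(x)
}

#' Number of layers of a network
#' @param net a `multilayer_network`.
#' @return integer.
#' @export
n_layers <- function(net) length(net$layers)

#' Test layers for undirectedness
#'
#' A layer is undirected when its adjacency matrix is symmetric.
#'
#' @param net a `multilayer_network`.
#' @param tol absolute symmetry tolerance.
#' @return logical vector, one entry per layer.
#' @export
is_undirected <- function(net, tol = 1e-12) {
  vapply(net$layers, function(ly) {
    max(abs(ly$adjacency - t(ly$adjacency))) <= tol
  }, logical(1))
}
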