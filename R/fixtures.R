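# Built-in example networks and the planted-partition generator.

#' Five-node directed example network
#'
#' A single-layer directed network with unit weights whose balanced
#' partitions form a seven-member lattice: the minimal coloring has two
#' clusters C1 = {1, 2} and C2 = {3, 4, 5}, every node of C1 receives one
#' arrow from C1 and two arrows from C2, every node of C2 receives exactly
#' one arrow from C1 and none from C2, and C2 is one-way-dependent on C1.
#' The adjacency is a reconstruction from these structural facts (the
#' arrows are 1->2, 2->1, 3->1, 5->1, 3->2, 5->2, 1->3, 2->4, 1->5); by
#' default the constructor validates that the seven known balanced
#' partitions are balanced and that the minimal coloring comes out right,
#' and fails loudly otherwise.
#'
#' @param validate run the structural validation checks.
#' @return a single-layer [multilayer_network()] with 5 nodes.
#' @export
fig2_network <- function(validate = TRUE) {
  edges <- rbind(c(1, 2), c(2, 1), c(3, 1), c(5, 1), c(3, 2), c(5, 2),
                 c(1, 3), c(2, 4), c(1, 5))
  A <- matrix(0, 5, 5)
  A[cbind(edges[, 2], edges[, 1])] <- 1     # receiver row, sender column
  net <- multilayer_network(5, rep("node", 5), list(layer(A, sigma = 1)))
  if (validate) {
    for (p in fig2_partitions()) {
      if (!is_balanced(net, p))
        stop("fig2_network validation failed: listed partition not balanced")
    }
    mc <- minimal_balanced_coloring(net)
    if (partition_key(mc) != partition_key(fig2_partitions()[[1]]))
      stop("fig2_network validation failed: wrong minimal coloring")
  }
  net
}

#' The seven balanced partitions of [fig2_network()]
#'
#' In order: the minimal partition P, then P1..P6.
#' @return list of `node_partition` objects.
#' @export
fig2_partitions <- function() {
  lapply(list(list(1:2, 3:5),
              list(1:2, 3, 4:5),
              list(1:2, 3:4, 5),
              list(1:2, c(3, 5), 4),
              list(1:2, 3, 4, 5),
              list(1, 2, c(3, 5), 4),
              list(1, 2, 3, 4, 5)),
         as_partition, n_nodes = 5)
}

#' Ring of eight violin players
#'
#' Eight phase oscillators on a ring; incoming weights are row-normalized
#' so that the total volume each player hears is constant. Three
#' connectivity regimes:
#' * `"undirected"`: both neighbors heard, weights 1/2 (low or high
#'   delay).
#' * `"arrowhead"`: intermediate delay; player 1 ignores everyone, the
#'   signal propagates along both sides of the ring (1->2->3->4->5 and
#'   1->8->7->6->5), and player 5 hears players 4 and 6 with weight 1/2.
#'   The minimal balanced coloring has the five clusters {1}, {2,8},
#'   {3,7}, {4,6}, {5}.
#' * `"unidirectional"`: every player listens only to its predecessor.
#'
#' @param regime one of `"undirected"`, `"arrowhead"`, `"unidirectional"`.
#' @param kappa coupling strength (Hz).
#' @param delay transmission delay (s).
#' @return a single-layer [multilayer_network()] with 8 nodes.
#' @export
violin_ring <- function(regime = c("undirected", "arrowhead",
                                   "unidirectional"),
                        kappa = 0.2, delay = 0) {
  regime <- match.arg(regime)
  A <- matrix(0, 8, 8)
  if (regime == "undirected") {
    for (i in 1:8) {
      A[i, (i %% 8) + 1] <- 0.5
      A[i, ((i - 2) %% 8) + 1] <- 0.5
    }
  } else if (regime == "arrowhead") {
    for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 5),
                   c(1, 8), c(8, 7), c(7, 6), c(6, 5)))
      A[e[2], e[1]] <- 1
    A[5, ] <- A[5, ] / 2                     # player 5 hears two inputs
  } else {
    for (i in 1:8) A[(i %% 8) + 1, i] <- 1
  }
  multilayer_network(8, rep("violin", 8),
                     list(layer(A, sigma = kappa, delay = delay,
                                label = regime)))
}

#' Two-layer neuron network
#'
#' Twenty neurons in two layers of ten. Layer II (nodes 1..10) is a ring
#' where every neuron couples electrically to its 6 closest neighbors
#' (weight 1). The chemical layer connects node i of layer II to node
#' i + 10 of layer I and back, both directions with weight
#' `up_weight = 1` times the chemical strength `sigma_2` (the dynamical
#' equations of the two layers both carry the full chemical strength;
#' `up_weight` rescales only the layer-I-to-layer-II direction, e.g.
#' `up_weight = 0.25` for a quarter-strength upward synapse). Either
#' interlayer direction can be removed entirely to study one-way
#' dependence.
#'
#' @param drop_II_to_I remove the arrows from layer II to layer I.
#' @param drop_I_to_II remove the arrows from layer I to layer II.
#' @param sigma1,sigma2 electrical and chemical coupling strengths.
#' @param up_weight relative weight of the layer-I-to-layer-II synapse.
#' @return a two-layer [multilayer_network()] with 20 nodes, node types
#'   `"II"` (1..10) and `"I"` (11..20).
#' @export
neuron_two_layer <- function(drop_II_to_I = FALSE, drop_I_to_II = FALSE,
                             sigma1 = 0.005, sigma2 = 1, up_weight = 1) {
  A1 <- matrix(0, 20, 20)
  for (i in 1:10) for (d in 1:3) {
    A1[i, ((i - 1 + d) %% 10) + 1] <- 1
    A1[i, ((i - 1 - d) %% 10) + 1] <- 1
  }
  A2 <- matrix(0, 20, 20)
  for (i in 1:10) {
    if (!drop_II_to_I) A2[i + 10, i] <- 1
    if (!drop_I_to_II) A2[i, i + 10] <- up_weight
  }
  multilayer_network(20, c(rep("II", 10), rep("I", 10)),
                     list(layer(A1, sigma = sigma1, delay = 0,
                                label = "electrical"),
                          layer(A2, sigma = sigma2, delay = 0,
                                label = "chemical")))
}

#' Violin-player dynamical system
#'
#' Delayed Kuramoto phase model on a [violin_ring()]: identical
#' eigenfrequencies `omega` and sine coupling through the row-normalized
#' ring adjacency.
#'
#' @inheritParams violin_ring
#' @param omega common eigenfrequency (Hz).
#' @return a [dyn_system()].
#' @export
violin_system <- function(regime = "undirected", delay = 0, omega = 0.25,
                          kappa = 0.2) {
  net <- violin_ring(regime, kappa = kappa, delay = delay)
  dyn_system(net, list(violin = kuramoto_node(omega)),
             list(kuramoto_coupling()))
}

#' Two-layer neuron dynamical system
#'
#' Bursting-neuron models on [neuron_two_layer()]: layer II neurons
#' (`alpha = 1.7`) couple electrically among themselves and chemically to
#' layer I neurons (`alpha = 1.6`), the chemical synapse being sigmoidal
#' with reversal potential `d = 2`.
#'
#' @inheritParams neuron_two_layer
#' @return a [dyn_system()].
#' @export
neuron_system <- function(sigma1 = 0.005, sigma2 = 1, drop_II_to_I = FALSE,
                          drop_I_to_II = FALSE, up_weight = 1) {
  net <- neuron_two_layer(drop_II_to_I, drop_I_to_II, sigma1, sigma2,
                          up_weight)
  dyn_system(net,
             list(II = neuron_node(alpha = 1.7),
                  I = neuron_node(alpha = 1.6)),
             list(diffusive_coupling(), sigmoid_coupling()))
}

#' Random digraph with a planted balanced partition
#'
#' For every ordered cluster pair (p, q), each node of cluster p receives
#' arrows (weight 1) from exactly `indeg[[k]][p, q]` nodes of cluster q,
#' the senders drawn uniformly at random. The planted partition is
#' balanced by construction.
#'
#' @param sizes integer vector of cluster sizes.
#' @param indeg quotient in-degree specification: a Q x Q matrix (single
#'   layer) or a list of such matrices (one per layer).
#' @param seed RNG seed (the generator is a pure function of its
#'   arguments).
#' @param sigma,delay per-layer strengths and delays.
#' @param types_by_cluster give each cluster its own node type (default:
#'   one shared type, so the planted partition need not be minimal).
#' @return a [multilayer_network()] with attribute `"partition"` holding
#'   the planted `node_partition`.
#' @export
random_planted <- function(sizes, indeg, seed = 1, sigma = 1, delay = 0,
                           types_by_cluster = FALSE) {
  if (is.matrix(indeg)) indeg <- list(indeg)
  Q <- length(sizes)
  N <- sum(sizes)
  stopifnot(all(vapply(indeg, function(m) all(dim(m) == Q), logical(1))))
  sigma <- rep_len(sigma, length(indeg))
  delay <- rep_len(delay, length(indeg))
  clusters <- split(seq_len(N), rep(seq_len(Q), sizes))
  set.seed(seed)
  layers <- lapply(seq_along(indeg), function(k) {
    A <- matrix(0, N, N)
    D <- indeg[[k]]
    for (p in seq_len(Q)) for (q in seq_len(Q)) {
      d <- D[p, q]
      if (d == 0) next
      for (i in clusters[[p]]) {
        pool <- setdiff(clusters[[q]], i)    # no self-loops
        if (d > length(pool))
          stop(sprintf("infeasible in-degree %d from cluster %d (size %d)",
                       d, q, sizes[q]))
        A[i, pool[sample.int(length(pool), d)]] <- 1
      }
    }
    layer(A, sigma = sigma[k], delay = delay[k], label = sprintf("L%d", k))
  })
  types <- if (types_by_cluster) sprintf("t%d", rep(seq_len(Q), sizes))
           else rep("node", N)
  net <- multilayer_network(N, types, layers)
  attr(net, "partition") <- as_partition(clusters, N)
  net
}
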