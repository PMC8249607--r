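#' Construct a node partition
#'
#' Clusters are stored 1-based, each sorted, and ordered by smallest member,
#' which makes the representation canonical.
#'
#' @param clusters list of integer vectors, disjoint and covering `1:n_nodes`.
#' @param n_nodes number of nodes.
#' @return an object of class `node_partition`.
#' @export
as_partition <- function(clusters, n_nodes) {
  clusters <- unname(lapply(clusters, function(cl)
    sort(as.integer(unname(cl)))))
  all_nodes <- sort(unlist(clusters))
  if (length(all_nodes) != n_nodes || any(all_nodes != seq_len(n_nodes)))
    stop("clusters must be disjoint and cover 1:n_nodes")
  clusters <- clusters[order(vapply(clusters, min, integer(1)))]
  structure(list(clusters = clusters, n_nodes = as.integer(n_nodes)),
            class = "node_partition")
}

#' Partition from a per-node membership vector
#' @param membership integer/character vector, one label per node.
#' @return a `node_partition`.
#' @export
partition_from_membership <- function(membership) {
  as_partition(split(seq_along(membership), membership),
               length(membership))
}

#' Per-node cluster index of a partition
#' @param part a `node_partition`.
#' @return integer vector: `membership[i]` is the cluster index of node i.
#' @export
partition_membership <- function(part) {
  m <- integer(part$n_nodes)
  for (q in seq_along(part$clusters)) m[part$clusters[[q]]] <- q
  m
}

#' Number of clusters
#' @param part a `node_partition`.
#' @export
n_clusters <- function(part) length(part$clusters)

partition_key <- function(part) {
  paste(vapply(part$clusters, function(cl) paste(cl, collapse = ","),
               character(1)), collapse = "|")
}

#' @export
print.node_partition <- function(x, ...) {
  cat(sprintf("partition of %d nodes into %d cluster(s):\n",
              x$n_nodes, length(x$clusters)))
  for (cl in x$clusters) cat("  {", paste(cl, collapse = ", "), "}\n")
  invisible(x)
}

#' @export
format.node_partition <- function(x, ...) {
  paste0("{", vapply(x$clusters, function(cl)
    paste(cl, collapse = " "), character(1)), "}", collapse = " ")
}

#' Does one partition refine another?
#'
#' `fine` refines `coarse` when every cluster of `fine` is contained in a
#' cluster of `coarse`.
#'
#' @param fine,coarse `node_partition` objects on the same node set.
#' @return logical.
#' @export
refines <- function(fine, coarse) {
  if (fine$n_nodes != coarse$n_nodes) stop("partitions are on different node sets")
  mc <- partition_membership(coarse)
  all(vapply(fine$clusters, function(cl) length(unique(mc[cl])) == 1,
             logical(1)))
}

# per-layer input-sum matrix: S[i, q] = total weight node i receives from
# cluster q
input_sums <- function(A, part) {
  M <- matrix(0, ncol(A), length(part$clusters))
  for (q in seq_along(part$clusters)) M[part$clusters[[q]], q] <- 1
  A %*% M
}

#' Test whether a partition is balanced (equitable)
#'
#' A partition is balanced when nodes sharing a cluster have the same
#' dynamical type and, for every layer and every cluster pair, receive the
#' same total input weight from that cluster.
#'
#' @param net a [multilayer_network()].
#' @param part a `node_partition` covering the network's nodes.
#' @param tol relative comparison tolerance for the input sums.
#' @return logical.
#' @export
is_balanced <- function(net, part, tol = 1e-9) {
  if (!inherits(part, "node_partition")) stop("part must be a node_partition")
  if (part$n_nodes != net$n_nodes)
    stop("partition does not cover the network's node set")
  for (cl in part$clusters)
    if (length(unique(net$node_types[cl])) > 1) return(FALSE)
  for (ly in net$layers) {
    S <- input_sums(ly$adjacency, part)
    for (cl in part$clusters) {
      if (length(cl) == 1) next
      rows <- S[cl, , drop = FALSE]
      ref <- rows[1, ]
      dev <- abs(sweep(rows, 2, ref)) > tol * pmax(1, abs(ref))[col(rows)]
      if (any(dev)) return(FALSE)
    }
  }
  TRUE
}

#' Coarsest balanced refinement (minimal balanced coloring)
#'
#' Iteratively splits colors on the signature of per-(layer, color) input
#' sums until the coloring is balanced. Starting from the node-type
#' coloring this yields the minimal balanced coloring; starting from a
#' finer seed it yields the coarsest balanced partition refining the seed.
#'
#' @param net a [multilayer_network()].
#' @param seed optional `node_partition` used as the initial coloring;
#'   defaults to the partition by node type. The seed may only group nodes
#'   of the same type.
#' @return a balanced `node_partition`.
#' @export
minimal_balanced_coloring <- function(net, seed = NULL) {
  n <- net$n_nodes
  if (is.null(seed)) {
    color <- match(net$node_types, unique(net$node_types))
  } else {
    if (seed$n_nodes != n) stop("seed partition does not cover the node set")
    color <- partition_membership(seed)
    # intersect with types so same-color nodes always share a vector field
    key <- paste(color, match(net$node_types, unique(net$node_types)))
    color <- match(key, unique(key))
  }
  color <- cpp_refine_coloring(lapply(net$layers, `[[`, "adjacency"),
                               as.integer(color))
  partition_from_membership(color)
}

#' All-singletons partition
#' @param n_nodes number of nodes.
#' @export
singleton_partition <- function(n_nodes)
  as_partition(as.list(seq_len(n_nodes)), n_nodes)

new_partition_lattice <- function(net, partitions, base = NULL) {
  keys <- vapply(partitions, partition_key, character(1))
  partitions <- partitions[!duplicated(keys)]
  if (is.null(base)) base <- minimal_balanced_coloring(net)
  bkey <- partition_key(base)
  keys <- vapply(partitions, partition_key, character(1))
  partitions <- partitions[keys != bkey]
  # order: base first, then by increasing cluster count, then canonical key
  qs <- vapply(partitions, n_clusters, integer(1))
  ord <- order(qs, vapply(partitions, partition_key, character(1)))
  partitions <- c(list(base), partitions[ord])
  P <- length(partitions)
  ref <- NULL
  if (P <= 2000) {
    ref <- matrix(FALSE, P, P)
    for (i in seq_len(P)) for (j in seq_len(P))
      ref[i, j] <- refines(partitions[[i]], partitions[[j]])
  }
  structure(list(partitions = partitions, refines = ref, net = net),
            class = "partition_lattice")
}

#' @export
print.partition_lattice <- function(x, ...) {
  cat(sprintf("lattice of %d balanced partition(s); base partition:\n",
              length(x$partitions)))
  print(x$partitions[[1]])
  invisible(x)
}

#' Enumerate all balanced partitions of a network
#'
#' `"bruteforce"` tests every type-compatible set partition of the node set
#' (exact, exponential; refused above `max_bell` nodes).
#' `"seeded_closure"` repeatedly takes coarsest balanced refinements of
#' seeds obtained by splitting one cluster of an already-found balanced
#' partition into two parts, over all such splits, until closure; this is
#' exhaustive as long as no cluster exceeds the internal split cutoff
#' (12 nodes), beyond which heuristic isolation seeds are used with a
#' warning. The strategy is cross-validated against bruteforce on small
#' networks in the test suite.
#'
#' @param net a [multilayer_network()].
#' @param strategy `"bruteforce"` or `"seeded_closure"`.
#' @param max_bell node-count cutoff for bruteforce.
#' @param tol balance tolerance.
#' @param max_partitions closure truncation cap: some networks (notably
#'   with driven but otherwise uncoupled node groups) have astronomically
#'   many balanced partitions; the closure stops with a warning when this
#'   many have been found, returning a partial (breadth-first, so
#'   coarsest-first) lattice.
#' @return a `partition_lattice` whose first element is the minimal
#'   balanced coloring.
#' @export
enumerate_balanced_partitions <- function(net,
                                          strategy = c("bruteforce",
                                                       "seeded_closure"),
                                          max_bell = 12, tol = 1e-9,
                                          max_partitions = 5000) {
  strategy <- match.arg(strategy)
  if (strategy == "bruteforce") {
    if (net$n_nodes > max_bell)
      stop(sprintf(paste("bruteforce enumeration refused for N = %d >",
                         "max_bell = %d; use strategy = 'seeded_closure'"),
                   net$n_nodes, max_bell))
    A <- lapply(net$layers, function(ly) ly$adjacency)
    ty <- match(net$node_types, unique(net$node_types))
    mem <- cpp_enumerate_balanced(A, as.integer(ty), tol)
    parts <- lapply(mem, partition_from_membership)
  } else {
    parts <- seeded_closure(net, tol, max_partitions = max_partitions)
  }
  new_partition_lattice(net, parts)
}

# Closure under coarsest balanced refinements of single-cluster two-part
# splits. Complete: any balanced partition R strictly refining a balanced P
# refines the seed S obtained by splitting one P-cluster into (one
# R-cluster, rest), hence refines mbc(S), which the closure visits. The
# exhaustive split enumeration is exponential in the cluster size; clusters
# larger than max_split fall back to singleton and pair isolation seeds
# (heuristic) with a warning.
seeded_closure <- function(net, tol = 1e-9, start = NULL, max_split = 12,
                           max_partitions = 5000) {
  n <- net$n_nodes
  found <- list()
  truncated <- FALSE
  add <- function(p) {
    k <- partition_key(p)
    if (is.null(found[[k]])) { found[[k]] <<- p; TRUE } else FALSE
  }
  base <- if (is.null(start)) minimal_balanced_coloring(net) else start
  add(base)
  add(minimal_balanced_coloring(net, singleton_partition(n)))
  queue <- unname(found)
  while (length(queue) && !truncated) {
    p <- queue[[1]]; queue <- queue[-1]
    mem <- partition_membership(p)
    for (q in seq_along(p$clusters)) {
      cl <- p$clusters[[q]]
      s <- length(cl)
      if (s < 2) next
      if (s <= max_split) {
        # all two-part splits of the cluster; cl[1] stays in the first part
        rest <- cl[-1]
        seeds <- lapply(seq_len(2^(s - 1) - 1), function(code) {
          rest[bitwAnd(code, 2^(seq_len(s - 1) - 1)) > 0]
        })
      } else {
        warning(sprintf(paste("cluster of size %d exceeds max_split = %d;",
                              "using heuristic isolation seeds"),
                        s, max_split))
        seeds <- lapply(cl, identity)
        if (s >= 3) seeds <- c(seeds, utils::combn(cl, 2, simplify = FALSE))
      }
      for (b in seeds) {
        m2 <- mem
        m2[b] <- max(mem) + 1L
        refined <- minimal_balanced_coloring(net,
                                             partition_from_membership(m2))
        if (!is.null(start) && !refines(refined, start)) next
        if (add(refined)) queue <- c(queue, list(refined))
        if (length(found) >= max_partitions) {
          warning(sprintf(paste("balanced-partition closure truncated at",
                                "%d members; the lattice of this network is",
                                "larger (possibly astronomically: clusters",
                                "of driven, otherwise uncoupled nodes can",
                                "split freely) and downstream",
                                "lattice-quantified results are partial"),
                          max_partitions))
          truncated <- TRUE
          break
        }
      }
      if (truncated) break
    }
  }
  unname(found)
}

#' All balanced partitions refining a given balanced partition
#'
#' Exhaustively combines set partitions of each cluster of `part` and keeps
#' the balanced combinations. The number of combinations is the product of
#' the Bell numbers of the cluster sizes; above `max_combos` the exhaustive
#' route is refused and the seeded-closure heuristic restricted to
#' refinements of `part` is used instead.
#'
#' @param net a [multilayer_network()].
#' @param part a balanced `node_partition`.
#' @param max_combos combination cutoff for the exhaustive route.
#' @param tol balance tolerance.
#' @return a `partition_lattice` with base `part`.
#' @export
balanced_refinements_below <- function(net, part, max_combos = 1e5,
                                       tol = 1e-9, max_partitions = 5000) {
  if (!is_balanced(net, part, tol)) stop("part must be balanced")
  sizes <- vapply(part$clusters, length, integer(1))
  combos <- prod(vapply(sizes, bell_number, numeric(1)))
  if (combos <= max_combos) {
    per_cluster <- lapply(part$clusters, set_partitions_of)
    grid <- list(integer(0))
    # build the cartesian product incrementally as membership vectors
    mems <- list(integer(net$n_nodes))
    offset <- 0L
    for (q in seq_along(per_cluster)) {
      new_mems <- list()
      for (m in mems) {
        for (sp in per_cluster[[q]]) {
          m2 <- m
          top <- max(m2, 0L)
          for (b in seq_along(sp)) m2[sp[[b]]] <- top + b
          new_mems[[length(new_mems) + 1]] <- m2
        }
      }
      mems <- new_mems
    }
    parts <- lapply(mems, partition_from_membership)
    keep <- vapply(parts, function(p) is_balanced(net, p, tol), logical(1))
    parts <- parts[keep]
  } else {
    parts <- seeded_closure(net, tol, start = part,
                            max_partitions = max_partitions)
  }
  new_partition_lattice(net, parts, base = part)
}

bell_number <- function(n) {
  if (n == 0) return(1)
  b <- 1
  row <- 1
  for (i in seq_len(n - 1)) {
    new_row <- numeric(i + 1)
    new_row[1] <- row[length(row)]
    for (j in seq_len(i)) new_row[j + 1] <- new_row[j] + row[j]
    row <- new_row
  }
  row[length(row)]
}

set_partitions_of <- function(items) {
  n <- length(items)
  if (n == 0) return(list(list()))
  if (n == 1) return(list(list(items)))
  out <- list()
  rec <- function(i, blocks) {
    if (i > n) { out[[length(out) + 1]] <<- blocks; return(invisible()) }
    for (b in seq_along(blocks)) {
      blocks2 <- blocks
      blocks2[[b]] <- c(blocks2[[b]], items[i])
      rec(i + 1, blocks2)
    }
    rec(i + 1, c(blocks, list(items[i])))
  }
  rec(2, list(items[1]))
  out
}

#' Quotient network of a balanced partition
#'
#' The quotient has one node per cluster; its layer-k adjacency row for
#' cluster p is the per-cluster input sum of any representative node of p
#' (identical across representatives exactly because the partition is
#' balanced). Layer strengths and delays carry over; the quotient node type
#' is the shared type of the cluster.
#'
#' @param net a [multilayer_network()].
#' @param part a balanced `node_partition`.
#' @param tol balance tolerance.
#' @return a `multilayer_network` with `n_clusters(part)` nodes and
#'   attribute `"partition"` recording `part`.
#' @export
quotient_network <- function(net, part, tol = 1e-9) {
  if (!is_balanced(net, part, tol))
    stop("partition is not balanced; quotient is undefined")
  reps <- vapply(part$clusters, `[`, integer(1), 1)
  qlayers <- lapply(net$layers, function(ly) {
    S <- input_sums(ly$adjacency, part)
    layer(S[reps, , drop = FALSE], sigma = ly$sigma, delay = ly$delay,
          label = ly$label)
  })
  qn <- multilayer_network(length(reps), net$node_types[reps], qlayers)
  attr(qn, "partition") <- part
  qn
}
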