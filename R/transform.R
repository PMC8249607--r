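#' Transverse rows for one cluster
#'
#' Builds the `N_q x N` block `T_q` of the coordinate transformation: a
#' uniform row `1/sqrt(N_q)` over the cluster's columns, then contrast rows
#' generated from the cluster's canonical breaking patterns taken in order
#' of ascending intertwining index, descending number of occurrences in the
#' lattice, and lexicographic pattern as the final tie-break. Each pattern
#' contributes the orthonormalized subcluster-indicator directions it spans;
#' if all patterns are exhausted before the block is full (possible when no
#' pattern family spans the transverse space) the block is completed with an
#' arbitrary orthonormal complement and a warning is issued.
#'
#' Rows follow a fixed sign convention: the entry of largest magnitude is
#' made positive, ties resolved by making the last nonzero entry positive.
#'
#' @param lattice a `partition_lattice` for the base partition.
#' @param q cluster index in the base partition.
#' @return numeric matrix with `N_q` rows and `N` columns.
#' @export
build_cluster_block <- function(lattice, q) {
  base <- lattice$partitions[[1]]
  cl <- base$clusters[[q]]
  n <- base$n_nodes
  nq <- length(cl)
  rows <- matrix(0, 1, n)
  rows[1, cl] <- 1 / sqrt(nq)
  if (nq == 1) return(rows)

  bv <- breaking_vectors(lattice, q)
  if (length(bv)) {
    keys <- vapply(bv, `[[`, character(1), "pattern_key")
    idx <- vapply(bv, `[[`, integer(1), "index")
    agg <- data.frame(key = unique(keys))
    agg$min_index <- vapply(agg$key, function(k) min(idx[keys == k]), integer(1))
    agg$occurrences <- vapply(agg$key, function(k) sum(keys == k), integer(1))
    agg <- agg[order(agg$min_index, -agg$occurrences, agg$key), , drop = FALSE]
    for (k in agg$key) {
      pat <- bv[[which(keys == k)[1]]]$pattern[cl]
      for (b in unique(pat)) {
        v <- numeric(n)
        v[cl[pat == b]] <- 1
        v <- orthogonalize(v, rows)
        if (!is.null(v)) rows <- rbind(rows, sign_convention(v))
        if (nrow(rows) == nq) return(rows)
      }
    }
  }
  # orthonormal completion restricted to the cluster's columns
  warning(sprintf(paste("breaking patterns of cluster %d span only %d of %d",
                        "transverse directions; completing the block with an",
                        "arbitrary orthonormal complement"),
                  q, nrow(rows) - 1, nq - 1))
  for (i in cl) {
    v <- numeric(n); v[i] <- 1
    v <- orthogonalize(v, rows)
    if (!is.null(v)) rows <- rbind(rows, sign_convention(v))
    if (nrow(rows) == nq) break
  }
  rows
}

orthogonalize <- function(v, rows, tol = 1e-9) {
  for (pass in 1:2)                        # two passes for numerical safety
    for (r in seq_len(nrow(rows))) v <- v - sum(v * rows[r, ]) * rows[r, ]
  nv <- sqrt(sum(v^2))
  if (nv < tol) return(NULL)
  v / nv
}

sign_convention <- function(v, tol = 1e-12) {
  av <- abs(v)
  m <- max(av)
  idx <- which(av > m - tol)
  if (length(idx) == 1) {
    if (v[idx] < 0) v <- -v
  } else {
    last_nz <- max(which(av > tol))
    if (v[last_nz] < 0) v <- -v
  }
  v
}

#' Assemble the irreducible coordinate transformation
#'
#' Stacks the per-cluster blocks into the orthonormal matrix
#' `T = [T_par; T_perp]`, computes `B^k = T A^k T'` for every layer, and
#' reorders the transverse rows so that the summed transverse block
#' `B_perp = sum_k B_perp^k` is block-diagonal with irreducible blocks of
#' decreasing size, each block upper triangular whenever its internal
#' dependency digraph is acyclic. Blocks are the connected components of
#' the symmetrized nonzero pattern of `B_perp`; inside a block, rows are
#' ordered by the topological order of the strongly-connected-component
#' condensation of the directed dependency graph (row j depends on row l
#' when `B_perp[j, l]` is nonzero), with ascending row index as tie-break.
#'
#' @param net a [multilayer_network()].
#' @param lattice a `partition_lattice`; its base partition defines the
#'   synchronization pattern.
#' @param tol threshold separating structural zeros from rounding noise in
#'   `B_perp` (applied after scaling each layer by `max(|A^k|)`).
#' @return an object of class `cs_transform` with fields `T`, `T_par`,
#'   `T_perp`, `row_cluster` (cluster index per transverse row), `B` (per
#'   layer), `B_perp` (per layer), `blocks` (list of `rows`, `clusters`,
#'   `pattern`), `partition`.
#' @export
assemble_transform <- function(net, lattice, tol = 1e-9) {
  base <- lattice$partitions[[1]]
  if (!is_balanced(net, base)) stop("base partition is not balanced")
  n <- net$n_nodes
  Q <- n_clusters(base)
  blocks_q <- lapply(seq_len(Q), function(q) build_cluster_block(lattice, q))
  T_par <- do.call(rbind, lapply(blocks_q, function(b) b[1, , drop = FALSE]))
  T_perp <- do.call(rbind, lapply(blocks_q, function(b) b[-1, , drop = FALSE]))
  row_cluster <- unlist(lapply(seq_len(Q), function(q)
    rep(q, nrow(blocks_q[[q]]) - 1)))
  m <- n - Q

  if (m > 0) {
    # nonzero pattern of the summed transverse block
    pat <- matrix(FALSE, m, m)
    for (ly in net$layers) {
      Bp <- T_perp %*% ly$adjacency %*% t(T_perp)
      scale <- max(abs(ly$adjacency), 1)
      pat <- pat | (abs(Bp) / scale > tol)
    }
    g_sym <- igraph::graph_from_adjacency_matrix(pat | t(pat), mode = "undirected")
    comp <- igraph::components(g_sym)$membership
    g_dep <- igraph::graph_from_adjacency_matrix(
      pat & !diag(TRUE, m), mode = "directed")
    scc <- igraph::components(g_dep, mode = "strong")$membership
    # condensation: edge scc(j) -> scc(l) when row j depends on row l
    ns <- max(scc)
    cond_edges <- which(pat & !diag(TRUE, m), arr.ind = TRUE)
    ce <- unique(cbind(scc[cond_edges[, 1]], scc[cond_edges[, 2]]))
    ce <- ce[ce[, 1] != ce[, 2], , drop = FALSE]
    g_cond <- igraph::graph_from_edgelist(
      matrix(as.character(rbind(ce, cbind(seq_len(ns), seq_len(ns)))[, 1:2]),
             ncol = 2), directed = TRUE)
    # topological order over scc ids: dependents first
    topo <- as.integer(igraph::topo_sort(
      igraph::simplify(g_cond), mode = "out")$name)
    scc_rank <- match(seq_len(ns), topo)
    ord_within <- order(scc_rank[scc], seq_len(m))
    # group rows by component, components by decreasing size then first row
    comp_sizes <- tabulate(comp)
    comp_rank <- order(-comp_sizes, vapply(seq_len(max(comp)), function(cc)
      min(which(comp == cc)), integer(1)))
    perm <- unlist(lapply(comp_rank, function(cc)
      ord_within[comp[ord_within] == cc]))
    T_perp <- T_perp[perm, , drop = FALSE]
    row_cluster <- row_cluster[perm]
  }

  TT <- rbind(T_par, T_perp)
  B <- lapply(net$layers, function(ly) TT %*% ly$adjacency %*% t(TT))
  B_perp <- lapply(B, function(b)
    b[seq_len(m) + Q, seq_len(m) + Q, drop = FALSE])

  blocks <- list()
  if (m > 0) {
    pat <- matrix(FALSE, m, m)
    for (k in seq_along(net$layers)) {
      scale <- max(abs(net$layers[[k]]$adjacency), 1)
      pat <- pat | (abs(B_perp[[k]]) / scale > tol)
    }
    g_sym <- igraph::graph_from_adjacency_matrix(pat | t(pat), mode = "undirected")
    comp <- igraph::components(g_sym)$membership
    sizes <- tabulate(comp)
    for (cc in order(-sizes, vapply(seq_len(max(comp)), function(x)
      min(which(comp == x)), integer(1)))) {
      rows <- which(comp == cc)
      blocks[[length(blocks) + 1]] <- list(
        rows = rows,
        clusters = sort(unique(row_cluster[rows])),
        pattern = pat[rows, rows, drop = FALSE])
    }
  }

  structure(list(T = TT, T_par = T_par, T_perp = T_perp,
                 row_cluster = row_cluster, B = B, B_perp = B_perp,
                 blocks = blocks, partition = base, n_nodes = n, Q = Q),
            class = "cs_transform")
}

#' @export
print.cs_transform <- function(x, ...) {
  cat(sprintf("irreducible transformation: N = %d, Q = %d, %d transverse row(s), %d block(s)\n",
              x$n_nodes, x$Q, x$n_nodes - x$Q, length(x$blocks)))
  for (i in seq_along(x$blocks)) {
    b <- x$blocks[[i]]
    cat(sprintf("  block %d: %d row(s), clusters {%s}\n", i,
                length(b$rows), paste(b$clusters, collapse = ", ")))
  }
  invisible(x)
}

#' Classify cluster interdependencies from the transverse block structure
#'
#' Clusters whose transverse rows sit in different irreducible blocks are
#' independent. Inside a block, cluster `a` depends on cluster `b` when
#' some row of `a` reaches a row of `b` along the directed dependency
#' pattern; mutual reachability marks the pair intertwined, one direction
#' only marks `a` one-way dependent on `b`.
#'
#' @param transform a `cs_transform` from [assemble_transform()].
#' @return character relation matrix in the same format as
#'   [classify_from_lattice()].
#' @export
classify_from_blocks <- function(transform) {
  Q <- transform$Q
  dep <- matrix(FALSE, Q, Q)
  for (b in transform$blocks) {
    m <- length(b$rows)
    reach <- b$pattern | diag(TRUE, m)
    for (i in seq_len(m))                       # transitive closure
      reach <- reach | (reach %*% reach > 0)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i == j || !reach[i, j]) next
      a <- transform$row_cluster[b$rows[i]]
      bb <- transform$row_cluster[b$rows[j]]
      if (a != bb) dep[a, bb] <- TRUE
    }
    # rows of two clusters in one block with any connection at all:
    # a perturbation pattern mixing both clusters lives in this block, so
    # the clusters' stability problems are coupled through it
  }
  relation_matrix(dep, transform$partition)
}
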