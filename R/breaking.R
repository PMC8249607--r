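#' Intertwining index of a cluster between two balanced partitions
#'
#' Counts the clusters of `base`, other than `C_q`, that are split in
#' `refined`. The pair is meaningful only when `C_q` itself is split.
#'
#' @param base a `node_partition` (the reference, usually minimal,
#'   partition).
#' @param refined a `node_partition` refining `base`.
#' @param q index of the cluster of `base` whose breaking is considered.
#' @return nonnegative integer.
#' @export
intertwining_index <- function(base, refined, q) {
  if (!refines(refined, base)) stop("'refined' must refine 'base'")
  if (q < 1 || q > n_clusters(base)) stop("cluster index q out of range")
  mf <- partition_membership(refined)
  split <- vapply(base$clusters, function(cl) length(unique(mf[cl])) > 1,
                  logical(1))
  if (!split[q])
    stop(sprintf("cluster %d is not broken in the refined partition; the pair is meaningless", q))
  sum(split[-q])
}

# which base clusters split in each lattice member (logical members x Q)
split_table <- function(lattice) {
  base <- lattice$partitions[[1]]
  Q <- n_clusters(base)
  S <- vapply(lattice$partitions, function(p) {
    m <- partition_membership(p)
    vapply(base$clusters, function(cl) length(unique(m[cl])) > 1, logical(1))
  }, logical(Q))
  matrix(S, ncol = Q, byrow = TRUE)   # robust for Q = 1
}

#' Breaking vectors of a cluster
#'
#' For each lattice member in which cluster `q` of the base partition is
#' broken, returns the pattern describing how `C_q` splits into
#' subclusters: a length-N vector that is zero outside `C_q` and constant
#' on each subcluster, with labels assigned in order of first appearance
#' (so equivalent labelings collapse to one canonical pattern). Each record
#' also carries the intertwining index of the transition.
#'
#' @param lattice a `partition_lattice` (base partition first).
#' @param q cluster index in the base partition.
#' @return list of `breaking_vector` records with fields `cluster_index`,
#'   `partition_index` (position of the member in the lattice, base = 1),
#'   `pattern` (integer vector, 0 outside `C_q`), `pattern_key`, `index`.
#' @export
breaking_vectors <- function(lattice, q) {
  base <- lattice$partitions[[1]]
  if (q < 1 || q > n_clusters(base)) stop("cluster index q out of range")
  cl <- base$clusters[[q]]
  out <- list()
  for (j in seq_along(lattice$partitions)[-1]) {
    p <- lattice$partitions[[j]]
    if (!refines(p, base)) next
    m <- partition_membership(p)
    sub <- m[cl]
    if (length(unique(sub)) < 2) next
    labels <- match(sub, unique(sub))    # first-appearance canonical form
    pattern <- integer(base$n_nodes)
    pattern[cl] <- labels
    out[[length(out) + 1]] <- structure(
      list(cluster_index = q, partition_index = j, pattern = pattern,
           pattern_key = paste(labels, collapse = ""),
           index = intertwining_index(base, p, q)),
      class = "breaking_vector")
  }
  out
}

#' @export
print.breaking_vector <- function(x, ...) {
  lab <- c("0", letters)[x$pattern + 1]
  cat(sprintf("breaking vector (cluster %d, lattice member %d): [%s], index %d\n",
              x$cluster_index, x$partition_index,
              paste(lab, collapse = " "), x$index))
  invisible(x)
}

#' Classify cluster interdependencies from the balanced-partition lattice
#'
#' Cluster `a` depends on cluster `b` when `b` breaks somewhere in the
#' lattice and every lattice member that breaks `b` also breaks `a` (the
#' desynchronization of `b` forces that of `a`). Mutual dependence makes a
#' pair intertwined, one direction only makes it one-way dependent, neither
#' makes it independent.
#'
#' @param lattice a `partition_lattice` whose base partition is the
#'   reference.
#' @return character matrix `rel` with `rel[a, b]` in `"independent"`,
#'   `"intertwined"`, `"one-way-dependent"` (meaning: `C_a` is one-way
#'   dependent on `C_b`); diagonal `"self"`.
#' @export
classify_from_lattice <- function(lattice) {
  S <- split_table(lattice)
  Q <- ncol(S)
  dep <- matrix(FALSE, Q, Q)
  for (a in seq_len(Q)) for (b in seq_len(Q)) {
    if (a == b) next
    dep[a, b] <- any(S[, b]) && all(S[S[, b], a])
  }
  relation_matrix(dep, lattice$partitions[[1]])
}

relation_matrix <- function(dep, base) {
  Q <- nrow(dep)
  rel <- matrix("independent", Q, Q)
  diag(rel) <- "self"
  for (a in seq_len(Q)) for (b in seq_len(Q)) {
    if (a == b) next
    if (dep[a, b] && dep[b, a]) rel[a, b] <- "intertwined"
    else if (dep[a, b]) rel[a, b] <- "one-way-dependent"
  }
  lab <- vapply(base$clusters, function(cl)
    paste0("C{", paste(cl, collapse = ","), "}"), character(1))
  dimnames(rel) <- list(lab, lab)
  rel
}
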