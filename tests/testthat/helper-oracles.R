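# Independent brute-force oracles, kept deliberately naive and separate from
# the package's code paths.

# all set partitions of a vector (exponential; for tiny n only)
oracle_set_partitions <- function(items) {
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

# naive balance check written against the definition, element by element
oracle_is_balanced <- function(net, clusters) {
  for (cl in clusters)
    if (length(unique(net$node_types[cl])) > 1) return(FALSE)
  for (ly in net$layers) {
    A <- ly$adjacency
    for (Cp in clusters) for (Cq in clusters) {
      sums <- vapply(Cp, function(i) sum(A[i, Cq]), numeric(1))
      if (max(sums) - min(sums) > 1e-9) return(FALSE)
    }
  }
  TRUE
}

oracle_enumerate <- function(net) {
  parts <- oracle_set_partitions(seq_len(net$n_nodes))
  Filter(function(p) oracle_is_balanced(net, p), parts)
}

canon_key <- function(clusters) {
  cl <- lapply(clusters, sort)
  cl <- cl[order(vapply(cl, min, numeric(1)))]
  paste(vapply(cl, paste, character(1), collapse = ","), collapse = "|")
}

lattice_keys <- function(lattice)
  sort(vapply(lattice$partitions, clustersync:::partition_key, character(1)))

# small fixture: a fresh copy of the 5-node example per call
fig2 <- function() fig2_network()

new_lattice_for_test <- function(net, base_clusters) {
  balanced_refinements_below(net,
                             as_partition(base_clusters[[1]], net$n_nodes))
}

expect_partition_equal <- function(part, clusters) {
  expect_identical(clustersync:::partition_key(part),
                   canon_key(clusters))
}
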