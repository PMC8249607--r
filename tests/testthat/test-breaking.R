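fig2_lattice <- function() enumerate_balanced_partitions(fig2(), "bruteforce")

test_that("intertwining indices reproduce the known table", {
  P <- as_partition(list(1:2, 3:5), 5)
  P1 <- as_partition(list(1:2, 3, 4:5), 5)
  P5 <- as_partition(list(1, 2, c(3, 5), 4), 5)
  expect_identical(intertwining_index(P, P1, 2), 0L)
  expect_identical(intertwining_index(P, P5, 1), 1L)
  expect_identical(intertwining_index(P, P5, 2), 1L)
  # refinement only inside C_q leaves the others untouched
  P4 <- as_partition(list(1:2, 3, 4, 5), 5)
  expect_identical(intertwining_index(P, P4, 2), 0L)
  # meaningless pair: C_1 does not break in P1
  expect_error(intertwining_index(P, P1, 1), "meaningless")
  expect_error(intertwining_index(P1, P, 2), "refine")
})

test_that("breaking vectors carry canonical patterns and indices", {
  lat <- fig2_lattice()
  bv2 <- breaking_vectors(lat, 2)
  expect_length(bv2, 6)
  keys <- vapply(bv2, `[[`, character(1), "pattern_key")
  idx <- vapply(bv2, `[[`, integer(1), "index")
  # canonical (first-appearance) patterns over nodes 3,4,5 with their
  # intertwining indices, as multisets
  tab <- sort(paste(keys, idx))
  expect_identical(tab, sort(c("122 0", "112 0", "121 0", "123 0",
                               "121 1", "123 1")))
  # zero outside the cluster, at least two labels inside
  for (b in bv2) {
    expect_identical(b$pattern[1:2], c(0L, 0L))
    expect_gte(length(unique(b$pattern[3:5])), 2)
  }
  bv1 <- breaking_vectors(lat, 1)
  expect_length(bv1, 2)
  expect_identical(vapply(bv1, `[[`, integer(1), "index"), c(1L, 1L))
})

test_that("singleton clusters yield no breaking vectors", {
  net <- violin_ring("arrowhead")
  lat <- enumerate_balanced_partitions(net, "bruteforce")
  # cluster {1} of the minimal partition is trivial
  q1 <- which(vapply(lat$partitions[[1]]$clusters, identical, logical(1),
                     1L))
  expect_length(breaking_vectors(lat, q1), 0)
})

test_that("lattice classification reproduces the known relations", {
  rel <- classify_from_lattice(fig2_lattice())
  expect_identical(rel[2, 1], "one-way-dependent")  # C2 depends on C1
  expect_identical(rel[1, 2], "independent")
  # two disconnected identical motifs -> independent clusters
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1
  net <- multilayer_network(4, rep("a", 4), list(layer(A)))
  lat <- new_lattice_for_test(net, list(list(1:2, 3:4)))
  rel2 <- classify_from_lattice(lat)
  expect_identical(rel2[1, 2], "independent")
  expect_identical(rel2[2, 1], "independent")
})

test_that("neuron-layer clusters are mutually dependent (intertwined)", {
  net <- neuron_two_layer()
  lat <- enumerate_balanced_partitions(net, "seeded_closure")
  rel <- classify_from_lattice(lat)
  expect_identical(unname(rel[1, 2]), "intertwined")
  expect_identical(unname(rel[2, 1]), "intertwined")
})

test_that("intertwining indices are monotone along refinement chains", {
  for (net in list(fig2(), violin_ring("arrowhead"))) {
    lat <- enumerate_balanced_partitions(net, "bruteforce")
    base <- lat$partitions[[1]]
    for (q in seq_along(base$clusters)) {
      bv <- breaking_vectors(lat, q)
      for (a in bv) for (b in bv) {
        pa <- lat$partitions[[a$partition_index]]
        pb <- lat$partitions[[b$partition_index]]
        if (refines(pb, pa) && a$partition_index != b$partition_index)
          expect_gte(b$index, a$index)
      }
    }
  }
})
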