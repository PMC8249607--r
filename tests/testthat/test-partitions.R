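test_that("balance checking matches the definition on the 5-node example", {
  net <- fig2()
  expect_true(is_balanced(net, as_partition(list(1:2, 3:5), 5)))
  expect_true(is_balanced(net, singleton_partition(5)))
  # frozen from the element-by-element oracle: unequal inputs from {4, 5}
  expect_false(is_balanced(net, as_partition(list(1:3, 4:5), 5)))
  expect_false(is_balanced(net, as_partition(list(1:5), 5)))
  expect_error(is_balanced(net, as_partition(list(1:3), 3)), "cover")
})

test_that("balance respects node types", {
  A <- matrix(0, 2, 2)
  net <- multilayer_network(2, c("a", "b"), list(layer(A)))
  expect_false(is_balanced(net, as_partition(list(1:2), 2)))
})

test_that("minimal balanced coloring reproduces the known fixtures", {
  expect_partition_equal(minimal_balanced_coloring(fig2()),
                         list(1:2, 3:5))
  expect_partition_equal(minimal_balanced_coloring(neuron_two_layer()),
                         list(1:10, 11:20))
  expect_partition_equal(minimal_balanced_coloring(violin_ring("arrowhead")),
                         list(1, c(2, 8), c(3, 7), c(4, 6), 5))
  expect_partition_equal(minimal_balanced_coloring(violin_ring("undirected")),
                         list(1:8))
  expect_partition_equal(
    minimal_balanced_coloring(violin_ring("unidirectional")), list(1:8))
  zero <- multilayer_network(4, rep("a", 4), list(layer(matrix(0, 4, 4))))
  expect_partition_equal(minimal_balanced_coloring(zero), list(1:4))
})

test_that("coarsest refinement is idempotent and monotone w.r.t. its seed", {
  for (seed in 1:5) {
    net <- random_planted(c(3, 3, 2),
                          matrix(c(1, 2, 1, 0, 1, 1, 2, 0, 1), 3,
                                 byrow = TRUE), seed = seed)
    mc <- minimal_balanced_coloring(net)
    expect_true(is_balanced(net, mc))
    again <- minimal_balanced_coloring(net, mc)
    expect_identical(clustersync:::partition_key(again),
                     clustersync:::partition_key(mc))
    # every balanced partition refines the coarsest one
    lat <- enumerate_balanced_partitions(net, "bruteforce")
    for (p in lat$partitions) expect_true(refines(p, mc))
  }
})

test_that("bruteforce enumeration agrees with the naive oracle", {
  for (seed in c(7, 42)) {
    net <- random_planted(c(2, 4), matrix(c(1, 2, 1, 1), 2, byrow = TRUE),
                          seed = seed)
    lat <- enumerate_balanced_partitions(net, "bruteforce")
    oracle <- sort(vapply(oracle_enumerate(net), canon_key, character(1)))
    expect_identical(lattice_keys(lat), oracle)
  }
})

test_that("the 5-node example has exactly the seven known balanced partitions", {
  lat <- enumerate_balanced_partitions(fig2(), "bruteforce")
  expect_length(lat$partitions, 7)
  expect_identical(lattice_keys(lat),
                   sort(vapply(fig2_partitions(),
                               clustersync:::partition_key, character(1))))
})

test_that("seeded closure equals brute force on small networks", {
  nets <- list(fig2(), violin_ring("arrowhead"),
               violin_ring("unidirectional"))
  for (seed in c(1, 3)) {
    nets[[length(nets) + 1]] <-
      random_planted(c(3, 3), matrix(c(1, 1, 2, 1), 2, byrow = TRUE),
                     seed = seed)
    nets[[length(nets) + 1]] <-
      random_planted(c(5, 5), matrix(c(2, 1, 1, 2), 2, byrow = TRUE),
                     seed = seed)
  }
  for (net in nets) {
    bf <- enumerate_balanced_partitions(net, "bruteforce")
    sc <- enumerate_balanced_partitions(net, "seeded_closure")
    expect_identical(lattice_keys(sc), lattice_keys(bf))
  }
})

test_that("enumeration is refused beyond the bruteforce cutoff", {
  expect_error(enumerate_balanced_partitions(neuron_two_layer(),
                                             "bruteforce"),
               "seeded_closure")
})

test_that("lattices contain the singleton partition and only balanced members", {
  for (net in list(fig2(), violin_ring("arrowhead"))) {
    lat <- enumerate_balanced_partitions(net, "bruteforce")
    keys <- lattice_keys(lat)
    expect_true(clustersync:::partition_key(
      singleton_partition(net$n_nodes)) %in% keys)
    for (p in lat$partitions) expect_true(is_balanced(net, p))
  }
  one <- multilayer_network(1, "a", list(layer(matrix(0, 1, 1))))
  expect_length(enumerate_balanced_partitions(one, "bruteforce")$partitions, 1)
})

test_that("refinements below a partition are found exhaustively", {
  net <- fig2()
  base <- as_partition(list(1:2, 3:5), 5)
  lat <- balanced_refinements_below(net, base)
  expect_length(lat$partitions, 7)
  s <- singleton_partition(5)
  lat2 <- balanced_refinements_below(net, s)
  expect_length(lat2$partitions, 1)
})

test_that("quotient networks have representative-independent rows", {
  net <- fig2()
  part <- as_partition(list(1:2, 3:5), 5)
  qn <- quotient_network(net, part)
  expect_equal(qn$layers[[1]]$adjacency,
               matrix(c(1, 2, 1, 0), 2, byrow = TRUE))
  # all-singleton quotient is the network itself
  qs <- quotient_network(net, singleton_partition(5))
  expect_equal(qs$layers[[1]]$adjacency, net$layers[[1]]$adjacency)
  # neuron: intralayer ring wraps into a self-weight of 6
  nn <- neuron_two_layer()
  qn2 <- quotient_network(nn, as_partition(list(1:10, 11:20), 20))
  expect_equal(qn2$layers[[1]]$adjacency[1, 1], 6)
  expect_error(quotient_network(net, as_partition(list(1:3, 4:5), 5)),
               "not balanced")
})

test_that("planted partitions are balanced by construction", {
  for (seed in 1:6) {
    net <- random_planted(c(2, 3, 4),
                          matrix(c(1, 1, 2, 1, 0, 2, 0, 3, 1), 3,
                                 byrow = TRUE), seed = seed)
    expect_true(is_balanced(net, attr(net, "partition")))
    lat <- enumerate_balanced_partitions(net, "bruteforce")
    expect_true(clustersync:::partition_key(attr(net, "partition")) %in%
                  lattice_keys(lat))
  }
  expect_error(random_planted(c(2, 2), matrix(c(3, 0, 0, 0), 2), seed = 1),
               "infeasible")
})
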