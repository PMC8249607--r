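fig2_transform <- function() {
  net <- fig2()
  assemble_transform(net, enumerate_balanced_partitions(net, "bruteforce"))
}

row_span_equal <- function(rows_a, rows_b, tol = 1e-9) {
  # same span: projecting one basis onto the other loses nothing
  pa <- t(rows_a) %*% solve(rows_a %*% t(rows_a)) %*% rows_a
  max(abs(rows_b %*% pa - rows_b)) < tol
}

test_that("per-cluster blocks reproduce the known contrast rows", {
  net <- fig2()
  lat <- enumerate_balanced_partitions(net, "bruteforce")
  T2 <- build_cluster_block(lat, 2)
  expect_equal(T2[1, ], c(0, 0, 1, 1, 1) / sqrt(3))
  expect_equal(abs(T2[2, ]), abs(c(0, 0, -1, 2, -1) / sqrt(6)))
  expect_equal(abs(T2[3, ]), abs(c(0, 0, -1, 0, 1) / sqrt(2)))
  T1 <- build_cluster_block(lat, 1)
  expect_equal(T1[1, ], c(1, 1, 0, 0, 0) / sqrt(2))
  expect_equal(abs(T1[2, ]), abs(c(1, -1, 0, 0, 0) / sqrt(2)))
  # a singleton cluster gets a single unit row
  lat_ah <- enumerate_balanced_partitions(violin_ring("arrowhead"),
                                          "bruteforce")
  q1 <- which(vapply(lat_ah$partitions[[1]]$clusters, identical,
                     logical(1), 1L))
  expect_equal(build_cluster_block(lat_ah, q1)[1, ],
               c(1, rep(0, 7)))
})

test_that("the assembled transformation matches the known matrix up to row sign and order", {
  tr <- fig2_transform()
  expected <- rbind(c(1, 1, 0, 0, 0) / sqrt(2),
                    c(0, 0, 1, 1, 1) / sqrt(3),
                    c(0, 0, -1, 2, -1) / sqrt(6),
                    c(1, -1, 0, 0, 0) / sqrt(2),
                    c(0, 0, -1, 0, 1) / sqrt(2))
  expect_true(row_span_equal(tr$T_par, expected[1:2, ]))
  # each transverse row spans the same line as one expected row
  for (r in 1:3) {
    matched <- any(vapply(3:5, function(e)
      row_span_equal(tr$T_perp[r, , drop = FALSE],
                     expected[e, , drop = FALSE]), logical(1)))
    expect_true(matched)
  }
})

test_that("the transverse block is one upper-triangular 2x2 block plus a 1x1 block", {
  tr <- fig2_transform()
  expect_length(tr$blocks, 2)
  expect_length(tr$blocks[[1]]$rows, 2)
  expect_length(tr$blocks[[2]]$rows, 1)
  # first block: a C2 perturbation driven by a C1 perturbation
  expect_identical(tr$row_cluster[tr$blocks[[1]]$rows], c(2L, 1L))
  Bp <- Reduce(`+`, tr$B_perp)
  b1 <- Bp[tr$blocks[[1]]$rows, tr$blocks[[1]]$rows]
  expect_lt(abs(b1[2, 1]), 1e-9)     # upper triangular
  expect_gt(abs(b1[1, 2]), 1e-9)
})

test_that("classification from blocks matches the known relations and the lattice route", {
  tr <- fig2_transform()
  rel <- classify_from_blocks(tr)
  expect_identical(rel[2, 1], "one-way-dependent")
  expect_identical(rel[1, 2], "independent")
  net <- neuron_two_layer()
  lat <- enumerate_balanced_partitions(net, "seeded_closure")
  rel2 <- classify_from_blocks(assemble_transform(net, lat))
  expect_identical(unname(rel2[1, 2]), "intertwined")
})

test_that("removing one interlayer direction gives one-way dependence in the right orientation", {
  # dropping ring->uncoupled arrows: the ring layer (cluster 1) drives
  # nothing, so the uncoupled layer's cluster depends on nothing; the ring
  # cluster is driven by the uncoupled layer
  # dropping one direction leaves the other layer's nodes free to split,
  # so the full lattice is astronomically large; a truncated breadth-first
  # closure (coarsest members first) suffices for the transform
  net_a <- neuron_two_layer(drop_II_to_I = TRUE)
  lat_a <- suppressWarnings(
    enumerate_balanced_partitions(net_a, "seeded_closure",
                                  max_partitions = 300))
  rel_a <- classify_from_blocks(assemble_transform(net_a, lat_a))
  expect_identical(unname(rel_a[1, 2]), "one-way-dependent")
  expect_identical(unname(rel_a[2, 1]), "independent")
  expect_identical(unname(classify_from_lattice(lat_a)[1, 2]),
                   "one-way-dependent")
  net_b <- neuron_two_layer(drop_I_to_II = TRUE)
  lat_b <- suppressWarnings(
    enumerate_balanced_partitions(net_b, "seeded_closure",
                                  max_partitions = 300))
  rel_b <- classify_from_blocks(assemble_transform(net_b, lat_b))
  expect_identical(unname(rel_b[2, 1]), "one-way-dependent")
  expect_identical(unname(rel_b[1, 2]), "independent")
})

test_that("orthonormality and the zero lower-left block hold on fixtures and random networks", {
  nets <- list(fig2(), violin_ring("undirected"), violin_ring("arrowhead"),
               violin_ring("unidirectional"), neuron_two_layer())
  lats <- c(lapply(nets[1:4], enumerate_balanced_partitions, "bruteforce"),
            list(enumerate_balanced_partitions(nets[[5]], "seeded_closure")))
  for (i in seq_along(nets)) {
    tr <- assemble_transform(nets[[i]], lats[[i]])
    expect_lt(max(abs(tr$T %*% t(tr$T) - diag(nets[[i]]$n_nodes))), 1e-9)
    for (ly in nets[[i]]$layers)
      expect_lt(max(abs(tr$T_perp %*% ly$adjacency %*% t(tr$T_par))), 1e-9)
  }
})

test_that("spectra are preserved and undirected networks give a vanishing coupling block", {
  net <- violin_ring("undirected")
  tr <- assemble_transform(net, enumerate_balanced_partitions(net,
                                                              "bruteforce"))
  A <- net$layers[[1]]$adjacency
  expect_lt(max(abs(sort(Re(eigen(tr$B[[1]])$values)) -
                      sort(Re(eigen(A)$values)))), 1e-8)
  # B12 = 0 for undirected networks
  Q <- tr$Q
  expect_lt(max(abs(tr$B[[1]][seq_len(Q), -seq_len(Q)])), 1e-9)
})

test_that("the all-singleton partition gives an empty transverse part", {
  net <- fig2()
  lat <- balanced_refinements_below(net, singleton_partition(5))
  tr <- assemble_transform(net, lat)
  expect_identical(nrow(tr$T_perp), 0L)
  expect_equal(tr$B[[1]][abs(tr$T) %*% (1:5), abs(tr$T) %*% (1:5)],
               net$layers[[1]]$adjacency)
})
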