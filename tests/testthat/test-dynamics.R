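linear_pair <- function(a = 1, sigma = 1) {
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  net <- multilayer_network(2, c("x", "x"), list(layer(A, sigma = sigma)))
  dyn_system(net, list(x = linear_node(a)), list(diffusive_coupling()))
}

test_that("analytic derivatives match finite differences", {
  set.seed(1)
  for (model in list(linear_node(0.7), kuramoto_node(0.25),
                     neuron_node(alpha = 1.6), neuron_node(alpha = 1.7))) {
    for (rep in 1:5)
      expect_lt(derivative_error(model, x = rnorm(model$n)), 1e-5)
  }
  for (coup in list(diffusive_coupling(), sigmoid_coupling())) {
    for (rep in 1:5)
      expect_lt(derivative_error(coup, xi = rnorm(3), xj = rnorm(3)), 1e-5)
  }
  for (rep in 1:5)
    expect_lt(derivative_error(kuramoto_coupling(), xi = rnorm(1),
                               xj = rnorm(1)), 1e-5)
})

test_that("the chemical synapse sender derivative carries the sigmoid slope", {
  cp <- sigmoid_coupling(d = 2, lambda = 10, theta = -0.25)
  xj <- 0.3
  g <- 1 / (1 + exp(-10 * (xj + 0.25)))
  expect_equal(cp$D2(c(0.5, 0, 0), c(xj, 0, 0))[1, 1],
               (2 - 0.5) * 10 * g * (1 - g))
})

test_that("uncoupled phases advance linearly (closed form)", {
  net <- multilayer_network(3, rep("v", 3), list(layer(matrix(0, 3, 3),
                                                       sigma = 0)))
  sys <- dyn_system(net, list(v = kuramoto_node(0.25)),
                    list(kuramoto_coupling()))
  init <- c(0.3, 1.1, -0.4)
  traj <- direct_simulation(sys, init = init, t_record = 40, dt = 0.02,
                            record_every = 500)
  tl <- length(traj$times)
  expect_equal(traj$states[tl, ], init + 0.25 * traj$times[tl],
               tolerance = 1e-10)
  # phase differences constant
  expect_equal(diff(traj$states[tl, ]), diff(init), tolerance = 1e-10)
})

test_that("the linear diffusive pair reproduces the closed-form exponent", {
  sys <- linear_pair(a = 1, sigma = 1)
  lat <- enumerate_balanced_partitions(sys$net, "bruteforce")
  tr <- assemble_transform(sys$net, lat)
  r <- transverse_mle(sys, tr, 1, t_transient = 10, t_total = 50,
                      dt = 0.01, seed = 1)
  expect_equal(r$mle, -1, tolerance = 1e-3)     # a - 2 sigma
  # transformed variational matrices: eta' = (a - 2 sigma) eta
  traj <- integrate_quotient(sys, tr$partition, init = 1, t_record = 5,
                             dt = 0.01)
  vm <- variational_matrices(sys, tr, traj, 2)
  expect_equal(vm$Psi1[1, 1] + vm$Psi2[[1]][1, 1], -1, tolerance = 1e-9)
  # sweeping sigma crosses zero exactly at a / 2
  sw <- stability_sweep(sys, tr, "sigma1", seq(0.2, 0.8, 0.1),
                        t_transient = 10, t_total = 50, dt = 0.01, seed = 1)
  expect_equal(unname(sw$crossings[1]), 0.5, tolerance = 1e-3)
})

test_that("the in-phase ring exponent matches the Laplacian mode at zero delay", {
  sys <- violin_system("undirected", delay = 0)
  lat <- enumerate_balanced_partitions(sys$net, "bruteforce")
  tr <- assemble_transform(sys$net, lat)
  r <- cluster_mles(sys, tr, t_transient = 100, t_total = 500, dt = 0.02,
                    seed = 1, jitter = 0.05)
  expect_equal(max(r$block_mle), -0.2 * (1 - cos(2 * pi / 8)),
               tolerance = 1e-3)
})

test_that("block exponents match direct-simulation transverse growth rates", {
  # linear dynamics: the within-cluster spread evolves exactly under the
  # transverse variational equation, so its log-slope must equal the
  # largest block exponent
  for (case in list(list(sigma = 0.1, seed = 11),
                    list(sigma = 0.4, seed = 11),
                    list(sigma = 0.25, seed = 5))) {
    net <- random_planted(c(3, 3), matrix(c(1, 1, 2, 1), 2, byrow = TRUE),
                          seed = case$seed, sigma = case$sigma)
    part <- attr(net, "partition")
    sys <- dyn_system(net, list(node = linear_node(0.3)),
                      list(diffusive_coupling()))
    lat <- balanced_refinements_below(net, part)
    tr <- assemble_transform(net, lat)
    r <- cluster_mles(sys, tr, t_transient = 5, t_total = 60, dt = 0.01,
                      seed = 1)
    lam <- max(r$block_mle)
    set.seed(2)
    init <- cluster_state_init(sys, part, jitter = 0.3, seed = 2) +
      1e-6 * rnorm(6 * sys$n)
    traj <- direct_simulation(sys, init = init, t_record = 20, dt = 0.01,
                              record_every = 100)
    co <- vapply(seq_along(traj$times), function(i) {
      X <- matrix(traj$states[i, ], nrow = sys$n)
      max(vapply(part$clusters, function(cl)
        diff(range(X[1, cl])), numeric(1)))
    }, numeric(1))
    # fit after the perturbation has aligned with the leading direction
    late <- traj$times >= 8
    slope <- stats::coef(stats::lm(log(co[late]) ~ traj$times[late]))[2]
    expect_lt(abs(unname(slope) - lam), 0.05)
  }
})

test_that("per-cluster exponents agree inside an intertwined block", {
  sys <- neuron_system(sigma2 = 2)
  lat <- enumerate_balanced_partitions(sys$net, "seeded_closure")
  tr <- assemble_transform(sys$net, lat)
  r <- cluster_mles(sys, tr, t_transient = 500, t_total = 1500, dt = 0.02,
                    seed = 1)
  expect_equal(r$lambda[1], r$lambda[2])
})

test_that("step-size and divergence guards trigger", {
  sys <- violin_system("undirected", delay = 0.5)
  part <- minimal_balanced_coloring(sys$net)
  expect_error(integrate_quotient(sys, part, dt = 0.2), "delay")
  runaway <- linear_pair(a = 100, sigma = 0)
  expect_error(direct_simulation(runaway, init = c(1, 1), t_record = 30,
                                 dt = 0.1), "diverged")
})
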