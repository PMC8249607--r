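# Bridges between the R-level objects and the compiled RK4/DDE engine.

build_cpp_sys <- function(sys, part, tol = 1e-9) {
  qn <- quotient_network(sys$net, part, tol)
  reps <- vapply(part$clusters, `[`, integer(1), 1)
  models <- lapply(sys$net$node_types[reps], function(tp) sys$node_models[[tp]])
  list(Q = qn$n_nodes,
       n = sys$n,
       model_id = vapply(models, `[[`, integer(1), "id"),
       model_pars = lapply(models, `[[`, "pars"),
       sigma = vapply(qn$layers, `[[`, numeric(1), "sigma"),
       delay = vapply(qn$layers, `[[`, numeric(1), "delay"),
       coupling_id = vapply(sys$couplings, `[[`, integer(1), "id"),
       coupling_pars = lapply(sys$couplings, `[[`, "pars"),
       R = lapply(qn$layers, `[[`, "adjacency"))
}

check_dt <- function(sys, dt) {
  pos <- Filter(function(d) d > 0,
                vapply(sys$net$layers, `[[`, numeric(1), "delay"))
  if (length(pos) && dt > min(pos) / 10)
    stop(sprintf("dt = %g too large for smallest positive delay %g (need dt <= delay/10)",
                 dt, min(pos)))
  dt
}

default_dt <- function(sys, dt = NULL) {
  if (!is.null(dt)) return(check_dt(sys, dt))
  pos <- Filter(function(d) d > 0,
                vapply(sys$net$layers, `[[`, numeric(1), "delay"))
  check_dt(sys, min(0.02, if (length(pos)) min(pos) / 20 else Inf))
}

base_state <- function(model) {
  switch(as.character(model$id),
         "1" = 1,
         "2" = 0,
         "3" = c(0, 0, 5),
         stop("unknown model id"))
}

default_init <- function(sys, part, jitter = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  reps <- vapply(part$clusters, `[`, integer(1), 1)
  unlist(lapply(sys$net$node_types[reps], function(tp) {
    m <- sys$node_models[[tp]]
    base_state(m) + jitter * stats::rnorm(m$n)
  }))
}

#' Integrate the quotient network
#'
#' Integrates the synchronous cluster states `s_q(t)` of a balanced
#' partition with a fixed-step fourth-order Runge-Kutta scheme; delayed
#' interactions read a linearly interpolated history buffer whose
#' pre-history is the (constant) initial state.
#'
#' @param sys a [dyn_system()].
#' @param part a balanced `node_partition`.
#' @param init initial state, length `Q * n` (cluster-major); defaults to a
#'   per-cluster base state plus Gaussian jitter of size `jitter`.
#' @param t_transient time discarded before recording.
#' @param t_record recorded time span.
#' @param dt integration step; refused when larger than a tenth of the
#'   smallest positive delay.
#' @param record_every record every so many steps.
#' @param jitter,seed control the default initial state.
#' @return a `cs_trajectory`: list with `times`, `states`
#'   (rows = recorded times, columns = cluster-major state), `part`, `n`.
#' @export
integrate_quotient <- function(sys, part, init = NULL, t_transient = 0,
                               t_record = 100, dt = NULL, record_every = 1L,
                               jitter = 0.1, seed = NULL) {
  dt <- default_dt(sys, dt)
  cs <- build_cpp_sys(sys, part)
  if (is.null(init)) init <- default_init(sys, part, jitter, seed)
  res <- cpp_integrate(cs, as.numeric(init), t_transient, t_record, dt,
                       as.integer(record_every))
  structure(list(times = res$times, states = res$states, part = part,
                 n = sys$n, dt = dt), class = "cs_trajectory")
}

#' @export
print.cs_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d clusters x %d state vars, %d samples over t = [%g, %g]\n",
              n_clusters(x$part), x$n, length(x$times), min(x$times),
              max(x$times)))
  invisible(x)
}

#' Full-network simulation
#'
#' Same integrator as [integrate_quotient()] applied to the all-singletons
#' partition, i.e. the original N-node network.
#'
#' @inheritParams integrate_quotient
#' @param init length `N * n` initial state (node-major); the default adds
#'   independent jitter to every node, which does not respect any cluster
#'   structure.
#' @return a `cs_trajectory` over all N nodes.
#' @export
direct_simulation <- function(sys, init = NULL, t_transient = 0,
                              t_record = 100, dt = NULL, record_every = 1L,
                              jitter = 0.1, seed = NULL) {
  integrate_quotient(sys, singleton_partition(sys$net$n_nodes), init,
                     t_transient, t_record, dt, record_every, jitter, seed)
}

#' Initial state inside a synchrony subspace
#'
#' Lifts one state per cluster to the full network (all nodes of a cluster
#' start identical), optionally after jittering the per-cluster states;
#' used to select which synchronization pattern a multistable network
#' settles into.
#'
#' @param sys a [dyn_system()].
#' @param part the target balanced partition.
#' @param jitter per-cluster jitter magnitude.
#' @param seed RNG seed for the jitter.
#' @return numeric vector of length `N * n`.
#' @export
cluster_state_init <- function(sys, part, jitter = 0.1, seed = NULL) {
  qinit <- default_init(sys, part, jitter, seed)
  Q <- n_clusters(part); n <- sys$n
  qm <- matrix(qinit, nrow = n)
  full <- matrix(0, n, sys$net$n_nodes)
  mem <- partition_membership(part)
  for (i in seq_len(sys$net$n_nodes)) full[, i] <- qm[, mem[i]]
  as.numeric(full)
}

#' Within-cluster coherence of a trajectory
#'
#' For each cluster, the maximum over the recorded window of the maximum
#' pairwise state distance (sup norm) between its nodes.
#'
#' @param traj a full-network `cs_trajectory` (from [direct_simulation()]).
#' @param part partition whose clusters are diagnosed.
#' @param from use records with `times >= from` (default: second half).
#' @return numeric vector, one coherence value per cluster.
#' @export
cluster_coherence <- function(traj, part, from = NULL) {
  if (is.null(from)) from <- stats::median(traj$times)
  rows <- which(traj$times >= from)
  n <- traj$n
  vapply(part$clusters, function(cl) {
    if (length(cl) < 2) return(0)
    worst <- 0
    for (r in rows) {
      X <- matrix(traj$states[r, ], nrow = n)[, cl, drop = FALSE]
      worst <- max(worst, max(apply(X, 1, function(v) diff(range(v)))))
    }
    worst
  }, numeric(1))
}

interp_state <- function(traj, t) {
  tt <- traj$times
  if (t <= tt[1]) return(traj$states[1, ])
  if (t >= tt[length(tt)]) return(traj$states[length(tt), ])
  i <- findInterval(t, tt)
  w <- (t - tt[i]) / (tt[i + 1] - tt[i])
  (1 - w) * traj$states[i, ] + w * traj$states[i + 1, ]
}

#' Variational matrices at a time point
#'
#' Evaluates, in the transformed transverse coordinates, the instantaneous
#' matrix `Psi1(t)` (block-diagonal: isolated-node Jacobian plus the
#' receiver-side derivative of every incoming quotient interaction) and the
#' delayed matrices `Psi2^k(t)` (sender-side derivatives weighted by the
#' transverse blocks `B_perp^k`), so that the transverse perturbation obeys
#' `eta'(t) = Psi1 eta(t) + sum_k Psi2^k eta(t - delta_k)`.
#'
#' @param sys a [dyn_system()].
#' @param transform a `cs_transform` for the partition of interest.
#' @param traj quotient trajectory from [integrate_quotient()].
#' @param t evaluation time (delayed states are read at `t - delta_k`).
#' @return list with `Psi1` (`(m n) x (m n)`) and `Psi2` (list per layer).
#' @export
variational_matrices <- function(sys, transform, traj, t) {
  part <- transform$partition
  qn <- quotient_network(sys$net, part)
  n <- sys$n
  m <- nrow(transform$T_perp)
  reps <- vapply(part$clusters, `[`, integer(1), 1)
  models <- lapply(sys$net$node_types[reps], function(tp) sys$node_models[[tp]])
  s_now <- matrix(interp_state(traj, t), nrow = n)
  s_del <- lapply(qn$layers, function(ly)
    matrix(interp_state(traj, t - ly$delay), nrow = n))
  Psi1 <- matrix(0, m * n, m * n)
  for (r in seq_len(m)) {
    q <- transform$row_cluster[r]
    J <- models[[q]]$Df(s_now[, q])
    for (k in seq_along(qn$layers)) {
      R <- qn$layers[[k]]$adjacency
      for (q2 in seq_len(qn$n_nodes)) {
        if (R[q, q2] == 0) next
        J <- J + qn$layers[[k]]$sigma * R[q, q2] *
          sys$couplings[[k]]$D1(s_now[, q], s_del[[k]][, q2])
      }
    }
    idx <- (r - 1) * n + seq_len(n)
    Psi1[idx, idx] <- J
  }
  Psi2 <- lapply(seq_along(qn$layers), function(k) {
    M <- matrix(0, m * n, m * n)
    Bp <- transform$B_perp[[k]]
    for (r in seq_len(m)) for (l in seq_len(m)) {
      if (Bp[r, l] == 0) next
      qr <- transform$row_cluster[r]; ql <- transform$row_cluster[l]
      D2 <- sys$couplings[[k]]$D2(s_now[, qr], s_del[[k]][, ql])
      M[(r - 1) * n + seq_len(n), (l - 1) * n + seq_len(n)] <-
        qn$layers[[k]]$sigma * Bp[r, l] * D2
    }
    M
  })
  list(Psi1 = Psi1, Psi2 = Psi2)
}

#' Transverse maximum Lyapunov exponent of one irreducible block
#'
#' Co-integrates the quotient trajectory and the block-restricted
#' transverse variational equation (shared delay buffers), renormalizing
#' the perturbation to unit norm at fixed intervals (Benettin). The
#' exponent is the time-average of the log growth factors accumulated
#' after the transient; for delayed systems the norm is taken over the
#' current (non-history) perturbation state and the renormalization also
#' rescales the perturbation history.
#'
#' @param sys a [dyn_system()].
#' @param transform a `cs_transform`; its partition defines the quotient.
#' @param block index into `transform$blocks`.
#' @param init quotient initial state (default as in
#'   [integrate_quotient()]).
#' @param t_transient settling time before accumulation starts.
#' @param t_total accumulation time.
#' @param dt integration step.
#' @param renorm_interval time between renormalizations.
#' @param jitter,seed control default initial states (quotient and
#'   perturbation direction).
#' @return list with `mle`, `se` (standard error over the last half of the
#'   accumulation), `n_renorm`. An `mle` of `+Inf` flags non-finite growth.
#' @export
transverse_mle <- function(sys, transform, block = 1L, init = NULL,
                           t_transient = 500, t_total = 2000, dt = NULL,
                           renorm_interval = 1, jitter = 0.1, seed = NULL) {
  dt <- default_dt(sys, dt)
  part <- transform$partition
  cs <- build_cpp_sys(sys, part)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- default_init(sys, part, jitter)
  b <- transform$blocks[[block]]
  rows <- b$rows
  Bb <- lapply(transform$B_perp, function(bp) bp[rows, rows, drop = FALSE])
  eta0 <- stats::rnorm(length(rows) * sys$n)
  res <- cpp_mle(cs, as.numeric(init),
                 as.integer(transform$row_cluster[rows] - 1L), Bb,
                 eta0, dt, t_transient, t_total, renorm_interval)
  res[c("mle", "se", "n_renorm")]
}

#' Per-cluster transverse MLEs at the current parameters
#'
#' Computes the block MLEs of every irreducible transverse block and
#' assigns to each cluster the largest MLE among the blocks containing one
#' of its transverse perturbation rows.
#'
#' @inheritParams transverse_mle
#' @return list with `block_mle` (per block), `block_se`, and `lambda`
#'   (per cluster of the partition; `NA` for trivial clusters without
#'   transverse rows).
#' @export
cluster_mles <- function(sys, transform, init = NULL, t_transient = 500,
                         t_total = 2000, dt = NULL, renorm_interval = 1,
                         jitter = 0.1, seed = NULL) {
  nb <- length(transform$blocks)
  block_mle <- numeric(nb); block_se <- numeric(nb)
  for (b in seq_len(nb)) {
    r <- transverse_mle(sys, transform, b, init, t_transient, t_total, dt,
                        renorm_interval, jitter, seed)
    block_mle[b] <- r$mle; block_se[b] <- if (is.null(r$se)) NA_real_ else r$se
  }
  Q <- transform$Q
  lambda <- rep(NA_real_, Q)
  for (b in seq_len(nb)) {
    for (q in transform$blocks[[b]]$clusters)
      lambda[q] <- max(lambda[q], block_mle[b], na.rm = TRUE)
  }
  list(block_mle = block_mle, block_se = block_se, lambda = lambda)
}

#' Parameter sweep of transverse MLEs
#'
#' Recomputes the per-block and per-cluster transverse MLEs over a grid of
#' one scalar parameter (the transformation does not depend on coupling
#' strengths or delays, so it is assembled once), and locates the zero
#' crossing of each cluster's MLE curve by linear interpolation between
#' sign-changing neighbors.
#'
#' @inheritParams transverse_mle
#' @param parameter parameter name understood by [set_parameter()].
#' @param values numeric grid.
#' @return a `cs_sweep`: list with `parameter`, `values`, `lambda`
#'   (matrix values x clusters), `blocks` (matrix values x blocks),
#'   `crossings` (per cluster; `NA` when the curve does not change sign).
#' @export
stability_sweep <- function(sys, transform, parameter, values, init = NULL,
                            t_transient = 500, t_total = 2000, dt = NULL,
                            renorm_interval = 1, jitter = 0.1, seed = NULL) {
  Q <- transform$Q
  nb <- length(transform$blocks)
  lambda <- matrix(NA_real_, length(values), Q)
  blocks <- matrix(NA_real_, length(values), nb)
  for (i in seq_along(values)) {
    sysi <- set_parameter(sys, parameter, values[i])
    r <- cluster_mles(sysi, transform, init, t_transient, t_total, dt,
                      renorm_interval, jitter, seed)
    lambda[i, ] <- r$lambda
    blocks[i, ] <- r$block_mle
  }
  crossings <- apply(lambda, 2, function(lam) zero_crossing(values, lam))
  structure(list(parameter = parameter, values = values, lambda = lambda,
                 blocks = blocks, crossings = crossings),
            class = "cs_sweep")
}

zero_crossing <- function(x, y) {
  ok <- is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(y) < 2) return(NA_real_)
  z <- which(y == 0)
  if (length(z)) return(x[z[1]])
  s <- sign(y)
  i <- which(s[-1] * s[-length(s)] < 0)
  if (!length(i)) return(NA_real_)
  i <- i[1]
  x[i] + y[i] * (x[i + 1] - x[i]) / (y[i] - y[i + 1])
}

#' @export
print.cs_sweep <- function(x, ...) {
  cat(sprintf("MLE sweep of %s over [%g, %g] (%d points)\n", x$parameter,
              min(x$values), max(x$values), length(x$values)))
  for (q in seq_len(ncol(x$lambda)))
    cat(sprintf("  cluster %d: zero crossing %s\n", q,
                if (is.na(x$crossings[q])) "absent"
                else sprintf("at %s = %.3f", x$parameter, x$crossings[q])))
  invisible(x)
}

#' @export
plot.cs_sweep <- function(x, ...) {
  matplot(x$values, x$lambda, type = "l", lty = 1,
          xlab = x$parameter, ylab = "transverse MLE", ...)
  abline(h = 0, lty = 3)
  invisible(x)
}
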