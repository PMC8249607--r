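#' Node models
#'
#' Each node model carries the state dimension `n`, the isolated vector
#' field `f` and its Jacobian `Df`, plus the integer id and parameter
#' vector used by the compiled integrator. Three families are built in:
#'
#' * `linear_node(a)`: scalar `f(x) = a x`, used for closed-form checks.
#' * `kuramoto_node(omega)`: scalar phase oscillator `f(x) = omega`.
#' * `neuron_node(alpha, ...)`: three-variable bursting neuron with fast
#'   variables `x, y` and slow adaptation `z`:
#'   `dx = a x^2 - x^3 - y - z`, `dy = (a + alpha) x^2 - y`,
#'   `dz = c (b x - z + e)`.
#'
#' @param a,omega,alpha,b,c,e model parameters.
#' @return an object of class `node_model`.
#' @name node_models
NULL

new_node_model <- function(id, pars, n, f, Df, label) {
  structure(list(id = as.integer(id), pars = as.numeric(pars),
                 n = as.integer(n), f = f, Df = Df, label = label),
            class = "node_model")
}

#' @rdname node_models
#' @export
linear_node <- function(a) {
  new_node_model(1L, a, 1L,
                 f = function(x) a * x,
                 Df = function(x) matrix(a, 1, 1),
                 label = sprintf("linear(a=%g)", a))
}

#' @rdname node_models
#' @export
kuramoto_node <- function(omega = 0.25) {
  new_node_model(2L, omega, 1L,
                 f = function(x) omega,
                 Df = function(x) matrix(0, 1, 1),
                 label = sprintf("kuramoto(omega=%g)", omega))
}

#' @rdname node_models
#' @export
neuron_node <- function(alpha, a = 2.8, b = 9, c = 0.001, e = 5) {
  new_node_model(3L, c(a, alpha, b, c, e), 3L,
                 f = function(x) c(a * x[1]^2 - x[1]^3 - x[2] - x[3],
                                   (a + alpha) * x[1]^2 - x[2],
                                   c * (b * x[1] - x[3] + e)),
                 Df = function(x) matrix(c(2 * a * x[1] - 3 * x[1]^2, -1, -1,
                                           2 * (a + alpha) * x[1], -1, 0,
                                           c * b, 0, -c),
                                         3, 3, byrow = TRUE),
                 label = sprintf("neuron(alpha=%g)", alpha))
}

#' Coupling models
#'
#' Pairwise interaction functions `h^k(x_receiver, x_sender_delayed)` with
#' their partial derivatives, one per layer. Built-in families:
#'
#' * `diffusive_coupling()`: `h = x_j - x_i` on the first state component
#'   (electrical synapse / linear diffusion).
#' * `sigmoid_coupling(d, lambda, theta)`: chemical synapse
#'   `h = (d - x_i) / (1 + exp(-lambda (x_j - theta)))` on the first
#'   component; the `(d - x_i)` factor is part of the receiver dependence.
#' * `kuramoto_coupling()`: `h = sin(x_j - x_i)` for scalar phases.
#'
#' @param d reversal potential of the chemical synapse.
#' @param lambda,theta sigmoid slope and threshold.
#' @return an object of class `coupling_model`.
#' @name coupling_models
NULL

new_coupling <- function(id, pars, h, D1, D2, label) {
  structure(list(id = as.integer(id), pars = as.numeric(pars),
                 h = h, D1 = D1, D2 = D2, label = label),
            class = "coupling_model")
}

#' @rdname coupling_models
#' @export
diffusive_coupling <- function() {
  new_coupling(1L, numeric(0),
               h = function(xi, xj) { v <- numeric(length(xi)); v[1] <- xj[1] - xi[1]; v },
               D1 = function(xi, xj) { J <- matrix(0, length(xi), length(xi)); J[1, 1] <- -1; J },
               D2 = function(xi, xj) { J <- matrix(0, length(xi), length(xi)); J[1, 1] <- 1; J },
               label = "diffusive")
}

#' @rdname coupling_models
#' @export
sigmoid_coupling <- function(d = 2, lambda = 10, theta = -0.25) {
  g <- function(u) 1 / (1 + exp(-lambda * (u - theta)))
  new_coupling(2L, c(d, lambda, theta),
               h = function(xi, xj) { v <- numeric(length(xi)); v[1] <- (d - xi[1]) * g(xj[1]); v },
               D1 = function(xi, xj) { J <- matrix(0, length(xi), length(xi)); J[1, 1] <- -g(xj[1]); J },
               D2 = function(xi, xj) {
                 J <- matrix(0, length(xi), length(xi))
                 s <- g(xj[1]); J[1, 1] <- (d - xi[1]) * lambda * s * (1 - s); J
               },
               label = "sigmoid")
}

#' @rdname coupling_models
#' @export
kuramoto_coupling <- function() {
  new_coupling(3L, numeric(0),
               h = function(xi, xj) sin(xj[1] - xi[1]),
               D1 = function(xi, xj) matrix(-cos(xj[1] - xi[1]), 1, 1),
               D2 = function(xi, xj) matrix(cos(xj[1] - xi[1]), 1, 1),
               label = "kuramoto")
}

#' Bind a network to node and coupling models
#'
#' @param net a [multilayer_network()].
#' @param node_models named list mapping each node type appearing in
#'   `net$node_types` to a `node_model`; all models must share the same
#'   state dimension.
#' @param couplings list of `coupling_model` objects, one per layer.
#' @return an object of class `dyn_system`.
#' @export
dyn_system <- function(net, node_models, couplings) {
  types <- unique(net$node_types)
  if (!all(types %in% names(node_models)))
    stop("node_models must name every node type of the network")
  if (length(couplings) != length(net$layers))
    stop("need one coupling model per layer")
  ns <- vapply(node_models, `[[`, integer(1), "n")
  if (length(unique(ns)) != 1)
    stop("all node models must share one state dimension")
  structure(list(net = net, node_models = node_models,
                 couplings = couplings, n = unname(ns[1])),
            class = "dyn_system")
}

#' @export
print.dyn_system <- function(x, ...) {
  cat(sprintf("dynamical system: %d nodes, state dimension %d\n",
              x$net$n_nodes, x$n))
  for (t in names(x$node_models))
    cat(sprintf("  type %-8s -> %s\n", t, x$node_models[[t]]$label))
  for (k in seq_along(x$couplings))
    cat(sprintf("  layer %d coupling: %s (sigma=%g, delay=%g)\n", k,
                x$couplings[[k]]$label, x$net$layers[[k]]$sigma,
                x$net$layers[[k]]$delay))
  invisible(x)
}

#' Set a named scalar parameter of a system
#'
#' Recognized names: `"sigma<k>"` and `"delta<k>"` for the strength and
#' delay of layer `k` (e.g. `"sigma2"`).
#'
#' @param sys a `dyn_system`.
#' @param parameter parameter name.
#' @param value new value.
#' @return the modified system.
#' @export
set_parameter <- function(sys, parameter, value) {
  m <- regmatches(parameter, regexec("^(sigma|delta)([0-9]+)$", parameter))[[1]]
  if (length(m) != 3)
    stop(sprintf("unknown parameter '%s' (use sigma<k> or delta<k>)", parameter))
  k <- as.integer(m[3])
  if (k < 1 || k > length(sys$net$layers))
    stop(sprintf("layer %d out of range", k))
  field <- if (m[2] == "sigma") "sigma" else "delay"
  sys$net$layers[[k]][[field]] <- value
  sys
}

#' Finite-difference check of model derivatives
#' @param model a `node_model` or `coupling_model`.
#' @param x,xi,xj evaluation points.
#' @param h finite-difference step.
#' @return maximum absolute deviation between analytic and numeric
#'   derivative.
#' @keywords internal
#' @export
derivative_error <- function(model, x = NULL, xi = NULL, xj = NULL, h = 1e-6) {
  fd <- function(f, x0) {
    n <- length(f(x0))
    J <- matrix(0, n, length(x0))
    for (j in seq_along(x0)) {
      e <- numeric(length(x0)); e[j] <- h
      J[, j] <- (f(x0 + e) - f(x0 - e)) / (2 * h)
    }
    J
  }
  if (inherits(model, "node_model"))
    return(max(abs(fd(model$f, x) - model$Df(x))))
  d1 <- max(abs(fd(function(u) model$h(u, xj), xi) - model$D1(xi, xj)))
  d2 <- max(abs(fd(function(u) model$h(xi, u), xj) - model$D2(xi, xj)))
  max(d1, d2)
}
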