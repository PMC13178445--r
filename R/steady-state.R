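#' Steady state of a machine network
#'
#' Solves the unique stationary distribution of the master equation and derives
#' the full set of steady-state observables: state probabilities `pi`, per-edge
#' symmetric traffics `tau = pi_i k_ij + pi_j k_ji`, antisymmetric net fluxes
#' `jnet = pi_i k_ij - pi_j k_ji`, one-way fluxes `p_fwd`/`p_bwd = (tau +- J)/2`,
#' the fundamental cycle fluxes on the chords of the deterministic spanning-tree
#' basis, and the entropy production rate.
#'
#' The stationary distribution is obtained from the null space of the dense
#' generator (networks here have at most a handful of states, so exactness wins
#' over scalability). A second small singular value signals a numerically
#' non-ergodic generator and is an error.
#'
#' On a non-invertible edge the backward one-way flux is exactly zero, so its
#' traffic equals its net flux.
#'
#' @param net a `machine_network`.
#' @param basis optional precomputed `cycle_basis(net)`.
#' @param tol relative tolerance separating the null singular value from the
#'   rest of the spectrum (default 1e-10).
#' @return an object of class `steady_state` with elements `pi`, `tau`, `jnet`,
#'   `p_fwd`, `p_bwd` (named by edge id), `j_cycle` (named by chord id), `epr`,
#'   and the `basis` used.
#' @export
steady_state <- function(net, basis = NULL, tol = 1e-10) {
  stopifnot(inherits(net, "machine_network"))
  if (is.null(basis)) basis <- cycle_basis(net)
  Q <- .generator(net)
  pi <- .solve_pi(Q, tol = tol)
  edges <- net$edges
  p_fwd <- pi[edges$tail] * edges$k_fwd
  p_bwd <- pi[edges$head] * edges$k_bwd
  names(p_fwd) <- names(p_bwd) <- edges$id
  tau <- p_fwd + p_bwd
  jnet <- p_fwd - p_bwd
  j_cycle <- jnet[basis$chords]
  fc <- .cycle_forces(net, basis)
  epr <- if (length(j_cycle)) sum(j_cycle * 2 * fc) else 0
  if (!is.finite(epr)) {
    stop("entropy production rate is undefined: a cycle force is not finite ",
         "(degenerate cycle through a non-invertible edge)")
  }
  structure(list(pi = pi, tau = tau, jnet = jnet, p_fwd = p_fwd, p_bwd = p_bwd,
                 j_cycle = j_cycle, epr = epr, basis = basis,
                 network = net$name),
            class = "steady_state")
}

# null space of the generator transpose via SVD, with ergodicity diagnostics
.solve_pi <- function(Q, tol = 1e-10) {
  n <- nrow(Q)
  s <- svd(t(Q))
  d <- s$d
  scale <- max(d)
  if (d[n] > tol * scale) {
    stop("generator has no numerical null vector at tolerance ", tol)
  }
  if (n >= 2L && d[n - 1L] <= tol * scale) {
    stop("generator null space is not one-dimensional at tolerance ", tol,
         " (near-non-ergodic input)")
  }
  v <- s$v[, n]
  pi <- v / sum(v)
  if (any(pi <= 0)) {
    stop("stationary distribution has non-positive entries ",
         "(near-non-ergodic input)")
  }
  names(pi) <- rownames(Q)
  pi
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("steady_state of '%s'\n", x$network))
  cat("pi:\n"); print(round(x$pi, 6))
  df <- data.frame(edge = names(x$tau), tau = x$tau, jnet = x$jnet,
                   p_fwd = x$p_fwd, p_bwd = x$p_bwd, row.names = NULL)
  print(df, row.names = FALSE, digits = 6)
  if (length(x$j_cycle)) {
    cat("cycle fluxes (chords):\n"); print(round(x$j_cycle, 8))
  }
  cat(sprintf("entropy production rate: %.8g\n", x$epr))
  invisible(x)
}

#' @export
summary.steady_state <- function(object, ...) {
  kirchhoff <- max(abs(.node_flux_residual(object)))
  cat(sprintf("steady_state: %d states, %d edges, %d chords\n",
              length(object$pi), length(object$tau), length(object$j_cycle)))
  cat(sprintf("max |node flux residual|: %.3g\n", kirchhoff))
  cat(sprintf("EPR: %.8g\n", object$epr))
  invisible(object)
}

# per-node signed sums of incident net fluxes (should vanish at stationarity)
.node_flux_residual <- function(ss) {
  edges <- ss$basis$edges
  res <- numeric(length(ss$basis$states))
  names(res) <- ss$basis$states
  for (e in seq_len(nrow(edges))) {
    res[edges$tail[e]] <- res[edges$tail[e]] - ss$jnet[[e]]
    res[edges$head[e]] <- res[edges$head[e]] + ss$jnet[[e]]
  }
  res
}

#' Entropy production rate
#'
#' The cycle-flux form of the entropy production rate,
#' `EPR = sum_c J_c * 2 F_cycle,c` over the chords of the spanning-tree basis.
#' On fully reversible networks this equals the edge-wise form
#' `sum_edges J_ij ln(pi_i k_ij / (pi_j k_ji))` (use `form = "edgewise"` to get
#' that independent evaluation); on networks with a non-invertible catalytic
#' edge only the cycle form is defined, with the catalytic chord's force taken
#' from its `ln k_cat` contribution.
#'
#' @param net a `machine_network`.
#' @param ss its `steady_state`.
#' @param form `"cycle"` (default) or `"edgewise"` (reversible networks only).
#' @return the entropy production rate (kT per unit time), non-negative.
#' @export
entropy_production_rate <- function(net, ss, form = c("cycle", "edgewise")) {
  form <- match.arg(form)
  if (form == "cycle") {
    fc <- .cycle_forces(net, ss$basis)
    return(if (length(ss$j_cycle)) sum(ss$j_cycle * 2 * fc) else 0)
  }
  if (any(!net$edges$reversible)) {
    stop("edge-wise EPR is undefined on networks with non-invertible edges")
  }
  sum(ss$jnet * log(ss$p_fwd / ss$p_bwd))
}
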