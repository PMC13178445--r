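# Flow response rules: node energies scale fluxes, kinetic barriers route them.
#
# Knobs are defined operationally on rates (so any network is tunable, whether
# or not it was written in Arrhenius form):
#   * raising node energy E_n by delta multiplies every rate leaving n by
#     exp(+delta);
#   * raising barrier B_ij by delta multiplies both k_ij and k_ji by
#     exp(-delta).
#
# Analytic responses are computed by implicit differentiation of the master
# equation through the generator's deviation matrix
#   D = (1 pi' - Q)^{-1} - 1 pi',
# which yields, for a barrier perturbation on edge e = (i,j),
#   d pi / dB_e = J_e (D[i, ] - D[j, ]),
# i.e. exactly the advertised structure: every response is the edge's net flux
# J_ij times an element of an inverse matrix, so a zero-flux (dead-end) edge
# routes nothing.

#' Parse an observable specification
#'
#' Observables are written as strings: `"prob:STATE"`, `"traffic:EDGE"`,
#' `"netflux:EDGE"`, `"cycleflux:CHORD"` or `"epr"`.
#' @noRd
.parse_obs <- function(observable) {
  if (identical(observable, "epr")) return(list(type = "epr", id = NA))
  parts <- strsplit(observable, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L ||
      !parts[1L] %in% c("prob", "traffic", "netflux", "cycleflux")) {
    stop("unknown observable: ", observable,
         " (use prob:STATE, traffic:EDGE, netflux:EDGE, cycleflux:CHORD, epr)")
  }
  list(type = parts[1L], id = parts[2L])
}

.obs_value <- function(ss, obs) {
  o <- .parse_obs(obs)
  switch(o$type,
         epr = ss$epr,
         prob = ss$pi[[o$id]],
         traffic = ss$tau[[o$id]],
         netflux = ss$jnet[[o$id]],
         cycleflux = ss$j_cycle[[o$id]])
}

.obs_is_flux <- function(obs) {
  .parse_obs(obs)$type %in% c("traffic", "netflux", "cycleflux", "epr")
}

# deviation matrix of the generator: D = (1 pi' - Q)^{-1} - 1 pi'
.deviation_matrix <- function(net, ss) {
  Q <- .generator(net)
  Pi <- matrix(ss$pi, nrow(Q), ncol(Q), byrow = TRUE,
               dimnames = dimnames(Q))
  solve(Pi - Q) - Pi
}

# stationary-distribution derivative for a barrier knob on one edge
.dpi_barrier <- function(net, ss, edge, D = NULL) {
  e <- match(edge, net$edges$id)
  if (is.na(e)) stop("unknown edge: ", edge)
  if (is.null(D)) D <- .deviation_matrix(net, ss)
  i <- net$edges$tail[e]; j <- net$edges$head[e]
  ss$jnet[[edge]] * (D[i, ] - D[j, ])
}

#' Node-energy response (flux scaling rule)
#'
#' Node-energy perturbations isotropically scale every flux-type observable:
#' `d(phi)/dE_n = pi_n * phi` for any edge traffic, cycle flux or linear
#' combination thereof, and likewise `d(EPR)/dE_n = pi_n * EPR` (cycle forces
#' are invariant under node-energy changes). Consequently flux *ratios* are
#' untouched by node energies: they shift state occupancies but cannot re-route
#' flows.
#'
#' On a network with non-invertible (catalytic) edges the EPR rule gains
#' extra terms: a catalytic chord's cycle force carries `ln k_cat` with no
#' compensating reverse member, so its force is not energy-invariant and
#' `d(EPR)/dE_n = pi_n EPR + sum_c 2 J_c dF_c/dE_n`, with `dF_c/dE_n` the
#' surviving endpoint half-terms around the irreversible member (verified
#' against the finite-difference oracle). On fully reversible networks all
#' `dF_c/dE_n` vanish and the plain scaling relation holds.
#'
#' Probabilities and forces are not covered by this scaling rule; requesting
#' them is an error directing the caller to [finite_difference_oracle()].
#'
#' @param net a `machine_network`.
#' @param ss its `steady_state`.
#' @param node state label whose energy is the knob.
#' @param observable observable string (see Details of
#'   [finite_difference_oracle()]); must be flux-type or `"epr"`.
#' @return the sensitivity `d(observable)/dE_n` (per kT).
#' @export
energy_response <- function(net, ss, node, observable) {
  stopifnot(inherits(net, "machine_network"), inherits(ss, "steady_state"))
  if (!node %in% net$states) stop("unknown state: ", node)
  if (!.obs_is_flux(observable)) {
    stop("observable '", observable, "' is not a flux observable; the ",
         "node-energy scaling rule does not apply - use ",
         "finite_difference_oracle()")
  }
  v <- ss$pi[[node]] * .obs_value(ss, observable)
  if (identical(.parse_obs(observable)$type, "epr") &&
      any(!net$edges$reversible)) {
    # cycle forces through a catalytic chord are not energy-invariant (the
    # ln k_cat member has no compensating reverse), so EPR picks up
    # sum_c 2 J_c dF_c/dE_n on top of the pi_n scaling
    for (ch in ss$basis$chords) {
      dF <- .cycle_force_energy_derivative(net, ss$basis, ch, node)
      if (dF != 0) v <- v + 2 * ss$j_cycle[[ch]] * dF
    }
  }
  v
}

# derivative of one chord's cycle-completion force with respect to a node
# energy; identically zero for fully reversible cycles (the half log-ratios
# telescope), +-1/2 endpoint terms survive around a non-invertible member
.cycle_force_energy_derivative <- function(net, basis, chord, node) {
  mem <- .cycle_members(basis, chord)
  d <- 0
  for (r in seq_len(nrow(mem))) {
    e <- match(mem$id[r], net$edges$id)
    ti <- net$edges$tail[e]; hi <- net$edges$head[e]
    if (net$edges$reversible[e]) {
      d <- d + mem$sign[r] * 0.5 * ((ti == node) - (hi == node))
    } else {
      d <- d + mem$sign[r] * (ti == node)
    }
  }
  d
}

#' Kinetic-barrier response (flux routing rule)
#'
#' Analytic sensitivity of an observable to the kinetic barrier of one edge,
#' mediated by that edge's net flux: every response is `J_ij` times an element
#' of an inverse matrix derived from the generator, so edges with zero net flux
#' (dead ends) leave all other observables exactly invariant.
#'
#' The perturbed edge's *own traffic* carries an additional non-routing term
#' and is deliberately computed by the finite-difference oracle instead (with a
#' warning). The perturbed edge's own net flux (and hence its chord's cycle
#' flux) is covered analytically; for the two-state unicycle this reproduces
#' the closed forms `d ln Jc/dB_T = -Sigma_D/Sigma` and
#' `d ln Jc/dB_D = -Sigma_T/Sigma`.
#'
#' @inheritParams energy_response
#' @param edge edge id whose barrier is the knob.
#' @return the sensitivity `d(observable)/dB_ij` (per kT).
#' @export
barrier_response <- function(net, ss, edge, observable) {
  stopifnot(inherits(net, "machine_network"), inherits(ss, "steady_state"))
  e <- match(edge, net$edges$id)
  if (is.na(e)) stop("unknown edge: ", edge)
  o <- .parse_obs(observable)
  if (o$type == "traffic" && identical(o$id, edge)) {
    warning("own-traffic barrier response has an additional non-routing ",
            "term; returning the finite-difference oracle value")
    return(finite_difference_oracle(net, paste0("barrier:", edge), observable))
  }
  dpi <- .dpi_barrier(net, ss, edge)
  .obs_from_dpi(net, ss, dpi, o, knob_edge = edge)
}

# assemble d(observable) from d(pi), adding direct rate terms where the knob
# edge itself enters the observable (barrier: both rates scale by exp(-dB))
.obs_from_dpi <- function(net, ss, dpi, o, knob_edge) {
  edges <- net$edges
  dedge <- function(id, signed) {
    e <- match(id, edges$id)
    v <- edges$k_fwd[e] * dpi[[edges$tail[e]]] +
      (if (signed) -1 else 1) * edges$k_bwd[e] * dpi[[edges$head[e]]]
    if (identical(id, knob_edge)) {
      v <- v - (if (signed) ss$jnet[[id]] else ss$tau[[id]])
    }
    v
  }
  switch(o$type,
         prob = dpi[[o$id]],
         traffic = dedge(o$id, signed = FALSE),
         netflux = dedge(o$id, signed = TRUE),
         cycleflux = dedge(o$id, signed = TRUE),
         epr = {
           fc <- .cycle_forces(net, ss$basis)
           sum(2 * fc * vapply(ss$basis$chords, dedge, numeric(1),
                               signed = TRUE))
         })
}

#' Finite-difference response oracle
#'
#' Independent central-difference estimate of any sensitivity: the knob is
#' applied as a multiplicative exponential factor on the rates (see the module
#' comments), the steady state is re-solved on both sides, and the symmetric
#' difference quotient is returned. This is the verification path for every
#' analytic response rule in the package.
#'
#' @param net a `machine_network`.
#' @param knob `"energy:STATE"` or `"barrier:EDGE"`.
#' @param observable observable string: `"prob:STATE"`, `"traffic:EDGE"`,
#'   `"netflux:EDGE"`, `"cycleflux:CHORD"` or `"epr"`.
#' @param step half-width of the central difference (default 1e-6, balancing
#'   truncation against round-off for order-one rates).
#' @param richardson if `TRUE`, also evaluate at 10x the step and report the
#'   Richardson-extrapolated value and a consistency estimate.
#' @return the sensitivity; with `richardson = TRUE`, a list with elements
#'   `value`, `coarse`, `extrapolated`.
#' @export
finite_difference_oracle <- function(net, knob, observable, step = 1e-6,
                                     richardson = FALSE) {
  stopifnot(inherits(net, "machine_network"), step > 0)
  eval_at <- function(s) {
    net2 <- .apply_knob(net, knob, s)
    ss2 <- tryCatch(steady_state(net2),
                    error = function(err) stop("steady state failed at step ",
                                               s, ": ", conditionMessage(err)))
    .obs_value(ss2, observable)
  }
  central <- function(h) (eval_at(h) - eval_at(-h)) / (2 * h)
  v <- central(step)
  if (!richardson) return(v)
  v10 <- central(10 * step)
  list(value = v, coarse = v10, extrapolated = (100 * v - v10) / 99)
}

# apply a knob (energy:STATE by +s, barrier:EDGE by +s) to the rates
.apply_knob <- function(net, knob, s) {
  parts <- strsplit(knob, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || !parts[1L] %in% c("energy", "barrier")) {
    stop("unknown knob: ", knob, " (use energy:STATE or barrier:EDGE)")
  }
  edges <- net$edges
  kf <- edges$k_fwd; kb <- edges$k_bwd
  if (parts[1L] == "energy") {
    n <- parts[2L]
    if (!n %in% net$states) stop("unknown state: ", n)
    kf[edges$tail == n] <- kf[edges$tail == n] * exp(s)
    kb[edges$head == n] <- kb[edges$head == n] * exp(s)
  } else {
    e <- match(parts[2L], edges$id)
    if (is.na(e)) stop("unknown edge: ", parts[2L])
    kf[e] <- kf[e] * exp(-s)
    kb[e] <- kb[e] * exp(-s)
  }
  .with_rates(net, kf, kb)
}

#' Force-rate Jacobian
#'
#' The matrix `A[(ij), alpha] = k_ij dF_alpha/dk_ij` of partial derivatives of
#' every caliber force (node forces without the reference, edge forces on
#' reversible edges, cycle forces on chords) with respect to the logarithm of
#' every directed positive rate. Rows are directed rates (`"id+"`, `"id-"`),
#' columns are forces.
#'
#' The matrix is square by construction but *exactly rank-deficient*: each
#' cycle force is identically the signed sum of the edge forces around its
#' fundamental cycle, so the cycle columns are linear combinations of edge
#' columns and the rank is `(number of directed rates) - (number of chords)`.
#' The object therefore carries the rank, the reciprocal condition number and
#' a Moore-Penrose pseudo-inverse; the package's response rules
#' ([barrier_response()], [energy_response()]) are computed from the exact
#' generator-based kernel rather than by inverting this matrix.
#'
#' @param net a `machine_network`.
#' @param basis optional precomputed basis.
#' @param ref_node reference node for the node forces.
#' @return an object of class `response_matrix` with `jacobian`, `rank`,
#'   `rcond`, `pinv`.
#' @export
force_rate_jacobian <- function(net, basis = NULL, ref_node = net$states[1L]) {
  stopifnot(inherits(net, "machine_network"))
  if (is.null(basis)) basis <- cycle_basis(net)
  edges <- net$edges
  rev <- edges$reversible
  dir_lab <- c(paste0(edges$id, "+"),
               paste0(edges$id[rev], "-"))
  dir_edge <- c(edges$id, edges$id[rev])
  dir_fwd <- c(rep(TRUE, nrow(edges)), rep(FALSE, sum(rev)))
  dir_tail <- c(edges$tail, edges$head[rev])
  dir_k <- c(edges$k_fwd, edges$k_bwd[rev])
  ndir <- length(dir_lab)

  f_lab <- c(paste0("node:", setdiff(net$states, ref_node)),
             paste0("edge:", edges$id[rev]),
             paste0("cycle:", basis$chords))
  A <- matrix(0, ndir, length(f_lab), dimnames = list(dir_lab, f_lab))
  # node-force columns: +1/k for rates out of n, -1/k for rates out of ref
  for (n in setdiff(net$states, ref_node)) {
    col <- paste0("node:", n)
    A[dir_tail == n, col] <- 1 / dir_k[dir_tail == n]
    A[dir_tail == ref_node, col] <- -1 / dir_k[dir_tail == ref_node]
  }
  # edge-force columns: +-1/2 on the edge's two directions
  for (id in edges$id[rev]) {
    col <- paste0("edge:", id)
    A[dir_edge == id & dir_fwd, col] <- 0.5
    A[dir_edge == id & !dir_fwd, col] <- -0.5
  }
  # cycle-force columns: +-1/2 per cycle member direction; ln(kcat) term gives
  # coefficient 1 on a non-invertible chord's single direction
  for (ch in basis$chords) {
    col <- paste0("cycle:", ch)
    mem <- .cycle_members(basis, ch)
    for (r in seq_len(nrow(mem))) {
      id <- mem$id[r]; sgn <- mem$sign[r]
      e <- match(id, edges$id)
      if (edges$reversible[e]) {
        A[dir_edge == id & dir_fwd, col] <- A[dir_edge == id & dir_fwd, col] +
          0.5 * sgn
        A[dir_edge == id & !dir_fwd, col] <- A[dir_edge == id & !dir_fwd, col] -
          0.5 * sgn
      } else {
        A[dir_edge == id & dir_fwd, col] <- A[dir_edge == id & dir_fwd, col] +
          sgn
      }
    }
  }
  if (nrow(A) != ncol(A)) {
    stop("force/rate dimension mismatch: ", nrow(A), " directed rates vs ",
         ncol(A), " forces")
  }
  structure(list(jacobian = A,
                 rank = qr(A)$rank,
                 rcond = rcond(A),
                 pinv = MASS::ginv(A)),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("response_matrix: %d x %d, rank %d, rcond %.3g\n",
              nrow(x$jacobian), ncol(x$jacobian), x$rank, x$rcond))
  invisible(x)
}

#' Barrier-sensitivity sum rule
#'
#' Sums `d ln Jc / dB` over the edges of a chord's fundamental cycle. On a
#' unicyclic network the sum is exactly -1: raising every barrier by the same
#' amount rescales time, leaving the stationary distribution untouched and
#' multiplying every flux by a common factor. This is the cycle response
#' symmetry analogous to the flux-control summation theorem of metabolic
#' control analysis. On multicyclic networks the quantity is still computed
#' (summing over the chosen cycle's edges only) but flagged as outside the
#' unicyclic setting.
#'
#' @param net a `machine_network`.
#' @param ss its `steady_state`.
#' @param chord chord id; defaults to the single chord of a unicycle.
#' @return list with `sum`, `per_edge` (named sensitivities `d ln Jc/dB`), and
#'   `unicyclic`.
#' @export
sensitivity_sum_rule <- function(net, ss, chord = NULL) {
  basis <- ss$basis
  if (is.null(chord)) {
    if (length(basis$chords) != 1L) {
      stop("chord must be given explicitly on a multicyclic network")
    }
    chord <- basis$chords
  }
  unicyclic <- length(basis$chords) == 1L
  if (!unicyclic) {
    warning("the -1 sum rule is printed for unicyclic networks; ",
            "computing the cycle-restricted sum anyway")
  }
  jc <- ss$j_cycle[[chord]]
  if (abs(jc) < .Machine$double.eps * max(ss$tau)) {
    stop("cycle flux is zero (equilibrium cycle); d ln Jc is undefined - ",
         "absolute responses all vanish with J_ij = 0")
  }
  mem <- .cycle_members(basis, chord)
  per <- vapply(mem$id, function(id) {
    barrier_response(net, ss, id, paste0("cycleflux:", chord)) / jc
  }, numeric(1))
  list(sum = sum(per), per_edge = per, unicyclic = unicyclic)
}
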