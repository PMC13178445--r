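#' Caliber forces of a machine network
#'
#' Computes the conjugate affinities of the stationary dynamics: the
#' node-dwelling force per state, the edge-exchange force per reversible edge,
#' and the cycle-completion force per chord of the deterministic spanning-tree
#' basis.
#'
#' Conventions:
#' * `f_node[n] = sum over transitions out of the reference node m of 1/k -
#'   sum over transitions out of n of 1/k`. The sums run over individual
#'   outgoing rates, one reciprocal per directed transition (not reciprocals of
#'   total escape rates); the reference node's force is zero. Units of time.
#' * `f_edge[ij] = (1/2) ln(k_ij / k_ji)`, antisymmetric under direction
#'   reversal; undefined (and omitted) on non-invertible edges.
#' * `f_cycle[c] = (1/2) sum over the chord's fundamental cycle of
#'   ln(k_ij/k_ji)`, equivalently `sum over the cycle of arctanh(J_ij/tau_ij)`
#'   at steady state (the stationary-probability terms telescope around a
#'   cycle). For a non-invertible chord (catalytic edge) the chord's own
#'   contribution is `ln k_cat` instead of the half log-ratio, so e.g. the
#'   Michaelis-Menten catalytic cycle has
#'   `F_cat = ln k_cat + (1/2) ln(k_E,ES / k_ES,E)`.
#'
#' The cycle force is half the cycle affinity, so Local Detailed Balance fixes
#' `2 f_cycle = (delta_mu - w)/kT` for a cycle driven by free energy `delta_mu`
#' doing work `w`.
#'
#' @param net a `machine_network`.
#' @param ref_node reference state for the node forces (default: first-listed
#'   state).
#' @param basis optional precomputed `cycle_basis(net)`.
#' @return an object of class `caliber_forces` with `f_node`, `f_edge`,
#'   `f_cycle`, `ref_node`, `basis`.
#' @export
caliber_forces <- function(net, ref_node = net$states[1L], basis = NULL) {
  stopifnot(inherits(net, "machine_network"))
  if (!ref_node %in% net$states) stop("unknown reference node: ", ref_node)
  if (is.null(basis)) basis <- cycle_basis(net)
  edges <- net$edges

  # sum of reciprocal outgoing rates per state (one term per directed rate)
  inv_out <- numeric(length(net$states))
  names(inv_out) <- net$states
  for (e in seq_len(nrow(edges))) {
    inv_out[edges$tail[e]] <- inv_out[edges$tail[e]] + 1 / edges$k_fwd[e]
    if (edges$reversible[e]) {
      inv_out[edges$head[e]] <- inv_out[edges$head[e]] + 1 / edges$k_bwd[e]
    }
  }
  f_node <- inv_out[[ref_node]] - inv_out
  f_edge <- 0.5 * log(edges$k_fwd / edges$k_bwd)[edges$reversible]
  names(f_edge) <- edges$id[edges$reversible]
  f_cycle <- .cycle_forces(net, basis)
  structure(list(f_node = f_node, f_edge = f_edge, f_cycle = f_cycle,
                 ref_node = ref_node, basis = basis),
            class = "caliber_forces")
}

# cycle-completion force per chord; catalytic chords contribute ln(kcat)
.cycle_forces <- function(net, basis) {
  edges <- net$edges
  half_lr <- ifelse(edges$reversible,
                    0.5 * log(edges$k_fwd / edges$k_bwd),
                    log(edges$k_fwd))
  fc <- drop(basis$incidence %*% half_lr)
  names(fc) <- basis$chords
  fc
}

#' @export
print.caliber_forces <- function(x, ...) {
  cat("caliber_forces (reference node:", x$ref_node, ")\n")
  cat("node dwelling (time units):\n"); print(round(x$f_node, 6))
  if (length(x$f_edge)) {
    cat("edge exchange:\n"); print(round(x$f_edge, 6))
  }
  if (length(x$f_cycle)) {
    cat("cycle completion (chords):\n"); print(round(x$f_cycle, 6))
  }
  invisible(x)
}

#' Check Local Detailed Balance constraints
#'
#' For each constraint, compares the cycle's log rate-ratio sum (twice the
#' cycle-completion force) with its thermodynamic target
#' `(delta_mu - work)/kT`: the free energy consumed per completed cycle minus
#' the work it performs. A zero residual (within tolerance) means the cycle
#' satisfies Local Detailed Balance. Cycles through a non-invertible edge use
#' the catalytic `ln k_cat` form of the chord contribution.
#'
#' @param net a `machine_network`.
#' @param constraints data frame with columns `cycle_id` (chord id),
#'   `delta_mu`, `work` (kT units).
#' @param basis optional precomputed basis.
#' @return data frame with the affinity, target and residual per constraint.
#' @export
check_ldb <- function(net, constraints, basis = NULL) {
  stopifnot(inherits(net, "machine_network"))
  constraints <- as.data.frame(constraints)
  stopifnot(all(c("cycle_id", "delta_mu", "work") %in% names(constraints)))
  if (is.null(basis)) basis <- cycle_basis(net)
  bad <- setdiff(constraints$cycle_id, basis$chords)
  if (length(bad)) stop("constraint references unknown chord(s): ",
                        paste(bad, collapse = ", "))
  fc <- .cycle_forces(net, basis)
  affinity <- 2 * fc[constraints$cycle_id]
  target <- constraints$delta_mu - constraints$work
  data.frame(cycle_id = constraints$cycle_id,
             affinity = unname(affinity),
             target = target,
             residual = unname(affinity) - target)
}
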