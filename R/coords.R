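# Canonical coordinates: rates <-> (pi, tree traffics, chord fluxes, cycle
# forces). Swapping each chord's traffic for its cycle flux (and pairing it
# with the cycle force) gives a coordinate system in which thermodynamic
# drives are held fixed while performance targets are dialed in; the map back
# to rates is closed-form.

#' Extract canonical coordinates
#'
#' Maps a solved network to the canonical coordinate
#' `(pi, tau_tree, J_cycle, F_cycle)`: state probabilities, traffics on the
#' spanning-tree edges, net fluxes on the chords, and cycle-completion forces
#' on the chords. Chord traffics are also recorded (`tau_chord`): together with
#' the tree traffics they give the plain observable form `(pi, tau, F_cycle)`,
#' and they disambiguate the inverse map on an equilibrium chord (`J = 0` and
#' zero residual force), where the chord traffic is otherwise indeterminate.
#'
#' @param net a `machine_network`.
#' @param ss optional precomputed `steady_state`.
#' @param basis optional precomputed `cycle_basis`.
#' @return an object of class `canonical_coords`.
#' @export
to_canonical <- function(net, ss = NULL, basis = NULL) {
  stopifnot(inherits(net, "machine_network"))
  if (is.null(basis)) basis <- cycle_basis(net)
  if (is.null(ss)) ss <- steady_state(net, basis)
  structure(list(pi = ss$pi,
                 tau_tree = ss$tau[basis$tree_edges],
                 tau_chord = ss$tau[basis$chords],
                 j_cycle = ss$j_cycle,
                 f_cycle = .cycle_forces(net, basis),
                 # exact one-way split of each edge's (tau, J) pair; carried so
                 # the inverse map does not have to recover a tiny backward
                 # flux from the cancellation tau - J (see the vignette's
                 # numerical notes); ignored wherever coordinates are modified
                 p_fwd = ss$p_fwd, p_bwd = ss$p_bwd,
                 basis = basis,
                 name = net$name),
            class = "canonical_coords")
}

#' @export
print.canonical_coords <- function(x, ...) {
  cat(sprintf("canonical_coords of '%s'\n", x$name))
  cat("pi:\n"); print(round(x$pi, 6))
  cat("tree traffics:\n"); print(round(x$tau_tree, 6))
  if (length(x$j_cycle)) {
    df <- data.frame(chord = names(x$j_cycle), j_cycle = x$j_cycle,
                     f_cycle = x$f_cycle[names(x$j_cycle)], row.names = NULL)
    print(df, row.names = FALSE, digits = 6)
  }
  invisible(x)
}

#' Solve transition rates from canonical coordinates
#'
#' The exact inverse of [to_canonical()]:
#' 1. tree-edge net fluxes follow from Kirchhoff reconstruction of the chord
#'    fluxes;
#' 2. tree-edge rates are `k_ij = (tau + J)/(2 pi_i)`,
#'    `k_ji = (tau - J)/(2 pi_j)`;
#' 3. each reversible chord's traffic solves its cycle-force equation: the
#'    residual `rho = F_cycle - sum over the tree path of arctanh(J/tau)` must
#'    carry the chord's own contribution `arctanh(J_chord/tau_chord)`, so
#'    `tau_chord = J_chord / tanh(rho)`; a non-invertible chord instead has
#'    `k_cat = J_chord / pi_tail` directly (its traffic equals its flux).
#'
#' Infeasibility is the non-negativity boundary of one-way fluxes: a tree edge
#' with `tau <= |J|` (a one-way flux crossing zero), or a reversible chord
#' whose residual force has the wrong sign for its flux, raises an error naming
#' the edge. An equilibrium chord (`J = 0`, `rho = 0`) takes its traffic from
#' `coords$tau_chord`.
#'
#' @param coords a `canonical_coords` (fields may be modified to pose design
#'   targets).
#' @param basis the `spanning_tree_basis` describing the topology (defaults to
#'   the one stored in `coords`).
#' @return a `machine_network` with the solved rates.
#' @export
rates_from_canonical <- function(coords, basis = coords$basis) {
  stopifnot(inherits(coords, "canonical_coords"),
            inherits(basis, "spanning_tree_basis"))
  edges <- basis$edges
  pi <- coords$pi
  if (any(pi <= 0) || abs(sum(pi) - 1) > 1e-8) {
    stop("pi must be strictly positive on the simplex")
  }
  jnet <- reconstruct_edge_fluxes(basis, coords$j_cycle)
  kf <- kb <- numeric(nrow(edges))
  names(kf) <- names(kb) <- edges$id
  arct <- numeric(nrow(edges))  # per-edge arctanh(J/tau), tree edges first

  for (id in basis$tree_edges) {
    e <- match(id, edges$id)
    tau <- coords$tau_tree[[id]]; J <- jnet[[id]]
    if (!edges$reversible[e]) stop("non-invertible edge in spanning tree: ", id)
    if (tau <= abs(J)) {
      stop("infeasible coordinates: one-way flux would be non-positive on ",
           "tree edge '", id, "' (tau = ", signif(tau, 6), ", |J| = ",
           signif(abs(J), 6), ")")
    }
    p <- .stored_split(coords, id, tau, J)
    kf[id] <- p[1L] / pi[[edges$tail[e]]]
    kb[id] <- p[2L] / pi[[edges$head[e]]]
    arct[e] <- 0.5 * log(p[1L] / p[2L])
  }
  for (ch in basis$chords) {
    e <- match(ch, edges$id)
    J <- coords$j_cycle[[ch]]
    mem <- .cycle_members(basis, ch)
    mem <- mem[mem$id != ch, , drop = FALSE]
    rho <- coords$f_cycle[[ch]] -
      sum(mem$sign * arct[match(mem$id, edges$id)])
    if (!edges$reversible[e]) {
      if (J <= 0) stop("non-invertible chord '", ch,
                       "' requires a positive cycle flux")
      kf[ch] <- J / pi[[edges$tail[e]]]
      kb[ch] <- 0
      next
    }
    if (J == 0 && abs(rho) < 1e-12) {
      tau <- if (ch %in% names(coords$tau_chord)) coords$tau_chord[[ch]] else NA
      if (!is.finite(tau) || tau <= 0) {
        stop("equilibrium chord '", ch, "' needs tau_chord to fix its traffic")
      }
      kf[ch] <- tau / (2 * pi[[edges$tail[e]]])
      kb[ch] <- tau / (2 * pi[[edges$head[e]]])
      next
    }
    if (rho == 0 || sign(rho) != sign(J)) {
      stop("infeasible coordinates: residual cycle force on chord '", ch,
           "' (", signif(rho, 6), ") is incompatible with its flux (",
           signif(J, 6), "); no positive traffic solves it")
    }
    # prefer the stored exact split when it still solves this chord equation
    p <- NULL
    if (!is.null(coords$p_fwd) && ch %in% names(coords$p_fwd)) {
      pf <- coords$p_fwd[[ch]]; pb <- coords$p_bwd[[ch]]
      if (pf > 0 && pb > 0 &&
          abs(pf - pb - J) <= 4 * .Machine$double.eps * (pf + pb) &&
          abs(0.5 * log(pf / pb) - rho) <= 1e-9 * max(1, abs(rho))) {
        p <- c(pf, pb)
      }
    }
    if (is.null(p)) {
      # arctanh(J/tau) = rho in closed form: p_fwd = J/(1 - exp(-2 rho)),
      # p_bwd = p_fwd - J; this keeps the tiny backward flux of a strongly
      # driven chord at full precision (tau = J/tanh(rho) would cancel it)
      den <- -expm1(-2 * rho)
      p <- c(J / den, J / den - J)
    }
    kf[ch] <- p[1L] / pi[[edges$tail[e]]]
    kb[ch] <- p[2L] / pi[[edges$head[e]]]
  }
  build_network(states = basis$states,
                edges = data.frame(id = edges$id, tail = edges$tail,
                                   head = edges$head, k_fwd = unname(kf),
                                   k_bwd = unname(kb),
                                   stringsAsFactors = FALSE),
                name = coords$name)
}

# one-way fluxes of an edge: the stored exact split when it is still
# consistent with the (tau, J) coordinates, otherwise (tau +- J)/2
.stored_split <- function(coords, id, tau, J) {
  if (!is.null(coords$p_fwd) && id %in% names(coords$p_fwd)) {
    pf <- coords$p_fwd[[id]]; pb <- coords$p_bwd[[id]]
    if (abs(pf + pb - tau) <= 4 * .Machine$double.eps * tau &&
        abs(pf - pb - J) <= 4 * .Machine$double.eps * tau) {
      return(c(pf, pb))
    }
  }
  c((tau + J) / 2, (tau - J) / 2)
}
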