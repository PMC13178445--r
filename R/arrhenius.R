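#' Arrhenius parameter set
#'
#' Bundles the Arrhenius parameterization of transition rates: a global
#' timescale prefactor `N`, node energies `E_i`, symmetric edge barriers `B_ij`
#' and antisymmetric per-edge affinity splits `F_ij` (all energies in kT), so
#' that
#' `k_ij = N exp(-(B_ij - E_i)) exp(+F_ij/2)` and
#' `k_ji = N exp(-(B_ij - E_j)) exp(-F_ij/2)`.
#'
#' Non-invertible edges admit no finite (B, F) decomposition; they may be
#' supplied in `catalytic` as raw forward rates.
#'
#' @param prefactor global timescale `N > 0` (1/time).
#' @param node_energy named numeric, one energy per state (kT).
#' @param barrier named numeric, one barrier per reversible edge (kT).
#' @param affinity_split named numeric, one split per reversible edge (kT).
#' @param catalytic optional named numeric of raw forward rates for
#'   non-invertible edges.
#' @return an object of class `arrhenius_params`.
#' @export
arrhenius_params <- function(prefactor = 1, node_energy, barrier,
                             affinity_split, catalytic = numeric(0)) {
  stopifnot(is.numeric(prefactor), length(prefactor) == 1L, prefactor > 0)
  stopifnot(!is.null(names(node_energy)), !is.null(names(barrier)),
            !is.null(names(affinity_split)))
  stopifnot(setequal(names(barrier), names(affinity_split)))
  structure(list(prefactor = prefactor, node_energy = node_energy,
                 barrier = barrier, affinity_split = affinity_split,
                 catalytic = catalytic),
            class = "arrhenius_params")
}

#' @export
print.arrhenius_params <- function(x, ...) {
  cat(sprintf("arrhenius_params: prefactor %.6g, %d node energies, %d edges\n",
              x$prefactor, length(x$node_energy), length(x$barrier)))
  cat("node energies (kT):\n"); print(round(x$node_energy, 6))
  df <- data.frame(edge = names(x$barrier), barrier = unname(x$barrier),
                   affinity_split = unname(x$affinity_split[names(x$barrier)]))
  print(df, row.names = FALSE, digits = 6)
  if (length(x$catalytic)) {
    cat("catalytic edges (raw rates):\n"); print(x$catalytic)
  }
  invisible(x)
}

#' Map Arrhenius parameters to transition rates
#'
#' Applies the Arrhenius form to a network topology: each reversible edge gets
#' `k_ij = N exp(-(B_ij - E_i) + F_ij/2)` and `k_ji` with the tail/head energy
#' and the opposite half-split; the barrier is shared by both directions, so
#' raising it by `delta` multiplies both rates by `exp(-delta)`, while raising a
#' node energy by `delta` multiplies every rate leaving that node by
#' `exp(delta)`.
#'
#' @param params an `arrhenius_params`.
#' @param topology a `machine_network` supplying states and edges (its rates
#'   are replaced).
#' @return a `machine_network` with the mapped rates.
#' @export
rates_from_arrhenius <- function(params, topology) {
  stopifnot(inherits(params, "arrhenius_params"),
            inherits(topology, "machine_network"))
  edges <- topology$edges
  missE <- setdiff(topology$states, names(params$node_energy))
  if (length(missE)) stop("missing node energy for state(s): ",
                          paste(missE, collapse = ", "))
  rev_ids <- edges$id[edges$reversible]
  irr_ids <- edges$id[!edges$reversible]
  missB <- setdiff(rev_ids, names(params$barrier))
  if (length(missB)) stop("missing barrier for edge(s): ",
                          paste(missB, collapse = ", "))
  missC <- setdiff(irr_ids, names(params$catalytic))
  if (length(missC)) stop("non-invertible edge(s) without raw catalytic rate: ",
                          paste(missC, collapse = ", "))
  E <- params$node_energy
  kf <- kb <- numeric(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    id <- edges$id[e]
    if (edges$reversible[e]) {
      B <- params$barrier[[id]]; Fs <- params$affinity_split[[id]]
      kf[e] <- params$prefactor * exp(-(B - E[[edges$tail[e]]]) + Fs / 2)
      kb[e] <- params$prefactor * exp(-(B - E[[edges$head[e]]]) - Fs / 2)
    } else {
      kf[e] <- params$catalytic[[id]]
      kb[e] <- 0
    }
  }
  .with_rates(topology, kf, kb)
}

#' Recover Arrhenius parameters in a chosen gauge
#'
#' The Arrhenius decomposition of a rate set is gauge-ambiguous: any node-energy
#' assignment can be absorbed by compensating barriers and affinity splits.
#' Given a gauge (a node-energy vector), this returns the unique `(B, F)`
#' reproducing the network's rates with prefactor 1:
#' `F_ij = ln(k_ij/k_ji) + (E_j - E_i)` and
#' `B_ij = (E_i + E_j - ln(k_ij k_ji)) / 2`.
#' When no energies are supplied, the stationary-distribution gauge
#' `E = -ln(pi)` is used, which makes detailed-balance networks have all
#' affinity splits zero.
#'
#' Non-invertible edges have no finite decomposition and are returned as raw
#' rates in the `catalytic` field.
#'
#' The composition `rates_from_arrhenius(arrhenius_gauge(net, E), net)`
#' reproduces the input rates to machine precision for any gauge.
#'
#' @param net a `machine_network`.
#' @param node_energy optional named node-energy vector (kT); default
#'   `-ln(pi)` from the steady state.
#' @return an `arrhenius_params`.
#' @export
arrhenius_gauge <- function(net, node_energy = NULL) {
  stopifnot(inherits(net, "machine_network"))
  if (is.null(node_energy)) {
    node_energy <- -log(steady_state(net)$pi)
  }
  missE <- setdiff(net$states, names(node_energy))
  if (length(missE)) stop("missing node energy for state(s): ",
                          paste(missE, collapse = ", "))
  edges <- net$edges
  rev <- edges$reversible
  Ei <- node_energy[edges$tail]; Ej <- node_energy[edges$head]
  Fs <- (log(edges$k_fwd / edges$k_bwd) + (Ej - Ei))[rev]
  B <- ((Ei + Ej - log(edges$k_fwd * edges$k_bwd)) / 2)[rev]
  names(Fs) <- names(B) <- edges$id[rev]
  catal <- edges$k_fwd[!rev]
  names(catal) <- edges$id[!rev]
  arrhenius_params(prefactor = 1, node_energy = node_energy,
                   barrier = B, affinity_split = Fs, catalytic = catal)
}
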