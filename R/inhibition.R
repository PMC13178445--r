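# Michaelis-Menten inhibition as a flow-routing problem: dead ends vs leaky
# loops around a non-invertible catalytic step.

#' Build a Michaelis-Menten inhibition network
#'
#' All three archetypes share the catalytic core: substrate binding
#' `bind: E <-> ES` and the non-invertible catalytic step `cat: ES -> E + P`
#' (`k_bwd = 0`, a parallel edge of the same state pair, so its traffic equals
#' its net flux). Inhibitor topologies:
#' * `competitive`: inhibitor binds the free enzyme, `i1: E <-> EI` — a dead
#'   end carrying zero steady-state net flux;
#' * `uncompetitive`: inhibitor binds the complex, `u1: ES <-> EIS` — also a
#'   dead end;
#' * `noncompetitive`: the loop `E <-> EI <-> EIS <-> ES` closes
#'   (`i1`, `i2`, `i3`), coupling the inhibitor pathway to catalysis. Even when
#'   this internal loop is futile (leak cycle force `F_leak = 0`), catalysis
#'   depletes `ES` and replenishes `E`, pumping a positive leak flux around the
#'   loop.
#'
#' With `project_fleak = TRUE` (noncompetitive only) the rate `k_fwd` of edge
#' `i3` is rescaled so the loop's log rate-ratio sum is exactly zero, the
#' futile-loop constraint of the sampling protocol.
#'
#' @param kind one of `"competitive"`, `"uncompetitive"`, `"noncompetitive"`.
#' @param rates named numeric overriding any of the defaults: `kon`, `koff`,
#'   `kcat`, `ki_on`, `ki_off` (E/ES <-> inhibitor-bound), and for the
#'   noncompetitive loop `kis_on`, `kis_off` (EI <-> EIS), `ks_on`, `ks_off`
#'   (EIS <-> ES).
#' @param project_fleak zero the leak cycle force by rescaling `ks_on`.
#' @return a `machine_network` with attribute `inhibition_kind`.
#' @export
mm_inhibition_network <- function(kind = c("competitive", "uncompetitive",
                                           "noncompetitive"),
                                  rates = numeric(0), project_fleak = FALSE) {
  kind <- match.arg(kind)
  r <- c(kon = 10, koff = 1, kcat = 1, ki_on = 5, ki_off = 0.5,
         kis_on = 3, kis_off = 0.3, ks_on = 2, ks_off = 4)
  bad <- setdiff(names(rates), names(r))
  if (length(bad)) stop("unknown rate name(s): ", paste(bad, collapse = ", "))
  r[names(rates)] <- rates
  ed <- function(id, tail, head, kf, kb) {
    data.frame(id = id, tail = tail, head = head, k_fwd = kf, k_bwd = kb,
               stringsAsFactors = FALSE)
  }
  core <- rbind(ed("bind", "E", "ES", r[["kon"]], r[["koff"]]),
                ed("cat", "ES", "E", r[["kcat"]], 0))
  net <- switch(kind,
    competitive = build_network(
      states = c("E", "ES", "EI"),
      edges = rbind(core, ed("i1", "E", "EI", r[["ki_on"]], r[["ki_off"]])),
      name = "mm-competitive"),
    uncompetitive = build_network(
      states = c("E", "ES", "EIS"),
      edges = rbind(core, ed("u1", "ES", "EIS", r[["ki_on"]], r[["ki_off"]])),
      name = "mm-uncompetitive"),
    noncompetitive = build_network(
      states = c("E", "ES", "EI", "EIS"),
      edges = rbind(core,
                    ed("i1", "E", "EI", r[["ki_on"]], r[["ki_off"]]),
                    ed("i2", "EI", "EIS", r[["kis_on"]], r[["kis_off"]]),
                    ed("i3", "EIS", "ES", r[["ks_on"]], r[["ks_off"]])),
      name = "mm-noncompetitive"))
  if (project_fleak) {
    if (kind != "noncompetitive") {
      stop("the leak-loop constraint applies to noncompetitive networks only")
    }
    fl <- leak_cycle_force(net)
    e <- match("i3", net$edges$id)
    net$edges$k_fwd[e] <- net$edges$k_fwd[e] * exp(-2 * fl)
  }
  attr(net, "inhibition_kind") <- kind
  net
}

#' Leak cycle force of a noncompetitive network
#'
#' Half the log rate-ratio sum around the inhibitor loop oriented
#' `E -> EI -> EIS -> ES -> E` (the last step runs backward along the binding
#' edge). A futile inhibitor loop has `F_leak = 0`.
#'
#' @param net a noncompetitive inhibition network.
#' @return the leak cycle force (kT).
#' @export
leak_cycle_force <- function(net) {
  ids <- c("i1", "i2", "i3", "bind")
  if (!all(ids %in% net$edges$id)) {
    stop("not a noncompetitive inhibition network (need edges i1, i2, i3, bind)")
  }
  e <- match(ids, net$edges$id)
  lr <- log(net$edges$k_fwd[e] / net$edges$k_bwd[e])
  0.5 * (lr[1L] + lr[2L] + lr[3L] - lr[4L])
}

#' Inhibitor Equal Traffic Principle bounds
#'
#' For a noncompetitive network with a futile inhibitor loop, the catalytic
#' production decomposes exactly as
#' `Jcat = Jleak + tau_E,ES * tanh(A_side)` with
#' `A_side = sum over the three sideway edges of arctanh(Jleak / tau_eta)`.
#' At fixed leak flux and fixed total sideway traffic, `A_side` is minimized
#' by equal sideway traffics, giving the lower bound; the upper bound
#' `Jcat <= Jleak + tau_E,ES` is reached when the backward one-way flux on the
#' binding edge (`p_ES->E`) vanishes.
#'
#' The identity is derived for `F_leak = 0`; a network violating that (beyond
#' `fleak_tol`) is refused.
#'
#' @param net a noncompetitive `machine_network` (e.g. from
#'   [mm_inhibition_network()]).
#' @param ss optional precomputed steady state.
#' @param fleak_tol tolerance on `|F_leak|` (default 1e-6).
#' @return list: `j_cat`, `j_leak`, `a_side`, `identity` (RHS of the
#'   decomposition), `lower`, `upper`, `tau_bind`, `tau_side` (named), and
#'   `p_back_bind`.
#' @export
ietp_bounds <- function(net, ss = NULL, fleak_tol = 1e-6) {
  kind <- attr(net, "inhibition_kind")
  if (!is.null(kind) && kind != "noncompetitive") {
    stop("iETP bounds apply to the noncompetitive (leaky-loop) topology; '",
         kind, "' is a dead-end kind")
  }
  fl <- leak_cycle_force(net)
  if (abs(fl) > fleak_tol) {
    stop("leak cycle force is ", signif(fl, 6),
         "; the decomposition requires a futile loop (F_leak = 0)")
  }
  if (is.null(ss)) ss <- steady_state(net)
  j_cat <- ss$j_cycle[["cat"]]
  j_leak <- ss$j_cycle[["i2"]]
  tau_side <- ss$tau[c("i1", "i2", "i3")]
  tau_bind <- ss$tau[["bind"]]
  a_side <- sum(atanh(j_leak / tau_side))
  identity <- j_leak + tau_bind * tanh(a_side)
  tau_side_tot <- sum(tau_side)
  a_min <- 3 * atanh(3 * j_leak / tau_side_tot)
  list(j_cat = j_cat, j_leak = j_leak, a_side = a_side, identity = identity,
       lower = j_leak + tau_bind * tanh(a_min),
       upper = j_leak + tau_bind,
       tau_bind = tau_bind, tau_side = tau_side,
       p_back_bind = ss$p_bwd[["bind"]])
}

#' Finite-shift dead-end invariance check
#'
#' A dead-end edge carries zero steady-state net flux, so scaling both of its
#' rates by a common factor leaves the stationary distribution — and with it
#' every other traffic, the catalytic flux, and all cycle fluxes — *exactly*
#' unchanged; only its own traffic scales. This is checked here with finite
#' barrier shifts (not just derivatives). An edge with nonzero net flux is
#' refused: its barrier genuinely routes flows.
#'
#' @param net a `machine_network`.
#' @param edge edge id to test (must carry zero net flux).
#' @param shifts finite barrier shifts in kT (default `c(-2, 2)`).
#' @param flux_tol |J| threshold (relative to max traffic) below which the edge
#'   counts as a dead end.
#' @return object of class `deadend_report`: per-shift maximal deviations of
#'   `pi`, other traffics and cycle fluxes, plus the own-traffic factors.
#' @export
deadend_invariance_check <- function(net, edge, shifts = c(-2, 2),
                                     flux_tol = 1e-9) {
  ss <- steady_state(net)
  if (!edge %in% net$edges$id) stop("unknown edge: ", edge)
  if (abs(ss$jnet[[edge]]) > flux_tol * max(ss$tau)) {
    stop("edge '", edge, "' carries nonzero net flux (J = ",
         signif(ss$jnet[[edge]], 6), "); it is not a dead end and its ",
         "barrier responses are nonzero")
  }
  others <- setdiff(net$edges$id, edge)
  res <- lapply(shifts, function(db) {
    ss2 <- steady_state(.apply_knob(net, paste0("barrier:", edge), db))
    list(shift = db,
         dpi = max(abs(ss2$pi - ss$pi)),
         dtau_other = if (length(others))
           max(abs(ss2$tau[others] - ss$tau[others])) else 0,
         dj_cycle = if (length(ss$j_cycle))
           max(abs(ss2$j_cycle - ss$j_cycle)) else 0,
         own_tau_factor = ss2$tau[[edge]] / ss$tau[[edge]])
  })
  structure(list(edge = edge, shifts = shifts, results = res,
                 derivative = barrier_response(net, ss, edge,
                                               paste0("prob:", net$states[1L]))),
            class = "deadend_report")
}

#' @export
print.deadend_report <- function(x, ...) {
  cat(sprintf("deadend_report for edge '%s'\n", x$edge))
  for (r in x$results) {
    cat(sprintf("  shift %+g kT: max|dpi| = %.2e, max|dtau_other| = %.2e, ",
                r$shift, r$dpi, r$dtau_other))
    cat(sprintf("max|dJc| = %.2e, own tau factor = %.6g\n",
                r$dj_cycle, r$own_tau_factor))
  }
  invisible(x)
}
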