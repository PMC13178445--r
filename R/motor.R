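# The two-state rotary motor and the Equal Traffic Principle.

#' Equal Traffic Principle bound on cycle flux
#'
#' Maximum cycle flux of a unicyclic machine at fixed cycle-completion force
#' and fixed total traffic budget: the optimum requires equal traffic on every
#' cycle edge. For the two-edge unicycle the bound is
#' `J_max = (tau_tot/2) tanh(F_cycle/2)`; for `n` edges the equal-traffic value
#' solves `n * arctanh(J n / tau_tot) = F_cycle`, i.e.
#' `J_max = (tau_tot/n) tanh(F_cycle/n)`. The general-`n` form is a derived
#' extension of the printed two-edge rule, verified numerically (see the
#' methods vignette), and is flagged as such on the return value.
#'
#' @param f_cycle cycle-completion force (half the cycle affinity, kT).
#' @param tau_tot total traffic budget over the cycle edges (1/time).
#' @param n_edges number of edges in the cycle (default 2).
#' @return the bound (1/time), with attribute `extension = TRUE` when
#'   `n_edges > 2`.
#' @export
etp_bound <- function(f_cycle, tau_tot, n_edges = 2L) {
  stopifnot(tau_tot > 0, n_edges >= 2L)
  b <- (tau_tot / n_edges) * tanh(f_cycle / n_edges)
  if (n_edges > 2L) attr(b, "extension") <- TRUE
  b
}

#' Thermal energy at room temperature in pN nm
#' @export
kBT_pN_nm <- 4.1

#' Two-state rotary motor model
#'
#' The 2-state, 2-edge unicycle describing the F1 rotary motor at low ATP: an
#' empty state `"0"` and a nucleotide-occupied state `"1"`, connected by the T
#' transition (ATP binding/unbinding, ~90 degree substep, edge `"T"`: 0 -> 1)
#' and the D transition (catalysis and product release, ~30 degree substep,
#' edge `"D"`: 1 -> 0). One completed cycle advances the rotor by
#' `delta_theta = 2 pi / 3` (one third of a revolution).
#'
#' Torque enters through exponential load-sharing factors
#' `k_X+-(Gamma) = k_X+-(0) exp(+- theta_X Gamma / (2 kT))` with substep
#' angles `theta_T = pi/2`, `theta_D = pi/6` by default; any admissible
#' load sharing must keep the cycle affinity at
#' `ln(kT+ kD+ / (kT- kD-)) = (delta_mu + Gamma delta_theta)/kT` for every
#' torque, which constrains the four exponents to sum to `delta_theta`.
#' Torque is confined to `|Gamma| <= 30` pN nm (tight coupling, no mechanical
#' slip); `kT = 4.1 pN nm` converts torque units.
#'
#' @param kT_plus,kT_minus,kD_plus,kD_minus base (zero-torque) rates (1/time).
#' @param torque applied torque Gamma in pN nm, `|Gamma| <= 30`.
#' @param load_sharing numeric of length 4 `(T+, T-, D+, D-)`: exponents
#'   (radians) multiplying `Gamma/kT` in each rate; must satisfy
#'   `(T+) - (T-) + (D+) - (D-) = 2 pi / 3`.
#' @return a `machine_network` with attribute `f1_params` (base rates, torque,
#'   inferred `delta_mu` in kT).
#' @export
f1_model <- function(kT_plus = 3, kT_minus = 0.15,
                     kD_plus = 20, kD_minus = 0.5,
                     torque = 0,
                     load_sharing = c(pi / 4, -pi / 4, pi / 12, -pi / 12)) {
  if (abs(torque) > 30) {
    stop("torque must lie in [-30, 30] pN nm (tight-coupling regime)")
  }
  stopifnot(length(load_sharing) == 4L)
  dtheta <- 2 * pi / 3
  spread <- load_sharing[1L] - load_sharing[2L] +
    load_sharing[3L] - load_sharing[4L]
  if (abs(spread - dtheta) > 1e-10) {
    stop("load-sharing exponents must span delta_theta = 2 pi / 3 ",
         "(got ", signif(spread, 8), ")")
  }
  g <- torque / kBT_pN_nm
  rates <- c(kT_plus, kT_minus, kD_plus, kD_minus) * exp(load_sharing * g)
  delta_mu <- log(kT_plus * kD_plus / (kT_minus * kD_minus))  # kT, at Gamma=0
  net <- build_network(
    states = c("0", "1"),
    edges = data.frame(id = c("D", "T"),
                       tail = c("1", "0"), head = c("0", "1"),
                       k_fwd = c(rates[3L], rates[1L]),
                       k_bwd = c(rates[4L], rates[2L]),
                       stringsAsFactors = FALSE),
    name = "f1-motor")
  attr(net, "f1_params") <- list(base = c(kT_plus = kT_plus,
                                          kT_minus = kT_minus,
                                          kD_plus = kD_plus,
                                          kD_minus = kD_minus),
                                 torque = torque, delta_mu = delta_mu,
                                 delta_theta = dtheta,
                                 load_sharing = load_sharing)
  net
}

#' Processive efficiency of a unicyclic machine
#'
#' The ratio of net transport to total transitions taken, `Jc / tau_tot`
#' (distinct from thermodynamic efficiency), together with its Equal Traffic
#' Principle bound `(tau_tot/n) tanh(F_cycle/n)` and the gap to it. The gap
#' closes only at equal traffic on all cycle edges; a traffic imbalance (e.g.
#' `tau_D >> tau_T` from futile backstepping) shows up as a large gap.
#'
#' @param net a unicyclic `machine_network`.
#' @param ss optional precomputed steady state.
#' @return list with `efficiency`, `bound`, `gap`, `tau` (per cycle edge),
#'   `f_cycle`.
#' @export
processive_efficiency <- function(net, ss = NULL) {
  basis <- cycle_basis(net)
  if (length(basis$chords) != 1L) {
    stop("processive efficiency is defined for unicyclic networks")
  }
  if (is.null(ss)) ss <- steady_state(net, basis)
  mem <- .cycle_members(basis, basis$chords)
  tau <- ss$tau[mem$id]
  tau_tot <- sum(tau)
  jc <- ss$j_cycle[[basis$chords]]
  fc <- .cycle_forces(net, basis)[[basis$chords]]
  # the bound constrains magnitudes: a cycle driven the other way obeys the
  # mirrored inequality, so the gap compares |J|/tau_tot with the bound at |F|
  bound <- as.numeric(etp_bound(abs(fc), tau_tot, n_edges = nrow(mem))) /
    tau_tot
  eff <- jc / tau_tot
  list(efficiency = eff, bound = bound, gap = bound - abs(eff),
       tau = tau, f_cycle = fc)
}
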