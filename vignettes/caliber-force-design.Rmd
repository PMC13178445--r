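---
title: "Caliber-force design of machine networks: models, conventions, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Caliber-force design of machine networks: models, conventions, numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caliberflow)
```

## The model

A machine network is an ergodic Markov jump process on a multigraph: states
are coarse-grained chemical or mechanical configurations, edges are
transition pairs with forward and backward rates `k_ij`, `k_ji > 0`, and a
non-invertible step (a catalytic release `ES -> E + P` whose reverse is
negligible at vanishing product concentration) is encoded as `k_bwd = 0`
exactly. Parallel edges between one state pair are allowed — the
Michaelis-Menten core needs both a binding edge and a catalytic edge between
`E` and `ES` — so all per-edge quantities are keyed by edge id, never by
state pair. Internally `kT = 1`: every energy, barrier, and force is
dimensionless, and the time unit is the inverse of the rate prefactor.

Steady-state behavior is summarized by the node probabilities, the edge
traffics `tau = pi_i k_ij + pi_j k_ji`, and the net fluxes
`J = pi_i k_ij - pi_j k_ji`, which Kirchhoff's current law reduces to
independent cycle fluxes on the chords of a spanning tree. The conjugate
caliber forces (node dwelling, edge exchange, cycle completion) are the
design handles; cycle forces are half the cycle affinity, so Local Detailed
Balance pins `2 F_cycle = (delta_mu - w)/kT` for a cycle fed free energy
`delta_mu` while performing work `w`.

### A consistency choice in the force convention

Per edge, `arctanh(J/tau) = (1/2) ln(pi_i k_ij / (pi_j k_ji))`; summed
around a closed cycle the stationary probabilities telescope away, leaving

```
sum_{(ij) in c} arctanh(J_ij / tau_ij) = (1/2) sum_{(ij) in c} ln(k_ij/k_ji) = F_cycle,c .
```

The package uses this convention everywhere: `F_cycle` is *half* the log
rate-ratio sum and *equals* the arctanh sum (one sometimes sees the arctanh
sum quoted as `2 F_cycle`; that normalization is inconsistent with the
half-log definition of the edge forces, as the telescoping identity above
shows). All downstream results — the motor bound
`J/tau_tot <= (1/2) tanh(F/2)`, the torque relation
`2F = (delta_mu + Gamma * dtheta)/kT`, the catalytic force
`F_cat = ln k_cat + (1/2) ln(k_E,ES/k_ES,E)`, and the inhibition
decomposition `J_cat = J_leak + tau_E,ES tanh(A_side)` — are consistent with
this choice, and the test suite verifies the telescoping identity on random
networks.

## Response rules and how they are computed

Knobs are defined operationally on rates: raising a node energy by `delta`
multiplies every rate leaving that node by `exp(delta)`; raising a barrier
multiplies both of an edge's rates by `exp(-delta)`. This keeps the rules
testable on networks never expressed in Arrhenius form.

*Energies scale.* `d phi / d E_n = pi_n phi` for every traffic, cycle flux,
or linear combination, hence flux ratios (and the proofreading error rate)
are invariant under node energies. For the entropy production rate the same
scaling holds on fully reversible networks; with a catalytic chord the
`ln k_cat` member of its cycle force has no compensating reverse, the
endpoint half-terms fail to telescope, and
`d EPR / d E_n = pi_n EPR + sum_c 2 J_c dF_c/dE_n`. `energy_response()`
implements the corrected form; the finite-difference oracle confirms it (on
the noncompetitive fixture the correction is `J_cat` per endpoint of the
catalytic cycle, which the plain scaling misses by exactly that much).

*Barriers route.* Differentiating the stationarity condition `pi Q = 0`
through the generator's deviation matrix `D = (1 pi' - Q)^{-1} - 1 pi'`
gives, for a barrier perturbation on edge `(i,j)`,

```
d pi / d B_ij = J_ij (D[i, ] - D[j, ]) ,
```

and chain rules extend this to traffics, cycle fluxes, EPR, and the
proofreading metrics: every response is the perturbed edge's net flux times
an element of an inverse matrix built from the generator. A dead-end edge
(`J_ij = 0`) therefore routes nothing — and because scaling the two rates of
a zero-flux edge leaves the stationarity equations untouched, the dead-end
invariance is exact at *finite* shifts, not merely to first order.

`force_rate_jacobian()` exposes the matrix
`A[(ij), alpha] = k_ij dF_alpha/dk_ij` over the full label set (node forces
without the reference, edge forces on reversible edges, cycle forces on
chords). That matrix is square but exactly rank-deficient: each cycle force
is identically the signed sum of the edge forces around its cycle, so the
cycle columns are linear combinations of edge columns and
`rank = #rates - #chords`. The object reports the rank, the condition
number, and a Moore-Penrose pseudo-inverse; the package's response rules are
computed from the deviation-matrix kernel above, which is exact, and agree
with the closed forms where those exist (`d ln Jc/dB_T = -Sigma_D/Sigma`
etc.) to 1e-10.

The perturbed edge's *own traffic* carries an additional non-routing term
under a barrier change; `barrier_response()` deliberately routes that one
request to the finite-difference oracle rather than asserting a closed form.

Two printed results acquire wider scope here, each verified before being
asserted in tests: raising every barrier of a network by the same amount is
a pure time rescaling (stationary distribution unchanged, every flux scaled
by `exp(-dB)`), so the barrier sensitivities of `ln J_c` sum to −1 on *any*
unicycle, not only the two-edge motor; and the equal-traffic bound
generalizes to `n`-edge cycles as `J <= (tau_tot/n) tanh(F/n)`, flagged as a
derived extension on the return value of `etp_bound()` and checked by an
independent numerical maximizer.

## Canonical coordinates and inverse design

`to_canonical()` maps a solved network to
`(pi, tau_tree, J_chord, F_chord)`; `rates_from_canonical()` inverts it:
tree fluxes by Kirchhoff reconstruction, tree rates as
`k = (tau ± J)/(2 pi)`, and each reversible chord's traffic from its
residual cycle force `rho = F_cycle - sum_tree arctanh(J/tau)` via
`p_fwd = J/(1 - exp(-2 rho))`. Infeasibility is precisely the non-negativity
boundary of one-way fluxes — a tree edge with `tau <= |J|`, or a chord whose
residual force disagrees in sign with its flux — and errors name the edge.

Numerical notes, in decreasing order of importance:

- A strongly driven chord's backward flux is `~J exp(-2 rho)`; recovering it
  through `tau = J/tanh(rho)` followed by `tau - J` would cancel it away, so
  the inverse map evaluates the one-way fluxes directly with `expm1`.
- The pair `(tau, J)` stored as doubles determines the smaller one-way flux
  only to an absolute error `~1e-16 * tau`; `to_canonical()` therefore also
  carries the exact one-way split, which the inverse map uses whenever it is
  still consistent with the (possibly modified) coordinates. With that,
  round trips on generic networks hold to 1e-10 and typically to 1e-13;
  on networks with edges saturated beyond `1 - 1e-10` (e.g. a 20 kT drive)
  the representation itself limits rate recovery to roughly 1e-5 relative on
  the nearly-extinct direction — an intrinsic property of the
  `(tau, J, F)` coordinate, documented rather than hidden.
- The stationary distribution is solved from the SVD null space of the dense
  generator with a 1e-10 relative tolerance separating the null direction
  from the rest of the spectrum (networks here have at most ~10 states;
  exactness beats scalability). A second near-null direction is reported as
  a near-non-ergodic input rather than silently resolved.
- The finite-difference oracle uses central differences with step 1e-6 and
  an optional Richardson check at 10x the step, balancing truncation against
  round-off for order-one rates.

The proofreading metrics `(S, eps, C, r')` are algebra on the four cycle
fluxes (error in log base 10, as is conventional); `design_path()` drives
them along a straight line while holding `(pi, tau_tree, r', F_cycle)` at
their origin values. Holding that particular set is one valid protocol among
several — the state probabilities and discard ratio are genuinely free
parameters of the inverse design — and it has two consequences worth
stating. First, when a waypoint's target flux overruns a held tree traffic
(a one-way flux crossing zero), that specific traffic limit is relaxed
tenfold and the waypoint retried, relaxations persisting down the path; if
several limits fail in one step all are relaxed, a deterministic tie-break.
Second, the anti-proofreading boundary (`J_R' + J_W' = 0`) is a hard wall
for this protocol: with the discard cycle forces held positive, the discard
chords' rates would have to pass through zero, and just beyond the crossing
no positive chord traffic solves the cycle-force equation. `design_path()`
flags the crossing waypoint from its target fluxes and terminates there with
a recorded reason; continuing into the regime requires releasing `pi` or the
cycle forces, which this protocol deliberately does not do.

## The application fixtures and the sampler

**Rotary motor.** Two states (empty / nucleotide-occupied), two edges: ATP
binding (~90° substep) and catalysis-plus-release (~30° substep); one cycle
advances the rotor 120°. Torque enters as exponential load-sharing factors
`k_X± = k_X±(0) exp(± theta_X Gamma/(2 kT))` with `theta_T = pi/2`,
`theta_D = pi/6` and `kT = 4.1 pN nm`; any admissible sharing must keep
`ln(kT+ kD+/(kT- kD-)) = (delta_mu + Gamma * 2pi/3)/kT` at every torque, and
the symmetric split is the simplest such choice — every result used here
(the bound, the sum rule, the response forms) is invariant to the split.
Torque is confined to ±30 pN nm (tight coupling, no slip). The default base
rates are synthetic order-of-magnitude values with `delta_mu ≈ 19 kT`
inferred from them; fitting measured torque-speed curves is out of scope.

**Proofreading.** The five-state fixture has, per substrate X ∈ {R, W},
binding `E <-> EX`, transfer to a checked state `EX <-> EXs`, a reversible
incorporation chord `EX -> E` and a discard chord `EXs -> E`; the
deterministic spanning tree is the star of binding and discard edges around
`E`, so the four chords carry `J_R, J_W, J_R', J_W'`. Rates are synthetic
(no measured polymerase or ribosome rate set is built in):
the Right substrate's two cycle affinities are pinned to `dmu_p = 6 kT`
(phosphodiester bond) and `dmu_ntp = 20 kT` (NTP hydrolysis) by construction
of the reverse rates, and the Wrong substrate is discriminated by
`delta = 4 kT` of bound-state destabilization plus the matching
incorporation-barrier shift of the classic scheme (which preserves both
affinities). The remaining base rates were chosen once so the fixture sits
in a recognizably proofreading-like regime — error `10^-1.7`, positive
discard fluxes, and a cognate-discard "free lunch" direction, the qualitative
signature of real proofreaders near their evolved operating point — and then
frozen. `classic_kp_model()` separately encodes the textbook two-ladder
argument: destabilizing the Wrong bound state by `delta` while keeping
forward incorporation identical forces the Wrong incorporation barrier up by
exactly `delta`.

**Inhibition.** Competitive (`E <-> EI`) and uncompetitive (`ES <-> EIS`)
inhibitors are dead ends; the noncompetitive loop `E-EI-EIS-ES` closes and
couples to catalysis. The loop's cycle force is computed with the loop
oriented `E -> EI -> EIS -> ES`, the orientation in which the pumped leak
flux is positive; `project_fleak = TRUE` rescales one loop rate to make the
loop exactly futile. The `ietp_bounds()` decomposition is derived at
`F_leak = 0` and the function refuses networks violating that beyond 1e-6.

**Sampler.** Validation ensembles redraw every positive rate of a template
topology log-uniformly over six decades centred at 1 (`1e-3..1e3`), then
project equality constraints (cycle-force targets) by rescaling one
designated rate, preserving the log-uniform marginals of the free rates;
streams are Mersenne-Twister seeded and platform-independent. For the
proofreading bound the draw is in coordinate space instead: all chord
traffics log-uniform over `1e-3..1e5`, chord fluxes placed uniformly inside
their one-way-flux feasible intervals (incorporation fluxes forward, discard
fluxes either sign), tree fluxes by Kirchhoff, and draws whose tree edges
would be infeasible rejected. These ensembles emulate breadth of kinetic
regimes, not biological rate distributions: passing them demonstrates the
operational bounds and identities across many decades of rates, not that any
particular enzyme's parameters are typical.

For the futile-loop ensemble the observables are evaluated by the
Markov-chain tree theorem rather than the generic linear solve: stationary
weights are sums of positive directed-spanning-tree products, and the leak
flux reduces, after exact cancellation of paired tree terms, to its cycle
terms — making its strict positivity numerically robust even where a
generic solve would lose it to cancellation at extreme rate ratios. The
construction is generated programmatically from the topology and is
cross-checked against the generic solver at machine precision in the tests.

Ensemble sizes: the bound validations run 10^4 samples each (about a second
apiece at these network sizes), the bijection check 10^3 random 4–6-state
networks, the response-oracle sweep 100 networks; these sizes give minima
and violation counts that are stable from seed to seed.

## Known limitations

- Transient dynamics, trajectory sampling, and first-passage statistics are
  out of scope; everything here is stationary.
- The dense-SVD solver targets networks of at most ~10 states; nothing is
  sparse.
- The printed force-set Jacobian is structurally singular (see above); users
  wanting a literal inverse must drop the dependent cycle columns
  themselves, or use the response functions, which do not need it.
- The node-dwelling force is implemented exactly as the per-transition
  reciprocal-rate sums given above; an alternative reading (reciprocal
  *escape* rates, i.e. mean dwell times) exists, and would change `f_node`
  values but none of the edge/cycle machinery.
- Near-saturated edges limit the precision of the inverse coordinate map
  (discussed above) and of any quantity that needs the nearly-extinct
  one-way flux.
- `design_path()` with the held-coordinate protocol cannot cross the
  anti-proofreading boundary; it flags and stops.

## Session info

```{r}
sessionInfo()
```
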