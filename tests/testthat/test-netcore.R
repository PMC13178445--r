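# Network construction, steady states, cycle bases, entropy production.

test_that("build_network validates its inputs", {
  ed <- function(...) data.frame(..., stringsAsFactors = FALSE)
  ok <- build_network(c("0", "1"),
                      ed(id = "e", tail = "0", head = "1", k_fwd = 1, k_bwd = 1))
  expect_s3_class(ok, "machine_network")

  expect_error(build_network(c("a", "a"),
                             ed(id = "e", tail = "a", head = "a",
                                k_fwd = 1, k_bwd = 1)),
               "duplicate state")
  expect_error(build_network(c("a", "b"),
                             ed(id = "e", tail = "a", head = "c",
                                k_fwd = 1, k_bwd = 1)),
               "unknown state")
  expect_error(build_network(c("a", "b"),
                             ed(id = "e", tail = "a", head = "b",
                                k_fwd = 0, k_bwd = 1)),
               "k_fwd")
  expect_error(build_network(c("a", "b"),
                             ed(id = "e", tail = "a", head = "b",
                                k_fwd = 1, k_bwd = -1)),
               "k_bwd")
  expect_error(build_network(c("a", "b"),
                             ed(id = "e", tail = "a", head = "a",
                                k_fwd = 1, k_bwd = 1)),
               "self-loop")
  expect_error(build_network(c("a", "b", "c", "d"),
                             ed(id = c("e1", "e2"),
                                tail = c("a", "c"), head = c("b", "d"),
                                k_fwd = 1, k_bwd = 1)),
               "disconnected")
  # absorbing state 3: edge 2-3 non-invertible into a dead end
  expect_error(build_network(c("1", "2", "3"),
                             ed(id = c("e1", "e2"),
                                tail = c("1", "2"), head = c("2", "3"),
                                k_fwd = c(1, 1), k_bwd = c(1, 0))),
               "ergodic")
})

test_that("the four-state inhibition multigraph with a parallel catalytic edge builds", {
  net <- mm_inhibition_network("noncompetitive")
  expect_equal(length(net$states), 4L)
  expect_equal(nrow(net$edges), 5L)
  # bind and cat connect the same state pair in a multigraph
  pair <- net$edges[net$edges$id %in% c("bind", "cat"), ]
  expect_setequal(unique(c(pair$tail, pair$head)), c("E", "ES"))
  expect_false(net$edges$reversible[net$edges$id == "cat"])
})

test_that("steady state matches closed forms and an independent eigen oracle", {
  ed <- function(...) data.frame(..., stringsAsFactors = FALSE)
  sym <- build_network(c("0", "1"),
                       ed(id = "e", tail = "0", head = "1", k_fwd = 1, k_bwd = 1))
  ss <- steady_state(sym)
  expect_equal(unname(ss$pi), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(unname(ss$jnet), 0, tolerance = 1e-14)
  expect_equal(unname(ss$tau), 1, tolerance = 1e-12)

  asym <- build_network(c("0", "1"),
                        ed(id = "e", tail = "0", head = "1", k_fwd = 2, k_bwd = 1))
  expect_equal(unname(steady_state(asym)$pi), c(1 / 3, 2 / 3),
               tolerance = 1e-12)

  ring <- build_network(c("a", "b", "c"),
                        ed(id = c("e1", "e2", "e3"),
                           tail = c("a", "b", "c"), head = c("b", "c", "a"),
                           k_fwd = 2, k_bwd = 1))
  ssr <- steady_state(ring)
  expect_equal(unname(ssr$pi), oracle_pi(ring), tolerance = 1e-10)
  # uniform driven ring: equal net flux on every edge
  expect_lt(diff(range(ssr$jnet)), 1e-14)
  expect_equal(unname(ssr$jnet[1L]),
               oracle_pi(ring)[1L] * 2 - oracle_pi(ring)[2L] * 1,
               tolerance = 1e-10)
})

test_that("steady-state invariants hold across random networks", {
  set.seed(401)
  for (rep in 1:25) {
    net <- rand_net(sample(3:6, 1L))
    ss <- steady_state(net)
    expect_equal(sum(ss$pi), 1, tolerance = 1e-12)
    expect_true(all(ss$pi > 0))
    expect_equal(ss$tau, ss$p_fwd + ss$p_bwd, tolerance = 1e-12)
    expect_equal(ss$jnet, ss$p_fwd - ss$p_bwd, tolerance = 1e-12)
    expect_true(all(abs(ss$jnet) <= ss$tau + 1e-14))
    # stationarity: generator applied to pi vanishes
    Q <- caliberflow:::.generator(net)
    expect_lt(max(abs(ss$pi %*% Q)), 1e-10 * max(ss$tau))
    # Kirchhoff: per-node signed flux sums vanish
    expect_lt(max(abs(caliberflow:::.node_flux_residual(ss))),
              1e-10 * max(ss$tau))
    # chord-flux reconstruction reproduces every edge flux
    expect_equal(reconstruct_edge_fluxes(ss$basis, ss$j_cycle), ss$jnet,
                 tolerance = 1e-9)
  }
})

test_that("non-invertible edges have zero backward flux and tau = J", {
  net <- mm_inhibition_network("noncompetitive")
  ss <- steady_state(net)
  expect_identical(ss$p_bwd[["cat"]], 0)
  expect_identical(ss$tau[["cat"]], ss$jnet[["cat"]])
})

test_that("cycle basis is deterministic with non-invertible edges as chords", {
  f1 <- f1_model()
  b <- cycle_basis(f1)
  expect_length(b$chords, 1L)
  mem <- caliberflow:::.cycle_members(b, b$chords)
  expect_setequal(mem$id, c("T", "D"))  # the cycle is both edges

  nc <- mm_inhibition_network("noncompetitive")
  bn <- cycle_basis(nc)
  expect_setequal(bn$chords, c("cat", "i2"))
  expect_equal(length(bn$chords), nrow(nc$edges) - length(nc$states) + 1L)
  # incidence has +1 on each chord itself
  for (ch in bn$chords) expect_identical(bn$incidence[ch, ch], 1L)

  # a pure tree has no chords and an empty incidence
  tree <- build_network(c("a", "b", "c"),
                        data.frame(id = c("e1", "e2"),
                                   tail = c("a", "b"), head = c("b", "c"),
                                   k_fwd = 1, k_bwd = 1))
  bt <- cycle_basis(tree)
  expect_length(bt$chords, 0L)
  expect_equal(nrow(bt$incidence), 0L)

  # a non-invertible edge that cannot be a chord is refused
  bad <- build_network(c("a", "b", "c"),
                       data.frame(id = c("e1", "e2", "e3"),
                                  tail = c("a", "b", "c"),
                                  head = c("b", "c", "a"),
                                  k_fwd = 1, k_bwd = c(1, 0, 0)))
  expect_error(cycle_basis(bad), "chord")
})

test_that("chord-flux reconstruction is the exact Kirchhoff inverse", {
  b <- cycle_basis(mm_inhibition_network("noncompetitive"))
  zero <- reconstruct_edge_fluxes(b, c(cat = 0, i2 = 0))
  expect_true(all(zero == 0))
  # unicycle: a chord flux c puts +-c on every cycle edge
  bf <- cycle_basis(f1_model())
  rec <- reconstruct_edge_fluxes(bf, stats::setNames(0.7, bf$chords))
  expect_true(all(abs(rec) == 0.7))
})

test_that("entropy production: zero at detailed balance, edge-wise equality, 2JF", {
  # detailed-balance triangle via Arrhenius with zero affinity splits
  states <- c("a", "b", "c")
  topo <- build_network(states,
                        data.frame(id = c("e1", "e2", "e3"),
                                   tail = c("a", "a", "b"),
                                   head = c("b", "c", "c"),
                                   k_fwd = 1, k_bwd = 1))
  pars <- arrhenius_params(node_energy = c(a = 0, b = 0.5, c = -0.3),
                           barrier = c(e1 = 1, e2 = 0.2, e3 = 0.7),
                           affinity_split = c(e1 = 0, e2 = 0, e3 = 0))
  db <- rates_from_arrhenius(pars, topo)
  ssdb <- steady_state(db)
  expect_equal(ssdb$epr, 0, tolerance = 1e-12)
  expect_equal(max(abs(caliberflow:::.cycle_forces(db, ssdb$basis))), 0,
               tolerance = 1e-12)

  set.seed(402)
  for (rep in 1:10) {
    net <- rand_net(4L)
    ss <- steady_state(net)
    expect_gte(ss$epr, 0)
    expect_equal(entropy_production_rate(net, ss, form = "cycle"),
                 entropy_production_rate(net, ss, form = "edgewise"),
                 tolerance = 1e-9)
  }

  # unicycle: EPR = 2 J F
  f1 <- f1_model()
  ss1 <- steady_state(f1)
  fc <- caliber_forces(f1)$f_cycle
  expect_equal(ss1$epr, 2 * ss1$j_cycle[[1L]] * fc[[1L]], tolerance = 1e-12)
})

test_that("EPR is non-negative over a large random ensemble, zero only at equilibrium", {
  set.seed(403)
  eprs <- replicate(1000, {
    net <- rand_net(sample(3:5, 1L))
    steady_state(net)$epr
  })
  expect_true(all(eprs >= 0))
  expect_true(all(eprs > 0))  # generic driven draws are strictly dissipative
})
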