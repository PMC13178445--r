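# Flow response rules: energy scaling, barrier routing, the Jacobian, the
# finite-difference oracle, and the cycle response symmetry.

test_that("node-energy responses scale fluxes by pi_n (motor closed form)", {
  f1 <- f1_model()
  ss <- steady_state(f1)
  jc <- ss$j_cycle[[1L]]
  for (n in c("0", "1")) {
    # d ln Jc/dE_n = pi_n, and the same for both traffics
    expect_equal(energy_response(f1, ss, n, "cycleflux:T") / jc,
                 ss$pi[[n]], tolerance = 1e-12)
    for (e in c("T", "D")) {
      expect_equal(energy_response(f1, ss, n, paste0("traffic:", e)) /
                     ss$tau[[e]],
                   ss$pi[[n]], tolerance = 1e-12)
    }
    fd <- finite_difference_oracle(f1, paste0("energy:", n), "cycleflux:T")
    expect_equal(energy_response(f1, ss, n, "cycleflux:T"), fd,
                 tolerance = 1e-6)
  }
  expect_error(energy_response(f1, ss, "0", "prob:1"), "not a flux")
})

test_that("finite node-energy shifts leave every flux ratio invariant", {
  kp <- kp_fixture()
  ss <- steady_state(kp)
  ratios0 <- ss$j_cycle / ss$j_cycle[[1L]]
  eps0 <- kp_metrics(kp, ss)$eps
  for (n in c("E", "ER", "EWs")) {
    kp2 <- caliberflow:::.apply_knob(kp, paste0("energy:", n), 0.8)
    ss2 <- steady_state(kp2)
    expect_equal(ss2$j_cycle / ss2$j_cycle[[1L]], ratios0, tolerance = 1e-10)
    # hence the error rate is untouched by node energies
    expect_equal(kp_metrics(kp2, ss2)$eps, eps0, tolerance = 1e-10)
    # and all fluxes share one common scale factor
    fac <- ss2$tau / ss$tau
    expect_lt(diff(range(fac)), 1e-10 * fac[[1L]])
  }
})

test_that("EPR scales with node energy as pi_n * EPR; cycle forces do not move", {
  set.seed(421)
  net <- rand_net(5L)
  ss <- steady_state(net)
  for (n in net$states[c(1L, 3L)]) {
    an <- energy_response(net, ss, n, "epr")
    expect_equal(an, ss$pi[[n]] * ss$epr, tolerance = 1e-12)
    fd <- finite_difference_oracle(net, paste0("energy:", n), "epr")
    expect_lt(abs(an - fd), 1e-4 * max(abs(fd), 1))
    # cycle forces are energy-invariant
    f0 <- caliber_forces(net)$f_cycle
    f1_ <- caliber_forces(caliberflow:::.apply_knob(net, paste0("energy:", n),
                                                    0.5))$f_cycle
    expect_equal(f1_, f0, tolerance = 1e-12)
  }
})

test_that("barrier responses reproduce the motor's closed forms", {
  set.seed(422)
  for (rep in 1:5) {
    k <- exp(stats::runif(4, -2, 2))
    f1 <- f1_model(k[1L], k[2L], k[3L], k[4L])
    ss <- steady_state(f1)
    jc <- ss$j_cycle[[1L]]
    SigT <- k[1L] + k[2L]; SigD <- k[3L] + k[4L]; Sig <- SigT + SigD
    expect_equal(barrier_response(f1, ss, "T", "cycleflux:T") / jc,
                 -SigD / Sig, tolerance = 1e-10)
    expect_equal(barrier_response(f1, ss, "D", "cycleflux:T") / jc,
                 -SigT / Sig, tolerance = 1e-10)
  }
})

test_that("analytic barrier and energy responses match the oracle on random networks", {
  set.seed(423)
  for (rep in 1:8) {
    net <- rand_net(4L)
    ss <- steady_state(net)
    obs <- c(paste0("prob:", net$states[2L]),
             paste0("traffic:", net$edges$id[1L]),
             paste0("cycleflux:", ss$basis$chords[1L]),
             "epr")
    knob_edge <- net$edges$id[nrow(net$edges)]
    for (o in obs) {
      an <- barrier_response(net, ss, knob_edge, o)
      fd <- finite_difference_oracle(net, paste0("barrier:", knob_edge), o)
      expect_lt(abs(an - fd), 1e-4 * max(abs(fd), 1e-3))
    }
    n <- net$states[1L]
    for (o in obs[-1L]) {
      if (startsWith(o, "prob")) next
      an <- energy_response(net, ss, n, o)
      fd <- finite_difference_oracle(net, paste0("energy:", n), o)
      expect_lt(abs(an - fd), 1e-4 * max(abs(fd), 1e-3))
    }
  }
})

test_that("a zero-flux edge routes nothing: all other observables invariant", {
  net <- mm_inhibition_network("competitive")
  ss <- steady_state(net)
  expect_lt(abs(ss$jnet[["i1"]]), 1e-14)
  for (o in c("prob:E", "prob:ES", "traffic:bind", "cycleflux:cat")) {
    expect_equal(barrier_response(net, ss, "i1", o), 0, tolerance = 1e-13)
  }
  # own traffic is the one thing that moves; routed to the oracle
  expect_warning(own <- barrier_response(net, ss, "i1", "traffic:i1"),
                 "own-traffic")
  expect_equal(own, -ss$tau[["i1"]], tolerance = 1e-5)
})

test_that("force-rate Jacobian has the printed row structure and known rank", {
  set.seed(424)
  net <- rand_net(4L)
  rm_ <- force_rate_jacobian(net)
  A <- rm_$jacobian
  expect_equal(nrow(A), ncol(A))  # square by the dimension count
  nch <- length(cycle_basis(net)$chords)
  # cycle-force columns are exact signed sums of edge-force columns, so the
  # rank falls short of full by exactly the number of chords
  expect_equal(rm_$rank, nrow(A) - nch)

  # edge-force column: +1/2 on the forward direction, -1/2 on the backward
  id <- net$edges$id[1L]
  col <- A[, paste0("edge:", id)]
  expect_equal(col[[paste0(id, "+")]], 0.5)
  expect_equal(col[[paste0(id, "-")]], -0.5)
  expect_true(all(col[setdiff(names(col), paste0(id, c("+", "-")))] == 0))

  # cycle-force column: +-1/2 on each directed rate around the cycle
  b <- cycle_basis(net)
  ch <- b$chords[1L]
  mem <- caliberflow:::.cycle_members(b, ch)
  colc <- A[, paste0("cycle:", ch)]
  for (r in seq_len(nrow(mem))) {
    expect_equal(colc[[paste0(mem$id[r], "+")]], 0.5 * mem$sign[r])
    expect_equal(colc[[paste0(mem$id[r], "-")]], -0.5 * mem$sign[r])
  }

  # node-force column agrees with independent numerical differentiation
  n <- net$states[2L]
  coln <- A[, paste0("node:", n)]
  fnode <- function(net2) caliber_forces(net2)$f_node[[n]]
  h <- 1e-7
  for (d in rownames(A)) {
    id2 <- substr(d, 1, nchar(d) - 1L); fwd <- endsWith(d, "+")
    bump <- function(s) {
      e <- match(id2, net$edges$id)
      net2 <- net
      if (fwd) net2$edges$k_fwd[e] <- net2$edges$k_fwd[e] * exp(s)
      else net2$edges$k_bwd[e] <- net2$edges$k_bwd[e] * exp(s)
      caliberflow:::.with_rates(net2, net2$edges$k_fwd, net2$edges$k_bwd)
    }
    num <- (fnode(bump(h)) - fnode(bump(-h))) / (2 * h)
    expect_equal(coln[[d]], num, tolerance = 1e-6 * max(1, abs(num)))
  }
})

test_that("the catalytic chord contributes ln(kcat) to its Jacobian column", {
  net <- mm_inhibition_network("competitive")
  rm_ <- force_rate_jacobian(net)
  expect_equal(rm_$jacobian["cat+", "cycle:cat"], 1)
  expect_equal(rm_$jacobian["bind+", "cycle:cat"], 0.5)
  expect_equal(rm_$jacobian["bind-", "cycle:cat"], -0.5)
  expect_false("cat-" %in% rownames(rm_$jacobian))
  expect_false("edge:cat" %in% colnames(rm_$jacobian))
})

test_that("barrier sensitivities over a cycle sum to -1", {
  set.seed(425)
  # the 2-edge motor, many random rate draws: exact closed-form sum
  for (rep in 1:10) {
    k <- exp(stats::runif(4, -3, 3))
    f1 <- f1_model(k[1L], k[2L], k[3L], k[4L])
    sr <- sensitivity_sum_rule(f1, steady_state(f1))
    expect_equal(sr$sum, -1, tolerance = 1e-10)
    expect_true(sr$unicyclic)
  }
  # the rule extends to a 3-edge unicycle (uniform barrier raise = time
  # rescaling), confirmed against the finite-difference oracle
  ring <- build_network(c("a", "b", "c"),
                        data.frame(id = c("e1", "e2", "e3"),
                                   tail = c("a", "b", "c"),
                                   head = c("b", "c", "a"),
                                   k_fwd = c(2, 3, 1.5), k_bwd = c(1, 0.5, 1)))
  ssr <- steady_state(ring)
  sr <- sensitivity_sum_rule(ring, ssr)
  expect_equal(sr$sum, -1, tolerance = 1e-10)
  fd_sum <- sum(vapply(ring$edges$id, function(e) {
    finite_difference_oracle(ring, paste0("barrier:", e),
                             paste0("cycleflux:", ssr$basis$chords))
  }, numeric(1))) / ssr$j_cycle[[1L]]
  expect_equal(fd_sum, -1, tolerance = 1e-5)

  # equilibrium unicycle: ln Jc undefined, absolute responses all vanish
  eq <- build_network(c("0", "1"),
                      data.frame(id = c("D", "T"), tail = c("1", "0"),
                                 head = c("0", "1"),
                                 k_fwd = c(2, 1), k_bwd = c(1, 2)))
  sseq <- steady_state(eq)
  expect_error(sensitivity_sum_rule(eq, sseq), "zero")
  expect_equal(barrier_response(eq, sseq, "T", "cycleflux:T"), 0,
               tolerance = 1e-14)

  # multicyclic networks are computed but flagged
  kp <- kp_fixture()
  expect_warning(srm <- sensitivity_sum_rule(kp, steady_state(kp),
                                             chord = "incR"),
                 "unicyclic")
  expect_false(srm$unicyclic)
})

test_that("the oracle returns near-zero for a zero-sensitivity knob", {
  net <- mm_inhibition_network("uncompetitive")
  v <- finite_difference_oracle(net, "barrier:u1", "cycleflux:cat")
  expect_equal(v, 0, tolerance = 1e-9)
  r <- finite_difference_oracle(net, "barrier:bind", "cycleflux:cat",
                                richardson = TRUE)
  expect_equal(r$value, r$extrapolated, tolerance = 1e-6 * abs(r$value))
})
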