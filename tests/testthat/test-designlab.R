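# Application systems: rotary motor + ETP, proofreading fixtures and barrier
# classification, enzyme inhibition with iETP and dead-end analysis.

test_that("the ETP bound has the right limits and beats brute-force search", {
  expect_equal(etp_bound(0, tau_tot = 3), 0)
  expect_equal(etp_bound(100, tau_tot = 3), 1.5, tolerance = 1e-10)
  expect_equal(etp_bound(1.2, 4), 2 * tanh(0.6), tolerance = 1e-14)
  b5 <- etp_bound(2, 10, n_edges = 5L)
  expect_equal(as.numeric(b5), 2 * tanh(0.4), tolerance = 1e-14)
  expect_true(isTRUE(attr(b5, "extension")))

  # independent numeric maximization of J/tau_tot at fixed cycle force
  set.seed(441)
  for (Fc in c(0.8, 2.5)) {
    o <- oracle_max_efficiency(Fc)
    expect_equal(o$efficiency, 0.5 * tanh(Fc / 2), tolerance = 1e-6)
    # the maximizer balances the traffic
    expect_lt(abs(o$tau1 - o$tau2) / (o$tau1 + o$tau2), 1e-4)
  }
})

test_that("the motor model satisfies its torque-dependent drive and limits", {
  for (g in c(-30, -5, 0, 12, 30)) {
    f1 <- f1_model(torque = g)
    p <- attr(f1, "f1_params")
    e <- f1$edges
    lhs <- log(e$k_fwd[e$id == "T"] * e$k_fwd[e$id == "D"] /
                 (e$k_bwd[e$id == "T"] * e$k_bwd[e$id == "D"]))
    expect_equal(lhs, p$delta_mu + g * p$delta_theta / kBT_pN_nm,
                 tolerance = 1e-10)
  }
  expect_error(f1_model(torque = 31), "30")
  expect_error(f1_model(load_sharing = c(1, 0, 0, 0)), "delta_theta")
  # zero torque: cycle force is half the chemical drive
  f1 <- f1_model(torque = 0)
  expect_equal(caliber_forces(f1)$f_cycle[[1L]],
               attr(f1, "f1_params")$delta_mu / 2, tolerance = 1e-12)
})

test_that("processive efficiency saturates its bound exactly at equal traffic", {
  # symmetric rates put pi = (1/2, 1/2) and equal traffic on both edges
  sym <- f1_model(kT_plus = 2, kT_minus = 0.4, kD_plus = 2, kD_minus = 0.4)
  pe <- processive_efficiency(sym)
  expect_lt(abs(diff(pe$tau)) / sum(pe$tau), 1e-12)
  expect_equal(pe$gap, 0, tolerance = 1e-12)

  # a strongly imbalanced motor falls far below the bound
  imb <- f1_model(kT_plus = 0.05, kT_minus = 0.001, kD_plus = 50,
                  kD_minus = 1)
  pei <- processive_efficiency(imb)
  expect_gt(pei$tau[["D"]] / pei$tau[["T"]], 10)
  expect_gt(pei$gap / pei$bound, 0.3)

  # the gap is non-negative for arbitrary rates
  set.seed(442)
  for (rep in 1:200) {
    k <- exp(stats::runif(4, -3, 3))
    pe <- processive_efficiency(f1_model(k[1L], k[2L], k[3L], k[4L]))
    expect_gte(pe$gap, -1e-12)
  }
  expect_error(processive_efficiency(kp_fixture()), "unicyclic")
})

test_that("classic proofreading needs barrier asymmetry, not just node energy", {
  expect_equal(classic_kp_model(0)$error_rate, 0, tolerance = 1e-12)

  ck <- classic_kp_model(3)
  eR <- ck$R$edges; eW <- ck$W$edges
  # unbinding rates differ by exp(delta) while incorporations are identical
  expect_equal(eW$k_bwd[eW$id == "bind"] / eR$k_bwd[eR$id == "bind"], exp(3),
               tolerance = 1e-12)
  expect_equal(eW$k_fwd[eW$id == "inc"], eR$k_fwd[eR$id == "inc"])
  expect_lt(ck$error_rate, 0)

  # without the compensating barrier, forward incorporation rates differ
  ck2 <- classic_kp_model(3, symmetric_incorporation = FALSE)
  expect_equal(ck2$W$edges$k_fwd[ck2$W$edges$id == "inc"],
               exp(3) * ck2$R$edges$k_fwd[ck2$R$edges$id == "inc"],
               tolerance = 1e-12)
})

test_that("the proofreading fixture operates in a discriminating, driven regime", {
  kp <- kp_fixture()
  ss <- steady_state(kp)
  m <- kp_metrics(kp, ss)
  expect_lt(m$eps, -1)
  expect_gt(m$fluxes[["JRp"]], 0)
  expect_gt(m$fluxes[["JWp"]], 0)
  expect_gt(m$r_prime, 0)
  # both cycle affinities equal their free-energy budgets by construction
  p <- attr(kp, "kp_params")
  fc <- caliber_forces(kp)$f_cycle
  expect_equal(2 * fc[["incR"]], p$dmu_p, tolerance = 1e-10)
  expect_equal(2 * fc[["transR"]], p$dmu_ntp, tolerance = 1e-10)
  expect_equal(2 * fc[["incW"]], p$dmu_p, tolerance = 1e-10)
  expect_equal(2 * fc[["transW"]], p$dmu_ntp, tolerance = 1e-10)
})

test_that("barrier gradients classify the cognate discard as a free lunch", {
  kp <- kp_fixture()
  ss <- steady_state(kp)
  pg <- performance_gradients(kp, ss)
  pg <- stats::setNames(split(pg, pg$edge), pg$edge)
  # raising the Right-substrate discard barrier: speed up, error and cost down
  expect_equal(pg[["discR"]]$class, "free_lunch")
  expect_equal(pg[["discR"]]$speed_up_direction, 1)
  # accelerating Wrong incorporation compounds error and cost
  expect_equal(pg[["incW"]]$class, "detrimental")
  expect_equal(pg[["incW"]]$speed_up_direction, -1)

  # classification is stable under finite-difference recomputation
  cm <- kp_chord_map()
  p <- attr(kp, "kp_params")
  for (edge in c("discR", "incW", "bindR")) {
    dj <- vapply(cm, function(ch) {
      finite_difference_oracle(kp, paste0("barrier:", edge),
                               paste0("cycleflux:", ch))
    }, numeric(1))
    dS <- dj[["JR"]] + dj[["JW"]]
    deps <- (dj[["JW"]] / ss$j_cycle[[cm[["JW"]]]] -
               dj[["JR"]] / ss$j_cycle[[cm[["JR"]]]]) / log(10)
    dC <- dS * p$dmu_p + (dj[["JRp"]] + dj[["JWp"]]) * p$dmu_ntp
    row <- pg[[edge]]
    expect_equal(sign(dS), row$speed_up_direction)
    expect_lt(abs(deps - row$deps_dB), 1e-4 * max(abs(deps), 1e-4))
    expect_lt(abs(dC - row$dC_dB), 1e-4 * max(abs(dC), 1e-3))
  }
})

test_that("barrier scans rise then plateau along the free-lunch direction", {
  kp <- kp_fixture()
  scan <- barrier_saturation_scan(kp, "discR", seq(-1, 14, by = 0.5))
  # speed is monotone non-decreasing along the raise and flattens out
  expect_true(all(diff(scan$S) > -1e-12))
  expect_false(scan$plateau_S[2L])
  expect_true(scan$plateau_S[nrow(scan)])
  expect_true(scan$plateau_eps[nrow(scan)])
  expect_true(scan$plateau_C[nrow(scan)])
})

test_that("inhibition topologies have the advertised dead ends and leaks", {
  comp <- mm_inhibition_network("competitive")
  ssc <- steady_state(comp)
  expect_lt(abs(ssc$jnet[["i1"]]), 1e-14)

  unc <- mm_inhibition_network("uncompetitive")
  ssu <- steady_state(unc)
  expect_lt(abs(ssu$jnet[["u1"]]), 1e-14)

  # futile noncompetitive loop still pumps a strictly positive leak flux
  nc <- mm_inhibition_network("noncompetitive", project_fleak = TRUE)
  expect_equal(leak_cycle_force(nc), 0, tolerance = 1e-12)
  ssn <- steady_state(nc)
  expect_gt(ssn$j_cycle[["i2"]], 0)

  # removing catalysis restores equilibrium: the leak dies with it
  nc0 <- mm_inhibition_network("noncompetitive", rates = c(kcat = 1e-9),
                               project_fleak = TRUE)
  expect_lt(abs(steady_state(nc0)$j_cycle[["i2"]]), 1e-9)

  expect_error(mm_inhibition_network("mixed"), "arg")
})

test_that("iETP: the decomposition is exact and the bounds sandwich Jcat", {
  nc <- mm_inhibition_network("noncompetitive", project_fleak = TRUE)
  ib <- ietp_bounds(nc)
  expect_equal(ib$identity, ib$j_cat, tolerance = 1e-10 * abs(ib$j_cat))
  expect_lte(ib$lower, ib$j_cat * (1 + 1e-10))
  expect_lte(ib$j_cat, ib$upper * (1 + 1e-10))

  # equal sideway traffics attain the lower bound
  eq <- equal_sideway_network()
  sse <- steady_state(eq)
  taus <- sse$tau[c("i1", "i2", "i3")]
  expect_lt(diff(range(taus)) / mean(taus), 1e-9)
  ibe <- ietp_bounds(eq, sse)
  expect_equal(ibe$j_cat, ibe$lower, tolerance = 1e-8 * abs(ibe$j_cat))

  # vanishing backward one-way flux on the binding edge attains the upper
  # bound: shrink koff so p_ES->E is negligible
  sat <- mm_inhibition_network("noncompetitive",
                               rates = c(koff = 1e-9, kcat = 25),
                               project_fleak = TRUE)
  ibs <- ietp_bounds(sat)
  expect_lt(ibs$p_back_bind / ibs$tau_bind, 1e-6)
  expect_equal(ibs$j_cat, ibs$upper, tolerance = 1e-5 * abs(ibs$upper))

  # dead-end kinds are refused, as is a driven (non-futile) loop
  expect_error(ietp_bounds(mm_inhibition_network("competitive")), "dead-end")
  expect_error(ietp_bounds(mm_inhibition_network("noncompetitive")),
               "futile")
})

test_that("the iETP sandwich holds across a sampled futile-loop ensemble", {
  cfg <- sampler_config("mm-noncompetitive", 300,
                        constraints = list(f_cycle = c(i2 = 0)), seed = 7)
  se <- scatter_experiment(cfg, "ietp")
  expect_equal(se$n_violations, 0L)
  expect_true(all(se$table$j_leak > 0))
})

test_that("finite barrier shifts on dead ends change nothing but their own traffic", {
  comp <- mm_inhibition_network("competitive")
  rep_c <- deadend_invariance_check(comp, "i1", shifts = c(-2, 2))
  for (r in rep_c$results) {
    expect_lt(r$dpi, 1e-10)
    expect_lt(r$dtau_other, 1e-10)
    expect_lt(r$dj_cycle, 1e-10)
    expect_equal(r$own_tau_factor, exp(-r$shift), tolerance = 1e-9)
  }
  expect_equal(rep_c$derivative, 0, tolerance = 1e-13)

  unc <- mm_inhibition_network("uncompetitive")
  rep_u <- deadend_invariance_check(unc, "u1", shifts = c(-2, 2))
  for (r in rep_u$results) expect_lt(max(r$dpi, r$dtau_other, r$dj_cycle),
                                     1e-10)

  # a loop edge with nonzero flux is refused, and its responses are nonzero
  nc <- mm_inhibition_network("noncompetitive", project_fleak = TRUE)
  expect_error(deadend_invariance_check(nc, "i2"), "not a dead end")
  ssn <- steady_state(nc)
  expect_gt(abs(barrier_response(nc, ssn, "i2", "cycleflux:cat")), 1e-6)
})
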