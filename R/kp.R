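# Kinetic proofreading fixtures and barrier-routing analysis.

#' Classic two-ladder proofreading model
#'
#' The foundational discrimination scheme: one binding/incorporation ladder per
#' substrate (Right and Wrong), modeled as 2-state unicycles over a free enzyme
#' `E` and a bound state `EX`. The Wrong ladder destabilizes its bound state by
#' a node energy `delta` (every rate leaving `EW` gains `exp(delta)`). Keeping
#' the forward incorporation rates *identical* between substrates then
#' mathematically requires elevating the Wrong incorporation barrier by exactly
#' the same `delta` — barrier asymmetry is implicit in the classic model
#' (`symmetric_incorporation = TRUE`). With it, the unbinding rates differ by
#' `exp(delta)` while forward incorporation rates match.
#'
#' @param delta discrimination energy (kT), >= 0.
#' @param symmetric_incorporation raise the Wrong incorporation barrier by
#'   `delta` so forward incorporation rates match (default `TRUE`).
#' @param kon,koff,kinc,krev shared base rates: binding `E -> EX`, unbinding,
#'   incorporation `EX -> E`, and its reverse.
#' @return list with networks `R`, `W` and the `error_rate`
#'   `eps = log10(JW/JR)`.
#' @export
classic_kp_model <- function(delta, symmetric_incorporation = TRUE,
                             kon = 1, koff = 5, kinc = 1, krev = 0.01) {
  stopifnot(delta >= 0)
  ladder <- function(koff_x, kinc_x, krev_x, nm) {
    build_network(states = c("E", "EX"),
                  edges = data.frame(id = c("bind", "inc"),
                                     tail = c("E", "EX"), head = c("EX", "E"),
                                     k_fwd = c(kon, kinc_x),
                                     k_bwd = c(koff_x, krev_x),
                                     stringsAsFactors = FALSE),
                  name = nm)
  }
  R <- ladder(koff, kinc, krev, "kp-classic-R")
  W <- if (symmetric_incorporation) {
    # node energy +delta on EW, incorporation barrier +delta
    ladder(koff * exp(delta), kinc, krev * exp(-delta), "kp-classic-W")
  } else {
    # node energy only: all rates out of EW scaled
    ladder(koff * exp(delta), kinc * exp(delta), krev, "kp-classic-W")
  }
  jr <- steady_state(R)$j_cycle[["inc"]]
  jw <- steady_state(W)$j_cycle[["inc"]]
  list(R = R, W = W, error_rate = log10(jw / jr))
}

#' Synthetic four-cycle proofreading network
#'
#' A five-state proofreading network with the four fundamental cycles of a
#' polymerase-style proofreader: for each substrate `X` in \{R, W\} the enzyme
#' `E` binds (`bindX`: E <-> EX), may transfer the substrate to a checked
#' state (`transX`: EX <-> EXs), incorporate (`incX`: EX -> E, reversible
#' chord) or discard from the checked state (`discX`: EXs -> E). The
#' deterministic spanning tree is the star of binding and discard edges around
#' `E`, so the four chords `incR`, `incW`, `transR`, `transW` carry the
#' incorporation fluxes (JR, JW) and the discard-cycle fluxes (JR', JW').
#'
#' The wild-type rates are synthetic (real polymerase/ribosome rate sets are
#' not built in): the Right substrate's cycles satisfy
#' `2 F_inc = dmu_p` and `2 F_disc = dmu_ntp` by construction, and the Wrong
#' substrate is discriminated by raising its bound-state node energies by
#' `delta` plus the matching incorporation-barrier shift of the classic
#' scheme, which preserves both cycle affinities.
#'
#' @param delta discrimination energy (kT).
#' @param dmu_p free energy of product-bond formation (kT): incorporation-cycle
#'   affinity.
#' @param dmu_ntp free energy of NTP hydrolysis (kT): discard-cycle affinity.
#' @param kon,koff,ktr_f,ktr_b,kdis,kinc base Right-substrate rates; the two
#'   reverse rates `kinc_b`, `kdis_b` are solved from the cycle affinities.
#' @return a `machine_network` with attribute `kp_params`.
#' @export
kp_fixture <- function(delta = 4, dmu_p = 6, dmu_ntp = 20,
                       kon = 1.2, koff = 10, ktr_f = 0.8, ktr_b = 2,
                       kdis = 0.5, kinc = 1.5) {
  # reverse rates fixed by the two cycle affinities (Right substrate):
  #   ln(kon kinc / (koff kinc_b)) = dmu_p
  #   ln(kon ktr_f kdis / (koff ktr_b kdis_b)) = dmu_ntp
  kinc_b <- kon * kinc / (koff * exp(dmu_p))
  kdis_b <- kon * ktr_f * kdis / (koff * ktr_b * exp(dmu_ntp))
  ed <- function(id, tail, head, kf, kb) {
    data.frame(id = id, tail = tail, head = head, k_fwd = kf, k_bwd = kb,
               stringsAsFactors = FALSE)
  }
  d <- exp(delta)
  edges <- rbind(
    ed("bindR", "E", "ER", kon, koff),
    ed("bindW", "E", "EW", kon, koff * d),
    ed("transR", "ER", "ERs", ktr_f, ktr_b),
    ed("transW", "EW", "EWs", ktr_f * d, ktr_b * d),
    ed("discR", "ERs", "E", kdis, kdis_b),
    ed("discW", "EWs", "E", kdis * d, kdis_b),
    # W incorporation: node-energy factor exp(delta) cancelled by the classic
    # barrier shift, reverse rate keeps the barrier shift only
    ed("incR", "ER", "E", kinc, kinc_b),
    ed("incW", "EW", "E", kinc, kinc_b / d))
  net <- build_network(states = c("E", "ER", "EW", "ERs", "EWs"),
                       edges = edges, name = "kp-4cycle")
  attr(net, "kp_params") <- list(delta = delta, dmu_p = dmu_p,
                                 dmu_ntp = dmu_ntp)
  net
}

#' Chord labels of the proofreading fixture
#'
#' Maps the four performance fluxes to the chords of [kp_fixture()].
#' @return named character vector.
#' @export
kp_chord_map <- function() {
  c(JR = "incR", JW = "incW", JRp = "transR", JWp = "transW")
}

#' Proofreading metrics of a solved network
#'
#' Convenience wrapper: extracts (JR, JW, JR', JW') from the chord fluxes and
#' forms the performance metrics.
#'
#' @param net a proofreading `machine_network`.
#' @param ss optional precomputed steady state.
#' @param dmu_p,dmu_ntp free-energy constants (kT); default from the fixture's
#'   `kp_params` attribute if present.
#' @param chord_map chord labels (default [kp_chord_map()]).
#' @return a `proofreading_metrics`.
#' @export
kp_metrics <- function(net, ss = NULL, dmu_p = NULL, dmu_ntp = NULL,
                       chord_map = kp_chord_map()) {
  p <- attr(net, "kp_params")
  if (is.null(dmu_p)) dmu_p <- if (!is.null(p)) p$dmu_p else 2
  if (is.null(dmu_ntp)) dmu_ntp <- if (!is.null(p)) p$dmu_ntp else 20
  if (is.null(ss)) ss <- steady_state(net)
  metrics_from_fluxes(JR = ss$j_cycle[[chord_map[["JR"]]]],
                      JW = ss$j_cycle[[chord_map[["JW"]]]],
                      JRp = ss$j_cycle[[chord_map[["JRp"]]]],
                      JWp = ss$j_cycle[[chord_map[["JWp"]]]],
                      dmu_p = dmu_p, dmu_ntp = dmu_ntp)
}

#' Per-barrier performance gradients with classification
#'
#' For every edge barrier, computes the analytic sensitivities of speed, error
#' and cost `(dS/dB, deps/dB, dC/dB)` through the cycle-flux routing rule, then
#' classifies the barrier by the metric signs in the direction that raises
#' speed: a `free_lunch` barrier raises speed while lowering both error and
#' cost; a `detrimental` one compounds error and cost; the rest enforce the
#' standard `trade_off` (speed up, cost up). Dead-end-like edges with no speed
#' leverage are `neutral`.
#'
#' @inheritParams kp_metrics
#' @return data frame: edge, dS_dB, deps_dB, dC_dB, speed_up_direction
#'   (+1 = raise barrier, -1 = lower), class.
#' @export
performance_gradients <- function(net, ss = NULL, dmu_p = NULL,
                                  dmu_ntp = NULL, chord_map = kp_chord_map()) {
  p <- attr(net, "kp_params")
  if (is.null(dmu_p)) dmu_p <- if (!is.null(p)) p$dmu_p else 2
  if (is.null(dmu_ntp)) dmu_ntp <- if (!is.null(p)) p$dmu_ntp else 20
  if (is.null(ss)) ss <- steady_state(net)
  jr <- ss$j_cycle[[chord_map[["JR"]]]]
  jw <- ss$j_cycle[[chord_map[["JW"]]]]
  rows <- lapply(net$edges$id, function(edge) {
    dj <- vapply(chord_map, function(ch) {
      barrier_response(net, ss, edge, paste0("cycleflux:", ch))
    }, numeric(1))
    dS <- dj[["JR"]] + dj[["JW"]]
    deps <- (dj[["JW"]] / jw - dj[["JR"]] / jr) / log(10)
    dC <- dS * dmu_p + (dj[["JRp"]] + dj[["JWp"]]) * dmu_ntp
    dirn <- if (dS == 0) 0 else sign(dS)
    cls <- if (dirn == 0) "neutral" else {
      de <- dirn * deps; dc <- dirn * dC
      if (de <= 0 && dc <= 0) "free_lunch"
      else if (de > 0 && dc > 0) "detrimental"
      else "trade_off"
    }
    data.frame(edge = edge, dS_dB = dS, deps_dB = deps, dC_dB = dC,
               speed_up_direction = dirn, class = cls,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Metric trajectories along a barrier scan
#'
#' Recomputes (S, eps, C) while shifting one edge's barrier over a grid, and
#' flags the plateau region where the marginal gain of pushing the barrier
#' further (the numerical slope of each metric) nearly vanishes.
#'
#' @inheritParams kp_metrics
#' @param edge edge id whose barrier is scanned.
#' @param dB_grid numeric grid of barrier shifts (kT), e.g. `seq(-2, 8, 0.5)`.
#' @param plateau_tol slope threshold relative to each metric's maximum
#'   absolute slope (default 0.01).
#' @return data frame `dB, S, eps, C, plateau_S, plateau_eps, plateau_C`.
#' @export
barrier_saturation_scan <- function(net, edge, dB_grid, dmu_p = NULL,
                                    dmu_ntp = NULL,
                                    chord_map = kp_chord_map(),
                                    plateau_tol = 0.01) {
  stopifnot(edge %in% net$edges$id, length(dB_grid) >= 3L)
  dB_grid <- sort(dB_grid)
  vals <- t(vapply(dB_grid, function(db) {
    net2 <- .apply_knob(net, paste0("barrier:", edge), db)
    m <- kp_metrics(net2, dmu_p = dmu_p, dmu_ntp = dmu_ntp,
                    chord_map = chord_map)
    c(S = m$S, eps = m$eps, C = m$C)
  }, numeric(3)))
  out <- data.frame(dB = dB_grid, vals)
  for (mcol in c("S", "eps", "C")) {
    slope <- c(NA, diff(out[[mcol]]) / diff(out$dB))
    ref <- max(abs(slope), na.rm = TRUE)
    out[[paste0("plateau_", mcol)]] <-
      if (ref == 0) TRUE else abs(slope) <= plateau_tol * ref
    out[[paste0("plateau_", mcol)]][1L] <- out[[paste0("plateau_", mcol)]][2L]
  }
  out
}
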