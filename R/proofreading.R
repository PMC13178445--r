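# Proofreading performance coordinates: speed, error, cost, discard ratio.
# The four fundamental cycle fluxes of a proofreading network are the correct
# and incorrect incorporations (JR, JW) and the corresponding discards
# (JR', JW'); performance metrics are algebraic combinations of these.

#' Proofreading metrics from cycle fluxes
#'
#' * speed `S = JR + JW` (1/time)
#' * error `eps = log10(JW / JR)` (dimensionless)
#' * cost `C = S * dmu_p + (JRp + JWp) * dmu_ntp` (kT/time), where `dmu_p` and
#'   `dmu_ntp` are the free energies of product-bond formation and NTP
#'   hydrolysis
#' * discard ratio `rp = JWp / JRp`
#'
#' A non-positive total discard flux `JRp + JWp <= 0` marks the
#' anti-proofreading regime (the machine net-synthesizes fuel).
#'
#' @param JR,JW correct/incorrect incorporation cycle fluxes (`JR > 0`).
#' @param JRp,JWp correct/incorrect discard cycle fluxes.
#' @param dmu_p,dmu_ntp free-energy constants (kT).
#' @return object of class `proofreading_metrics`.
#' @export
metrics_from_fluxes <- function(JR, JW, JRp, JWp, dmu_p, dmu_ntp) {
  if (JR <= 0) stop("JR must be positive for a finite error rate")
  S <- JR + JW
  eps <- log10(JW / JR)
  C <- S * dmu_p + (JRp + JWp) * dmu_ntp
  rp <- if (JRp == 0) NA_real_ else JWp / JRp
  structure(list(S = S, eps = eps, C = C, r_prime = rp,
                 fluxes = c(JR = JR, JW = JW, JRp = JRp, JWp = JWp),
                 dmu_p = dmu_p, dmu_ntp = dmu_ntp,
                 anti_proofreading = (JRp + JWp) <= 0,
                 r_prime_defined = JRp != 0),
            class = "proofreading_metrics")
}

#' @export
print.proofreading_metrics <- function(x, ...) {
  cat(sprintf("proofreading_metrics: S = %.6g, eps = %.4f, C = %.6g\n",
              x$S, x$eps, x$C))
  cat(sprintf("  discard ratio r' = %s; discard total JR'+JW' = %.6g%s\n",
              if (x$r_prime_defined) signif(x$r_prime, 6) else "undefined",
              x$fluxes[["JRp"]] + x$fluxes[["JWp"]],
              if (x$anti_proofreading) "  [anti-proofreading]" else ""))
  invisible(x)
}

#' Cycle fluxes from proofreading metrics
#'
#' Exact inverse of [metrics_from_fluxes()] given the constants and the
#' discard ratio:
#' `JR = S/(1 + 10^eps)`, `JW = S 10^eps/(1 + 10^eps)`,
#' `JRp = (C - S dmu_p) / (dmu_ntp (1 + rp))`, `JWp = rp JRp`.
#'
#' @param m a `proofreading_metrics`, or `NULL` if the scalar arguments are
#'   given.
#' @param S,eps,C,r_prime,dmu_p,dmu_ntp scalar metric values (used when `m` is
#'   `NULL`).
#' @return named numeric `c(JR, JW, JRp, JWp)`.
#' @export
fluxes_from_metrics <- function(m = NULL, S, eps, C, r_prime, dmu_p, dmu_ntp) {
  if (!is.null(m)) {
    stopifnot(inherits(m, "proofreading_metrics"))
    S <- m$S; eps <- m$eps; C <- m$C; r_prime <- m$r_prime
    dmu_p <- m$dmu_p; dmu_ntp <- m$dmu_ntp
  }
  if (!is.finite(eps)) stop("eps must be finite")
  if (S <= 0) stop("S must be positive")
  if (!is.finite(r_prime) || r_prime == -1) {
    stop("discard ratio r' must be finite and != -1")
  }
  JR <- S / (1 + 10^eps)
  JW <- S * 10^eps / (1 + 10^eps)
  JRp <- (C - S * dmu_p) / (dmu_ntp * (1 + r_prime))
  c(JR = JR, JW = JW, JRp = JRp, JWp = r_prime * JRp)
}

#' Traffic-jam bound on proofreading throughput
#'
#' Productive incorporation and futile proofreading of the cognate substrate
#' compete for the finite kinetic bandwidth of the initial binding edge:
#' `S/(1 + 10^eps) + (C - S dmu_p)/(dmu_ntp (1 + r')) <= tau_E,ER`, i.e.
#' `JR + JR' <= tau_E,ER`. The bound saturates exactly when the backward
#' one-way flux on that edge vanishes (`p_ER->E = 0`).
#'
#' @param m a `proofreading_metrics`.
#' @param tau_EER traffic on the cognate binding edge (1/time).
#' @param tol relative saturation tolerance: saturated when
#'   `p_ER->E < tol * tau_EER` with `p_ER->E = (tau_EER - lhs)/2`.
#' @return list with `lhs`, `bound`, `satisfied`, `saturated`, `p_back`.
#' @export
traffic_bound_check <- function(m, tau_EER, tol = 1e-9) {
  stopifnot(inherits(m, "proofreading_metrics"))
  fl <- fluxes_from_metrics(m)
  lhs <- fl[["JR"]] + fl[["JRp"]]
  p_back <- (tau_EER - lhs) / 2
  list(lhs = lhs, bound = tau_EER,
       satisfied = lhs <= tau_EER * (1 + tol),
       saturated = p_back < tol * tau_EER,
       p_back = p_back)
}

#' Inverse-design path through performance space
#'
#' Drives a proofreading network along a straight line in `(S, eps, C)` space
#' from its origin (wild-type) values, re-solving the transition rates at every
#' waypoint through the canonical-coordinate map. The origin's state
#' probabilities, non-chord traffics, discard ratio and cycle forces are held
#' fixed; only the four metric-carrying chord fluxes move.
#'
#' Whenever a waypoint is infeasible because a held tree-edge traffic limit is
#' hit (a one-way flux crossing zero), that specific traffic is relaxed by
#' `relax_factor` (default tenfold) and the waypoint retried; relaxations
#' persist along the path and are recorded. Waypoints where the total discard
#' flux `JR' + JW'` becomes non-positive are flagged as anti-proofreading, and
#' the emitted rate protocol records which reversed rates grew relative to the
#' origin.
#'
#' @param net origin network (e.g. [kp_fixture()]).
#' @param direction numeric `c(dS, deps, dC)` step in metric space per
#'   waypoint.
#' @param n_steps number of waypoints beyond the origin.
#' @param chord_map named character: which chord carries `JR`, `JW`, `JRp`,
#'   `JWp` (default [kp_chord_map()]).
#' @param dmu_p,dmu_ntp free-energy constants (kT); default from the network's
#'   `kp_params` attribute when present.
#' @param relax_factor traffic relaxation factor on infeasibility (default 10).
#' @param max_relax maximum relaxations per edge per waypoint (default 10).
#' @return object of class `design_path`: `waypoints` (metrics, regime flag),
#'   `rates` (one row per waypoint, one column per directed rate),
#'   `relaxations` (edge, waypoint, old/new traffic), `origin`.
#' @export
design_path <- function(net, direction, n_steps,
                        chord_map = kp_chord_map(),
                        dmu_p = NULL, dmu_ntp = NULL,
                        relax_factor = 10, max_relax = 10) {
  stopifnot(inherits(net, "machine_network"), length(direction) == 3L,
            n_steps >= 0)
  kpp <- attr(net, "kp_params")
  if (is.null(dmu_p)) dmu_p <- if (!is.null(kpp)) kpp$dmu_p else 2
  if (is.null(dmu_ntp)) dmu_ntp <- if (!is.null(kpp)) kpp$dmu_ntp else 20
  basis <- cycle_basis(net)
  stopifnot(all(c("JR", "JW", "JRp", "JWp") %in% names(chord_map)),
            all(chord_map %in% basis$chords))
  ss0 <- steady_state(net, basis)
  co0 <- to_canonical(net, ss0, basis)
  m0 <- metrics_from_fluxes(JR = ss0$j_cycle[[chord_map[["JR"]]]],
                            JW = ss0$j_cycle[[chord_map[["JW"]]]],
                            JRp = ss0$j_cycle[[chord_map[["JRp"]]]],
                            JWp = ss0$j_cycle[[chord_map[["JWp"]]]],
                            dmu_p = dmu_p, dmu_ntp = dmu_ntp)
  if (!m0$r_prime_defined) stop("origin discard ratio r' undefined (JR' = 0)")

  tau_tree <- co0$tau_tree
  dir_names <- c(paste0(net$edges$id, "+"), paste0(net$edges$id, "-"))
  rate_rows <- list()
  waypoints <- data.frame()
  relaxations <- data.frame()
  terminated <- FALSE
  termination_reason <- NULL
  for (t in 0:n_steps) {
    S <- m0$S + t * direction[1L]
    eps <- m0$eps + t * direction[2L]
    C <- m0$C + t * direction[3L]
    fl <- fluxes_from_metrics(S = S, eps = eps, C = C, r_prime = m0$r_prime,
                              dmu_p = dmu_p, dmu_ntp = dmu_ntp)
    anti <- (fl[["JRp"]] + fl[["JWp"]]) <= 0
    solved <- NULL
    relax_count <- integer(length(tau_tree))
    names(relax_count) <- names(tau_tree)
    pending <- data.frame()
    co <- co0
    co$j_cycle[chord_map] <- fl[names(chord_map)]
    repeat {
      co$tau_tree <- tau_tree
      solved <- tryCatch(rates_from_canonical(co, basis), error = identity)
      if (!inherits(solved, "error")) break
      msg <- conditionMessage(solved)
      hit <- regmatches(msg, regexpr("tree edge '[^']+'", msg))
      if (!length(hit)) {
        # a chord's one-way flux would cross zero (e.g. the discard cycles at
        # the anti-proofreading boundary under a fixed positive cycle force):
        # a hard boundary of the held-coordinate protocol, not a traffic limit
        terminated <- TRUE
        termination_reason <- paste0("waypoint ", t, ": ", msg)
        break
      }
      edge <- sub("tree edge '([^']+)'", "\\1", hit)
      if (relax_count[[edge]] >= max_relax) {
        terminated <- TRUE
        termination_reason <- paste0("waypoint ", t, ": traffic limit on '",
                                     edge, "' infeasible after ", max_relax,
                                     " relaxations")
        break
      }
      old <- tau_tree[[edge]]
      tau_tree[[edge]] <- old * relax_factor
      relax_count[[edge]] <- relax_count[[edge]] + 1L
      pending <- rbind(pending,
                       data.frame(waypoint = t, edge = edge, tau_old = old,
                                  tau_new = tau_tree[[edge]]))
    }
    waypoints <- rbind(waypoints,
                       data.frame(step = t, S = S, eps = eps, C = C,
                                  JRp_plus_JWp = fl[["JRp"]] + fl[["JWp"]],
                                  anti_proofreading = anti,
                                  solved = !terminated))
    if (terminated) break
    relaxations <- rbind(relaxations, pending)
    rates <- c(stats::setNames(solved$edges$k_fwd,
                               paste0(solved$edges$id, "+")),
               stats::setNames(solved$edges$k_bwd,
                               paste0(solved$edges$id, "-")))
    rate_rows[[length(rate_rows) + 1L]] <- rates[dir_names]
  }
  rates <- do.call(rbind, rate_rows)
  colnames(rates) <- dir_names
  origin_rates <- rates[1L, ]
  grew_reversed <- colnames(rates)[grepl("-$", colnames(rates)) &
                                     rates[nrow(rates), ] > origin_rates]
  structure(list(waypoints = waypoints, rates = rates,
                 relaxations = relaxations,
                 origin = m0, chord_map = chord_map,
                 reversed_rates_grown = grew_reversed,
                 terminated = terminated,
                 termination_reason = termination_reason,
                 basis = basis),
            class = "design_path")
}

#' @export
print.design_path <- function(x, ...) {
  n <- nrow(x$waypoints)
  cat(sprintf("design_path: %d waypoints from origin (S=%.4g, eps=%.3f, C=%.4g)\n",
              n, x$origin$S, x$origin$eps, x$origin$C))
  last <- x$waypoints[n, ]
  cat(sprintf("  endpoint: S=%.4g, eps=%.3f, C=%.4g%s\n", last$S, last$eps,
              last$C,
              if (last$anti_proofreading) "  [anti-proofreading]" else ""))
  if (nrow(x$relaxations)) {
    cat(sprintf("  %d traffic relaxation(s) on: %s\n", nrow(x$relaxations),
                paste(unique(x$relaxations$edge), collapse = ", ")))
  }
  if (any(x$waypoints$anti_proofreading)) {
    cat(sprintf("  anti-proofreading from waypoint %d\n",
                min(x$waypoints$step[x$waypoints$anti_proofreading])))
  }
  if (length(x$reversed_rates_grown)) {
    cat("  reversed rates grown:",
        paste(x$reversed_rates_grown, collapse = ", "), "\n")
  }
  if (x$terminated) {
    cat("  terminated:", x$termination_reason, "\n")
  }
  invisible(x)
}

#' @export
plot.design_path <- function(x, ...) {
  wp <- x$waypoints
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::matplot(wp$step, scale(wp[c("S", "eps", "C")], center = FALSE),
                    type = "l", lty = 1, xlab = "waypoint",
                    ylab = "metric (scaled)", ...)
  graphics::legend("topleft", legend = c("S", "eps", "C"), col = 1:3, lty = 1,
                   bty = "n")
  graphics::matplot(wp$step, log10(x$rates), type = "l", lty = 1,
                    xlab = "waypoint", ylab = "log10 rate")
  invisible(x)
}
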