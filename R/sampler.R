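# Seeded random-network ensembles for validating the operational bounds.

#' Sampler configuration
#'
#' @param topology fixture name (see [load_fixture()]) or a `machine_network`
#'   template whose rates are redrawn.
#' @param n_samples number of networks to draw.
#' @param rate_range log-uniform support for every positive directed rate;
#'   default six orders of magnitude centred at one, `c(1e-3, 1e3)`.
#' @param constraints list of equality constraints applied after the raw draw
#'   by rescaling a designated adjustment rate; currently cycle-force targets:
#'   `list(f_cycle = c(CHORD = value))`. The futile-loop constraint of the
#'   noncompetitive ensemble is `list(f_cycle = c(i2 = 0))`.
#' @param seed integer seed; the stream is reproducible across platforms
#'   (Mersenne-Twister with fixed init).
#' @return object of class `sampler_config`.
#' @export
sampler_config <- function(topology, n_samples, rate_range = c(1e-3, 1e3),
                           constraints = list(), seed) {
  stopifnot(n_samples >= 0, length(rate_range) == 2L,
            all(rate_range > 0), rate_range[1L] < rate_range[2L])
  if (is.character(topology)) topology <- load_fixture(topology)
  stopifnot(inherits(topology, "machine_network"))
  if (!is.null(constraints$f_cycle)) {
    basis <- cycle_basis(topology)
    bad <- setdiff(names(constraints$f_cycle), basis$chords)
    if (length(bad)) stop("f_cycle constraint on non-chord edge(s): ",
                          paste(bad, collapse = ", "))
  }
  structure(list(topology = topology, n_samples = as.integer(n_samples),
                 rate_range = rate_range, constraints = constraints,
                 seed = as.integer(seed)),
            class = "sampler_config")
}

# draw the rate matrix: one row per sample, columns are the template's
# directed positive rates in edge order (k_fwd first, then reversible k_bwd)
.sample_rates <- function(cfg) {
  edges <- cfg$topology$edges
  nf <- nrow(edges); nb <- sum(edges$reversible)
  lo <- log(cfg$rate_range[1L]); hi <- log(cfg$rate_range[2L])
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  m <- matrix(exp(stats::runif(cfg$n_samples * (nf + nb), lo, hi)),
              nrow = cfg$n_samples)
  colnames(m) <- c(paste0(edges$id, "+"), paste0(edges$id[edges$reversible], "-"))
  m
}

# apply cycle-force equality constraints to one rate vector by rescaling the
# chord's forward rate (a single loop rate)
.project_constraints <- function(cfg, kf, kb, basis) {
  fc_target <- cfg$constraints$f_cycle
  if (is.null(fc_target)) return(list(kf = kf, kb = kb))
  edges <- cfg$topology$edges
  half_lr <- ifelse(edges$reversible, 0.5 * log(kf / kb), log(kf))
  for (ch in names(fc_target)) {
    cur <- sum(basis$incidence[ch, ] * half_lr)
    e <- match(ch, edges$id)
    fac <- if (edges$reversible[e]) exp(2 * (fc_target[[ch]] - cur))
           else exp(fc_target[[ch]] - cur)
    kf[e] <- kf[e] * fac
    half_lr[e] <- half_lr[e] + (fc_target[[ch]] - cur)
  }
  list(kf = kf, kb = kb)
}

#' Draw a reproducible ensemble of networks
#'
#' Each sample keeps the template topology, redraws every positive directed
#' rate log-uniformly over `rate_range`, then projects onto the equality
#' constraints (preserving the log-uniform marginals of the free rates).
#' Identical configuration and seed give a bit-identical stream.
#'
#' @param cfg a `sampler_config`.
#' @return list of `machine_network`s.
#' @export
sample_networks <- function(cfg) {
  stopifnot(inherits(cfg, "sampler_config"))
  if (cfg$n_samples == 0L) return(list())
  m <- .sample_rates(cfg)
  edges <- cfg$topology$edges
  basis <- cycle_basis(cfg$topology)
  rev <- edges$reversible
  lapply(seq_len(cfg$n_samples), function(s) {
    kf <- m[s, seq_len(nrow(edges))]
    kb <- numeric(nrow(edges)); kb[rev] <- m[s, -seq_len(nrow(edges))]
    pr <- .project_constraints(cfg, kf, kb, basis)
    net <- .with_rates(cfg$topology, unname(pr$kf), unname(pr$kb))
    net$name <- paste0(cfg$topology$name, "#", s)
    net
  })
}

# Markov-chain-tree evaluation of the noncompetitive topology: the stationary
# distribution is a ratio of sums of positive directed-spanning-tree products,
# and the leak flux reduces to the surviving cycle terms after the exact
# symbolic cancellation of the tree quadruples, so no catastrophic
# cancellation occurs even for rates spanning many decades (the strict
# positivity of the leak flux on a futile loop is then numerically exact).
# The structure below is computed once per ensemble.
.noncomp_struct <- function(net) {
  edges <- net$edges  # bind, cat, i1, i2, i3 in id order
  stopifnot(identical(edges$id, c("bind", "cat", "i1", "i2", "i3")))
  states <- c("E", "ES", "EI", "EIS")
  ne <- nrow(edges)
  # directed-rate index: e -> kf, ne + e -> kb (kb of "cat" is zero)
  tails <- match(edges$tail, states); heads <- match(edges$head, states)
  spans <- function(sub) {
    comp <- seq_along(states)
    for (e in sub) {
      a <- comp[tails[e]]; b <- comp[heads[e]]
      comp[comp == b] <- a
    }
    length(unique(comp)) == 1L
  }
  trees <- Filter(spans, utils::combn(ne, 3L, simplify = FALSE))
  # orient one tree toward one root: directed-rate indices, child -> parent
  orient <- function(sub, root) {
    parent <- rep(NA_integer_, length(states)); parent[root] <- 0L
    queue <- root; used <- integer(0)
    adj <- lapply(seq_along(states), function(v) {
      sub[tails[sub] == v | heads[sub] == v]
    })
    pedge <- rep(NA_integer_, length(states))
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (e in adj[[v]]) {
        w <- if (tails[e] == v) heads[e] else tails[e]
        if (is.na(parent[w])) {
          parent[w] <- v; pedge[w] <- e; queue <- c(queue, w)
        }
      }
    }
    vapply(setdiff(seq_along(states), root), function(w) {
      e <- pedge[w]
      if (tails[e] == w) e else ne + e  # child->parent uses kf or kb
    }, integer(1))
  }
  rooted <- lapply(seq_along(states), function(r) {
    do.call(rbind, lapply(trees, orient, root = r))
  })
  # leak-flux decomposition on edge i2 (EI -> EIS positive):
  # J = (pi_EI d1 - pi_EIS d2) = (sum_EI-trees * d1 - sum_EIS-trees * d2)/Sigma;
  # identical rate multisets cancel exactly, leaving the cycle terms
  e_i2 <- match("i2", edges$id)
  quad <- function(m, extra) {
    lapply(seq_len(nrow(m)), function(r) sort(c(m[r, ], extra)))
  }
  pos <- quad(rooted[[3L]], e_i2)        # EI-rooted trees times d1
  neg <- quad(rooted[[4L]], ne + e_i2)   # EIS-rooted trees times d2
  keep_p <- rep(TRUE, length(pos)); keep_n <- rep(TRUE, length(neg))
  for (i in seq_along(pos)) {
    for (j in which(keep_n)) {
      if (identical(pos[[i]], neg[[j]])) {
        keep_p[i] <- FALSE; keep_n[j] <- FALSE; break
      }
    }
  }
  list(rooted = rooted, ne = ne,
       leak_pos = do.call(rbind, pos[keep_p]),
       leak_neg = do.call(rbind, neg[keep_n]))
}

.noncomp_observables <- function(kf, kb, struct = NULL) {
  if (is.null(struct)) {
    struct <- .noncomp_struct(mm_inhibition_network("noncompetitive"))
  }
  v <- c(unname(kf), unname(kb))
  tsum <- vapply(struct$rooted, function(m) {
    sum(v[m[, 1L]] * v[m[, 2L]] * v[m[, 3L]])
  }, numeric(1))
  sig <- sum(tsum)
  pi <- c(E = tsum[1L], ES = tsum[2L], EI = tsum[3L], EIS = tsum[4L]) / sig
  prodsum <- function(m) {
    if (is.null(m) || nrow(m) == 0L) return(0)
    sum(v[m[, 1L]] * v[m[, 2L]] * v[m[, 3L]] * v[m[, 4L]])
  }
  j_leak <- (prodsum(struct$leak_pos) - prodsum(struct$leak_neg)) / sig
  j_cat <- pi[["ES"]] * kf[2L]  # non-invertible: flux = forward one-way flux
  list(pi = pi,
       j_cat = unname(j_cat), j_leak = j_leak,
       tau_bind = pi[["E"]] * kf[1L] + pi[["ES"]] * kb[1L],
       tau_side = c(i1 = pi[["E"]] * kf[3L] + pi[["EI"]] * kb[3L],
                    i2 = pi[["EI"]] * kf[4L] + pi[["EIS"]] * kb[4L],
                    i3 = pi[["EIS"]] * kf[5L] + pi[["ES"]] * kb[5L]))
}

#' Ensemble validation of the operational bounds
#'
#' Runs one of the scatter validations over a random ensemble:
#'
#' * `"ietp"` — noncompetitive inhibition networks with the futile-loop
#'   constraint: per sample, the catalytic flux, the leak flux, the exact
#'   decomposition `Jleak + tau_E,ES tanh(A_side)`, and the equal-traffic
#'   lower / kinetic upper bounds; violations are counted at relative
#'   tolerance `tol`.
#' * `"kp-bound"` — proofreading coordinate draws on the [kp_fixture()]
#'   topology: per sample, all edge traffics are drawn log-uniformly over
#'   `rate_range`, chord fluxes are placed inside their one-way-flux feasible
#'   intervals, tree fluxes follow from Kirchhoff (draws whose tree edges
#'   would be infeasible are rejected and redrawn), and the traffic-jam bound
#'   `JR + JR' <= tau_E,ER` is evaluated through the metric expressions.
#'
#' @param cfg a `sampler_config`. For `"ietp"` the topology must be the
#'   noncompetitive network; for `"kp-bound"` the [kp_fixture()] topology is
#'   used and `rate_range` is interpreted as the traffic range.
#' @param experiment `"ietp"` or `"kp-bound"`.
#' @param tol violation tolerance separating float noise from genuine
#'   violations (default 1e-9 relative).
#' @return object of class `scatter_experiment`: `table` (per-sample results),
#'   `n_violations`, `n_saturated`, `max_violation`.
#' @export
scatter_experiment <- function(cfg, experiment = c("ietp", "kp-bound"),
                               tol = 1e-9) {
  stopifnot(inherits(cfg, "sampler_config"))
  experiment <- match.arg(experiment)
  out <- switch(experiment,
                "ietp" = .scatter_ietp(cfg, tol),
                "kp-bound" = .scatter_kp(cfg, tol))
  structure(c(out, list(experiment = experiment, seed = cfg$seed)),
            class = "scatter_experiment")
}

#' @export
print.scatter_experiment <- function(x, ...) {
  cat(sprintf("scatter_experiment '%s': %d samples (seed %d)\n",
              x$experiment, nrow(x$table), x$seed))
  cat(sprintf("  violations: %d, max signed violation: %.3g\n",
              x$n_violations, x$max_violation))
  cat(sprintf("  saturated (within 1e-6 of bound): %d\n", x$n_saturated))
  invisible(x)
}

.scatter_ietp <- function(cfg, tol) {
  net <- cfg$topology
  if (!identical(attr(net, "inhibition_kind"), "noncompetitive")) {
    stop("the ietp experiment needs the noncompetitive topology")
  }
  fc <- cfg$constraints$f_cycle
  if (is.null(fc) || !"i2" %in% names(fc) || abs(fc[["i2"]]) > 0) {
    stop("the ietp experiment requires the futile-loop constraint ",
         "constraints = list(f_cycle = c(i2 = 0))")
  }
  edges <- net$edges
  basis <- cycle_basis(net)
  rev <- edges$reversible
  m <- .sample_rates(cfg)
  struct <- .noncomp_struct(net)
  res <- matrix(NA_real_, cfg$n_samples, 6,
                dimnames = list(NULL, c("j_cat", "j_leak", "identity",
                                        "lower", "upper", "a_side")))
  for (s in seq_len(cfg$n_samples)) {
    kf <- m[s, seq_len(nrow(edges))]
    kb <- numeric(nrow(edges)); kb[rev] <- m[s, -seq_len(nrow(edges))]
    pr <- .project_constraints(cfg, kf, kb, basis)
    ob <- .noncomp_observables(pr$kf, pr$kb, struct)
    a_side <- sum(atanh(ob$j_leak / ob$tau_side))
    a_min <- 3 * atanh(3 * ob$j_leak / sum(ob$tau_side))
    res[s, ] <- c(ob$j_cat, ob$j_leak,
                  ob$j_leak + ob$tau_bind * tanh(a_side),
                  ob$j_leak + ob$tau_bind * tanh(a_min),
                  ob$j_leak + ob$tau_bind,
                  a_side)
  }
  tab <- as.data.frame(res)
  viol_low <- (tab$lower - tab$j_cat) / pmax(abs(tab$j_cat), 1e-300)
  viol_up <- (tab$j_cat - tab$upper) / pmax(abs(tab$j_cat), 1e-300)
  tab$violation <- pmax(viol_low, viol_up)
  list(table = tab,
       n_violations = sum(tab$violation > tol),
       n_saturated = sum(pmin(abs(tab$j_cat - tab$lower),
                              abs(tab$upper - tab$j_cat)) <
                           1e-6 * abs(tab$j_cat)),
       max_violation = max(tab$violation))
}

.scatter_kp <- function(cfg, tol) {
  net <- if (identical(cfg$topology$name, "kp-4cycle")) cfg$topology
         else kp_fixture()
  p <- attr(net, "kp_params")
  basis <- cycle_basis(net)
  cm <- kp_chord_map()
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  lo <- log(cfg$rate_range[1L]); hi <- log(cfg$rate_range[2L])
  n_tree <- length(basis$tree_edges)
  rows <- vector("list", cfg$n_samples)
  s <- 0L; tries <- 0L
  while (s < cfg$n_samples) {
    tries <- tries + 1L
    if (tries > 100L * cfg$n_samples) stop("kp-bound rejection rate too high")
    tau_ch <- exp(stats::runif(4, lo, hi)); names(tau_ch) <- cm
    # incorporation fluxes forward, discard fluxes either sign
    u <- c(stats::runif(2, 0, 1), stats::runif(2, -1, 1))
    j_ch <- tau_ch * u * 0.999999; names(j_ch) <- names(cm)
    j_edge <- reconstruct_edge_fluxes(basis, stats::setNames(j_ch, unname(cm)))
    tau_tree <- exp(stats::runif(n_tree, lo, hi))
    names(tau_tree) <- basis$tree_edges
    if (any(tau_tree <= abs(j_edge[basis$tree_edges]))) next  # reject
    s <- s + 1L
    JR <- j_ch[["JR"]]; JW <- j_ch[["JW"]]
    JRp <- j_ch[["JRp"]]; JWp <- j_ch[["JWp"]]
    m <- metrics_from_fluxes(JR, JW, JRp, JWp, p$dmu_p, p$dmu_ntp)
    lhs <- m$S / (1 + 10^m$eps) +
      (m$C - m$S * p$dmu_p) / (p$dmu_ntp * (1 + m$r_prime))
    tau_EER <- tau_tree[["bindR"]]
    rows[[s]] <- c(S = m$S, eps = m$eps, C = m$C, r_prime = m$r_prime,
                   lhs = lhs, tau_EER = tau_EER,
                   p_back = (tau_EER - lhs) / 2)
  }
  tab <- as.data.frame(do.call(rbind, rows))
  tab$violation <- (tab$lhs - tab$tau_EER) / tab$tau_EER
  list(table = tab,
       n_violations = sum(tab$violation > tol),
       n_saturated = sum(tab$p_back < 1e-9 * tab$tau_EER),
       max_violation = max(tab$violation))
}
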