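# Shared test helpers: random network generation and independent oracles.
# Oracles here deliberately avoid the package's own computational paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

# random connected reversible network: ring backbone plus random extra edges,
# log-uniform rates; deterministic under the caller's RNG state
rand_net <- function(n_states, rate_range = c(0.1, 10), p_extra = 0.5) {
  states <- sprintf("s%02d", seq_len(n_states))
  pairs <- cbind(seq_len(n_states), c(seq_len(n_states)[-1L], 1L))
  if (n_states > 3L) {
    extra <- t(utils::combn(n_states, 2L))
    adj <- abs(extra[, 1L] - extra[, 2L])
    extra <- extra[adj != 1L & adj != n_states - 1L, , drop = FALSE]
    keep <- stats::runif(nrow(extra)) < p_extra
    pairs <- rbind(pairs, extra[keep, , drop = FALSE])
  }
  ne <- nrow(pairs)
  lo <- log(rate_range[1L]); hi <- log(rate_range[2L])
  build_network(
    states = states,
    edges = data.frame(id = sprintf("e%02d", seq_len(ne)),
                       tail = states[pairs[, 1L]], head = states[pairs[, 2L]],
                       k_fwd = exp(stats::runif(ne, lo, hi)),
                       k_bwd = exp(stats::runif(ne, lo, hi)),
                       stringsAsFactors = FALSE),
    name = "random")
}

# independent stationary-distribution oracle: eigen decomposition of the
# transition-rate matrix built directly from the edge table
oracle_pi <- function(net) {
  n <- length(net$states)
  W <- matrix(0, n, n, dimnames = list(net$states, net$states))
  for (e in seq_len(nrow(net$edges))) {
    i <- net$edges$tail[e]; j <- net$edges$head[e]
    W[j, i] <- W[j, i] + net$edges$k_fwd[e]   # column-stochastic convention
    W[i, j] <- W[i, j] + net$edges$k_bwd[e]
  }
  diag(W) <- diag(W) - colSums(W)
  ev <- eigen(W)
  k <- which.min(abs(ev$values))
  v <- Re(ev$vectors[, k])
  v / sum(v)
}

# brute-force maximizer of processive efficiency J/tau_tot for the 2-edge
# unicycle at fixed cycle force; independent of the package's coordinate maps
oracle_max_efficiency <- function(f_cycle, n_starts = 40) {
  eff <- function(x) {
    k1f <- exp(x[1L]); k1b <- exp(x[2L]); k2f <- exp(x[3L])
    k2b <- k1f * k2f / (k1b * exp(2 * f_cycle))
    S <- k1f + k1b + k2f + k2b
    pa <- (k1b + k2f) / S; pb <- (k1f + k2b) / S
    J <- pa * k1f - pb * k1b
    tau <- pa * k1f + pb * k1b + pb * k2f + pa * k2b
    J / tau
  }
  best <- -Inf; best_x <- NULL
  for (s in seq_len(n_starts)) {
    x0 <- stats::runif(3, -2, 2)
    o <- stats::optim(x0, function(x) -eff(x), method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    if (-o$value > best) { best <- -o$value; best_x <- o$par }
  }
  k1f <- exp(best_x[1L]); k1b <- exp(best_x[2L]); k2f <- exp(best_x[3L])
  k2b <- k1f * k2f / (k1b * exp(2 * f_cycle))
  S <- k1f + k1b + k2f + k2b
  pa <- (k1b + k2f) / S; pb <- (k1f + k2b) / S
  list(efficiency = best,
       tau1 = pa * k1f + pb * k1b,
       tau2 = pb * k2f + pa * k2b)
}

# noncompetitive network whose three sideway edges carry equal steady-state
# traffic, built by root-finding on the canonical coordinates
equal_sideway_network <- function(pi = c(E = 0.4, ES = 0.3, EI = 0.2,
                                         EIS = 0.1),
                                  j_cat = 0.05, j_leak = 0.02) {
  template <- mm_inhibition_network("noncompetitive")
  basis <- cycle_basis(template)
  solve_net <- function(t) {
    co <- structure(list(
      pi = pi,
      tau_tree = c(bind = 1, i1 = t, i3 = t),
      tau_chord = c(cat = NA, i2 = NA),
      j_cycle = c(cat = j_cat, i2 = j_leak),
      f_cycle = c(cat = NA, i2 = 0),   # futile loop; cat force implied
      basis = basis, name = "equal-sideway"), class = "canonical_coords")
    rates_from_canonical(co, basis)
  }
  mismatch <- function(t) {
    # infeasible (loop too saturated to close the futile cycle) counts as a
    # large positive mismatch: the solved chord traffic diverges there
    tryCatch({
      net <- solve_net(t)
      ss <- steady_state(net)
      ss$tau[["i2"]] - t
    }, error = function(e) 1e6)
  }
  t_star <- stats::uniroot(mismatch, c(j_leak * 1.001, 20), tol = 1e-14)$root
  solve_net(t_star)
}
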