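#' Build a machine network
#'
#' Constructs and validates a `machine_network`: an ergodic Markov jump process
#' on a multigraph of machine states. Edges are directed transition pairs with a
#' forward rate `k_fwd > 0` and a backward rate `k_bwd >= 0`; `k_bwd = 0` encodes
#' a non-invertible transition (e.g. the catalytic step ES -> E + P). Parallel
#' edges between the same state pair are allowed and are distinguished by edge
#' id; every per-edge quantity in this package is keyed by edge id, never by
#' state pair.
#'
#' Rates are in units of the inverse time set by their common prefactor, and all
#' energies elsewhere in the package are in units of kT (kT = 1 internally).
#'
#' @param states character vector of state labels (>= 2, unique). The first
#'   state is the deterministic root for spanning trees and the default
#'   reference node for caliber forces.
#' @param edges data frame with columns `id`, `tail`, `head`, `k_fwd`, `k_bwd`.
#' @param name optional network name.
#' @return an object of class `machine_network`.
#' @examples
#' net <- build_network(
#'   states = c("0", "1"),
#'   edges = data.frame(id = "e", tail = "0", head = "1", k_fwd = 1, k_bwd = 1))
#' @export
build_network <- function(states, edges, name = "network") {
  stopifnot(is.character(states) || is.factor(states))
  states <- as.character(states)
  if (length(states) < 2L) stop("a machine network needs at least 2 states")
  if (anyDuplicated(states)) {
    stop("duplicate state labels: ",
         paste(unique(states[duplicated(states)]), collapse = ", "))
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  req <- c("id", "tail", "head", "k_fwd", "k_bwd")
  if (!all(req %in% names(edges))) {
    stop("edges must have columns: ", paste(req, collapse = ", "))
  }
  edges <- edges[req]
  edges$id <- as.character(edges$id)
  edges$tail <- as.character(edges$tail)
  edges$head <- as.character(edges$head)
  if (nrow(edges) < 1L) stop("a machine network needs at least 1 edge")
  if (anyDuplicated(edges$id)) {
    stop("duplicate edge ids: ",
         paste(unique(edges$id[duplicated(edges$id)]), collapse = ", "))
  }
  unknown <- setdiff(c(edges$tail, edges$head), states)
  if (length(unknown)) {
    stop("edge references unknown state(s): ", paste(unknown, collapse = ", "))
  }
  if (any(edges$tail == edges$head)) {
    stop("self-loops are not allowed (edge ",
         edges$id[edges$tail == edges$head][1L], ")")
  }
  if (any(!is.finite(edges$k_fwd)) || any(edges$k_fwd <= 0)) {
    stop("k_fwd must be strictly positive and finite for every edge")
  }
  if (any(!is.finite(edges$k_bwd)) || any(edges$k_bwd < 0)) {
    stop("k_bwd must be non-negative and finite for every edge")
  }
  edges$reversible <- edges$k_bwd > 0
  # deterministic edge order: by id, platform-independent
  edges <- edges[order(edges$id, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL

  net <- structure(
    list(name = as.character(name), states = states, edges = edges),
    class = "machine_network")

  if (!.is_connected(net)) stop("network is disconnected")
  if (!.is_ergodic(net)) {
    stop("network is not ergodic: some state is not reachable from every ",
         "other via positive-rate transitions")
  }
  net
}

#' @export
print.machine_network <- function(x, ...) {
  n_irr <- sum(!x$edges$reversible)
  cat(sprintf("machine_network '%s': %d states, %d edges (%d non-invertible)\n",
              x$name, length(x$states), nrow(x$edges), n_irr))
  cat("states:", paste(x$states, collapse = ", "), "\n")
  print(x$edges[c("id", "tail", "head", "k_fwd", "k_bwd")], row.names = FALSE)
  invisible(x)
}

# state index lookup for a network
.state_index <- function(net) {
  idx <- seq_along(net$states)
  names(idx) <- net$states
  idx
}

# dense generator matrix Q (rows = from-state), summing parallel edges
.generator <- function(net) {
  n <- length(net$states)
  idx <- .state_index(net)
  Q <- matrix(0, n, n, dimnames = list(net$states, net$states))
  ti <- idx[net$edges$tail]; hi <- idx[net$edges$head]
  for (e in seq_len(nrow(net$edges))) {
    Q[ti[e], hi[e]] <- Q[ti[e], hi[e]] + net$edges$k_fwd[e]
    Q[hi[e], ti[e]] <- Q[hi[e], ti[e]] + net$edges$k_bwd[e]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# undirected connectivity by BFS over edges (any rate)
.is_connected <- function(net) {
  n <- length(net$states)
  idx <- .state_index(net)
  adj <- vector("list", n)
  for (e in seq_len(nrow(net$edges))) {
    i <- idx[[net$edges$tail[e]]]; j <- idx[[net$edges$head[e]]]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n); seen[1L] <- TRUE; queue <- 1L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

# ergodicity = strong connectivity of the directed positive-rate graph
.is_ergodic <- function(net) {
  n <- length(net$states)
  idx <- .state_index(net)
  fwd <- vector("list", n); bwd <- vector("list", n)
  for (e in seq_len(nrow(net$edges))) {
    i <- idx[[net$edges$tail[e]]]; j <- idx[[net$edges$head[e]]]
    fwd[[i]] <- c(fwd[[i]], j); bwd[[j]] <- c(bwd[[j]], i)
    if (net$edges$k_bwd[e] > 0) {
      fwd[[j]] <- c(fwd[[j]], i); bwd[[i]] <- c(bwd[[i]], j)
    }
  }
  reach <- function(adj) {
    seen <- logical(n); seen[1L] <- TRUE; queue <- 1L
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    seen
  }
  all(reach(fwd)) && all(reach(bwd))
}

# replace the rates of a network, keeping topology; k is a data.frame or list
# with columns/elements id, k_fwd, k_bwd (ids must match)
.with_rates <- function(net, k_fwd, k_bwd) {
  net$edges$k_fwd <- k_fwd
  net$edges$k_bwd <- k_bwd
  net$edges$reversible <- k_bwd > 0
  net
}
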