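#' Spanning-tree cycle basis
#'
#' Partitions the edges of a network into a deterministic spanning tree and its
#' chords, and builds the signed cycle-edge incidence implementing Kirchhoff's
#' current law. The tree is grown by breadth-first search from the first-listed
#' state, trying edges in id order, so the basis is reproducible across runs and
#' platforms. Only reversible edges are eligible for the tree, which guarantees
#' that every non-invertible edge becomes a chord (its fundamental cycle is the
#' catalytic cycle of the Michaelis-Menten extension).
#'
#' Each chord's fundamental cycle is the chord plus the unique tree path closing
#' it; the chord's tail-to-head direction defines the positive cycle direction,
#' and the incidence row of a chord has +1 on the chord itself.
#'
#' @param net a `machine_network`.
#' @return an object of class `spanning_tree_basis` with elements `tree_edges`,
#'   `chords`, `incidence` (chords x edges signed matrix in \{-1, 0, +1\}) and
#'   `edges` (the network's edge table, for self-contained reconstruction).
#' @export
cycle_basis <- function(net) {
  stopifnot(inherits(net, "machine_network"))
  edges <- net$edges
  n <- length(net$states)
  idx <- .state_index(net)

  # adjacency over reversible edges only, neighbors in edge-id order
  inc <- vector("list", n)  # list of (edge row, other-state index, is_tail)
  for (e in seq_len(nrow(edges))) {
    if (!edges$reversible[e]) next
    i <- idx[[edges$tail[e]]]; j <- idx[[edges$head[e]]]
    inc[[i]] <- rbind(inc[[i]], c(e, j))
    inc[[j]] <- rbind(inc[[j]], c(e, i))
  }
  # edges are already sorted by id, so row order within inc[[v]] is id order
  seen <- logical(n); seen[1L] <- TRUE
  parent_edge <- integer(n)   # edge row used to reach each state
  parent_dir <- integer(n)    # +1 if reached tail->head, -1 if head->tail
  parent <- integer(n)
  queue <- 1L
  tree_rows <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    m <- inc[[v]]
    if (is.null(m)) next
    for (r in seq_len(nrow(m))) {
      e <- m[r, 1L]; w <- m[r, 2L]
      if (!seen[w]) {
        seen[w] <- TRUE
        parent[w] <- v
        parent_edge[w] <- e
        parent_dir[w] <- if (idx[[edges$tail[e]]] == v) +1L else -1L
        tree_rows <- c(tree_rows, e)
        queue <- c(queue, w)
      }
    }
  }
  if (!all(seen)) {
    stop("removing all non-invertible edges disconnects the network; ",
         "a non-invertible edge cannot be made a chord (model unsupported)")
  }
  chord_rows <- setdiff(seq_len(nrow(edges)), tree_rows)
  tree_ids <- edges$id[sort(tree_rows)]
  chord_ids <- edges$id[chord_rows]  # edge table is id-ordered already

  # path from a state up to the root as signed tree-edge steps
  path_to_root <- function(v) {
    steps <- NULL
    while (v != 1L) {
      steps <- rbind(steps, c(parent_edge[v], -parent_dir[v]))  # v -> parent
      v <- parent[v]
    }
    steps
  }
  incidence <- matrix(0L, nrow = length(chord_ids), ncol = nrow(edges),
                      dimnames = list(chord_ids, edges$id))
  for (c_id in chord_ids) {
    e <- match(c_id, edges$id)
    u <- idx[[edges$tail[e]]]; v <- idx[[edges$head[e]]]
    incidence[c_id, e] <- 1L
    # tree path head -> tail = (head -> root) minus shared part (root -> tail);
    # compose head->root then reversed tail->root
    up_v <- path_to_root(v); up_u <- path_to_root(u)
    coef <- numeric(nrow(edges))
    if (!is.null(up_v)) for (r in seq_len(nrow(up_v)))
      coef[up_v[r, 1L]] <- coef[up_v[r, 1L]] + up_v[r, 2L]
    if (!is.null(up_u)) for (r in seq_len(nrow(up_u)))
      coef[up_u[r, 1L]] <- coef[up_u[r, 1L]] - up_u[r, 2L]
    incidence[c_id, ] <- incidence[c_id, ] + as.integer(coef)
  }
  structure(list(tree_edges = tree_ids, chords = chord_ids,
                 incidence = incidence,
                 edges = edges[c("id", "tail", "head", "reversible")],
                 states = net$states),
            class = "spanning_tree_basis")
}

#' @export
print.spanning_tree_basis <- function(x, ...) {
  cat(sprintf("spanning_tree_basis: %d tree edges, %d chords\n",
              length(x$tree_edges), length(x$chords)))
  cat("tree:  ", paste(x$tree_edges, collapse = ", "), "\n")
  cat("chords:", if (length(x$chords)) paste(x$chords, collapse = ", ")
                 else "(none)", "\n")
  invisible(x)
}

#' Reconstruct edge net fluxes from chord fluxes
#'
#' Every edge net-flux vector satisfying node current conservation is the
#' incidence-transpose combination of its chord (fundamental cycle) fluxes.
#'
#' @param basis a `spanning_tree_basis`.
#' @param j_cycle numeric vector of chord fluxes, named by chord id or in chord
#'   order.
#' @return named numeric vector of net fluxes, one per edge.
#' @export
reconstruct_edge_fluxes <- function(basis, j_cycle) {
  stopifnot(inherits(basis, "spanning_tree_basis"))
  nc <- length(basis$chords)
  if (nc == 0L) {
    out <- numeric(nrow(basis$edges))
    names(out) <- basis$edges$id
    return(out)
  }
  if (!is.null(names(j_cycle))) j_cycle <- j_cycle[basis$chords]
  stopifnot(length(j_cycle) == nc, all(is.finite(j_cycle)))
  out <- drop(crossprod(basis$incidence, j_cycle))
  names(out) <- colnames(basis$incidence)
  out
}

# signed edge ids of the fundamental cycle of a chord, as a data.frame
# (edge row index in basis$edges, sign)
.cycle_members <- function(basis, chord) {
  z <- basis$incidence[chord, ]
  rows <- which(z != 0L)
  data.frame(id = names(z)[rows], sign = as.numeric(z[rows]),
             stringsAsFactors = FALSE)
}
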