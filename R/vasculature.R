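#' Initialize vascular branch weights
#'
#' Draws a positive random weight for every branch (edge from a node's parent
#' to the node) and normalizes each sibling group so the absolute weights sum
#' to one. The weight of a branch is the fraction of the parent node's energy
#' sent down that branch.
#'
#' @param topology An `anvn_topology` from [plan_tree()].
#' @param seed Optional integer seed for reproducible initialization.
#' @return An object of class `anvn_vasculature`: list with `topology`,
#'   `U` (per-node incoming branch weight, `NA` at the root), `E` (per-node
#'   energies, filled by [propagate_energy()]), and reservoir fields
#'   `source_weight`/`source_energy` (`NULL` unless used as an ANVN_R).
#' @export
init_vasculature <- function(topology, seed = NULL) {
  stopifnot(inherits(topology, "anvn_topology"))
  if (!is.null(seed)) set.seed(seed)
  U <- rep(NA_real_, topology$n_nodes)
  if (topology$n_nodes > 1L) {
    U[-1L] <- stats::runif(topology$n_nodes - 1L)
  }
  state <- structure(
    list(topology = topology, U = U, E = rep(NA_real_, topology$n_nodes),
         source_weight = NULL, source_energy = NULL),
    class = "anvn_vasculature"
  )
  normalize_weights(state)
}

#' Normalize sibling branch weights
#'
#' Divides every branch weight by the sum of absolute weights over its
#' sibling group, so each group's absolute weights sum to one and the
#' energy leaving a parent equals the energy that entered it.
#'
#' @param state An `anvn_vasculature`.
#' @return The state with normalized weights.
#' @export
normalize_weights <- function(state) {
  stopifnot(inherits(state, "anvn_vasculature"))
  top <- state$topology
  if (top$n_nodes == 1L) return(state)
  U <- state$U
  p <- top$parent[-1L]
  s_by_parent <- rowsum(abs(U[-1L]), p)
  if (any(s_by_parent == 0)) {
    stop("degenerate weights: a sibling group sums to zero", call. = FALSE)
  }
  sums <- numeric(top$n_nodes)
  sums[as.integer(rownames(s_by_parent))] <- s_by_parent[, 1L]
  U[-1L] <- U[-1L] / sums[p]
  state$U <- U
  state
}

#' Propagate energy from the root to the leaves
#'
#' Sets the root energy to `E_s` and assigns every other node the product of
#' its parent's energy and its branch weight, level by level. With
#' nonnegative normalized weights the leaf energies sum to `E_s`.
#'
#' @param state An `anvn_vasculature` with normalized weights.
#' @param E_s Energy supplied at the root node, >= 0.
#' @return The state with `E` filled for every node.
#' @export
propagate_energy <- function(state, E_s) {
  stopifnot(inherits(state, "anvn_vasculature"))
  if (length(E_s) != 1L || !is.finite(E_s) || E_s < 0) {
    stop("`E_s` must be a single nonnegative number", call. = FALSE)
  }
  top <- state$topology
  E <- numeric(top$n_nodes)
  E[1L] <- E_s
  if (top$n_levels > 1L) {
    for (l in seq(2L, top$n_levels)) {
      nodes <- top$level_nodes[[l]]
      E[nodes] <- state$U[nodes] * E[top$parent[nodes]]
    }
  }
  state$E <- E
  state
}

#' Leaf-node energies in hidden-neuron order
#'
#' @param state An `anvn_vasculature` after [propagate_energy()].
#' @return Numeric vector of length `n_leaves`; element `j` is the energy
#'   delivered to hidden neuron `j`.
#' @export
leaf_energies <- function(state) {
  stopifnot(inherits(state, "anvn_vasculature"))
  state$E[state$topology$leaf_ids]
}

#' Total consumed energy (sum over leaf nodes)
#'
#' @param state An `anvn_vasculature` after [propagate_energy()].
#' @return Scalar total energy delivered to the hidden layer.
#' @export
consumed_energy <- function(state) {
  sum(leaf_energies(state))
}

#' Backpropagate energy-demand gradients up the tree
#'
#' Each internal node's gradient is the mean of its children's gradients,
#' computed leaves to root. Every branch weight is then incremented by
#' `eta_v` times the gradient of the node it feeds, optionally clamped to be
#' nonnegative, and all sibling groups are renormalized. The root-node
#' gradient is kept in `state$root_gradient` (the reservoir variant uses it
#' to update the source weight).
#'
#' @param state An `anvn_vasculature`.
#' @param leaf_gradients Numeric vector, one energy gradient per leaf in
#'   hidden-neuron order.
#' @param eta_v Vascular learning rate (default 0.01).
#' @param clamp If `TRUE` (default), clamp updated weights at zero before
#'   renormalizing so energies stay nonnegative; if `FALSE`, apply the
#'   absolute-value normalization to possibly negative weights.
#' @return The updated state.
#' @export
backpropagate_energy <- function(state, leaf_gradients, eta_v = 0.01,
                                 clamp = TRUE) {
  stopifnot(inherits(state, "anvn_vasculature"))
  top <- state$topology
  if (length(leaf_gradients) != top$n_leaves) {
    stop("`leaf_gradients` must have one entry per leaf", call. = FALSE)
  }
  g <- numeric(top$n_nodes)
  g[top$leaf_ids] <- leaf_gradients
  if (top$n_levels > 1L) {
    for (l in seq(top$n_levels - 1L, 1L)) {
      kids <- top$level_nodes[[l + 1L]]
      p <- top$parent[kids]
      s <- rowsum(g[kids], p)
      n_c <- rowsum(rep(1, length(kids)), p)
      g[as.integer(rownames(s))] <- s[, 1L] / n_c[, 1L]
    }
    U <- state$U
    U[-1L] <- U[-1L] + eta_v * g[-1L]
    if (clamp) U[-1L] <- pmax(U[-1L], 0)
    state$U <- U
    state <- normalize_weights(state)
  }
  state$root_gradient <- g[1L]
  state
}

#' @export
print.anvn_vasculature <- function(x, ...) {
  top <- x$topology
  cat("anvn vasculature:", top$n_leaves, "leaves, k =", top$k,
      ",", top$n_levels, "levels\n")
  if (!all(is.na(x$E))) {
    cat("  root energy:", format(x$E[1L]),
        " leaf sum:", format(sum(leaf_energies(x))), "\n")
  }
  if (!is.null(x$source_weight)) {
    cat("  source weight U0:", format(x$source_weight),
        " reservoir:", format(x$source_energy * (1 - x$source_weight)), "\n")
  }
  invisible(x)
}

#' Serialize a vasculature (topology + weights) to JSON
#'
#' Numbers are written with 17 significant digits so the round trip through
#' [vasculature_from_json()] is exact.
#'
#' @param state An `anvn_vasculature`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
vasculature_to_json <- function(state, path = NULL) {
  stopifnot(inherits(state, "anvn_vasculature"))
  top <- state$topology
  obj <- list(
    n_leaves = top$n_leaves, k = top$k,
    U = state$U, E = state$E,
    source_weight = state$source_weight,
    source_energy = state$source_energy
  )
  js <- jsonlite::toJSON(obj, digits = I(17), null = "null", na = "null",
                         auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize a vasculature from JSON
#'
#' @param x A JSON string or a path to a JSON file produced by
#'   [vasculature_to_json()].
#' @return An `anvn_vasculature` (topology rebuilt deterministically from
#'   the stored `n_leaves` and `k`).
#' @export
vasculature_from_json <- function(x) {
  if (length(x) == 1L && file.exists(x)) x <- paste(readLines(x), collapse = "")
  obj <- jsonlite::fromJSON(x)
  top <- plan_tree(obj$n_leaves, obj$k)
  state <- structure(
    list(topology = top,
         U = as.numeric(obj$U), E = as.numeric(obj$E),
         source_weight = if (is.null(obj$source_weight)) NULL else
           as.numeric(obj$source_weight),
         source_energy = if (is.null(obj$source_energy)) NULL else
           as.numeric(obj$source_energy)),
    class = "anvn_vasculature"
  )
  state
}
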