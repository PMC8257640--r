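#' Plan a k-ary vascular tree topology
#'
#' Constructs the static topology of a vascular tree with `n_leaves` terminal
#' nodes, one per hidden neuron, branching with at most `k` children per
#' node. The number of levels is \eqn{L = 1 + \lceil \log N / \log k \rceil}
#' and level \eqn{l} (root at level 1) holds \eqn{\lceil N / k^{L-l} \rceil}
#' nodes. When `n_leaves` is not a power of `k`, the first
#' \eqn{\lfloor c/k \rfloor} parents of a level receive `k` children each and
#' the remaining children are attached to the last parent in breadth-first
#' order.
#'
#' Nodes are numbered 1..`n_nodes` in breadth-first order with the root at 1;
#' the leaves occupy the final `n_leaves` positions and leaf `j` feeds hidden
#' neuron `j`.
#'
#' @param n_leaves Number of leaf nodes (= hidden neurons), >= 1.
#' @param k Branching factor, >= 2. For `n_leaves >= 2`, `k <= n_leaves`
#'   (`k = n_leaves` gives a 2-level star). For `n_leaves = 1` the tree is a
#'   single node and `k` is irrelevant.
#' @return An object of class `anvn_topology`: a list with elements
#'   `n_leaves`, `k`, `n_levels`, `n_nodes`, `level_sizes`, `parent`
#'   (integer vector, `NA` at the root), `level`, `children` (list of integer
#'   vectors), `level_nodes` (list of node ids per level) and `leaf_ids`.
#' @examples
#' top <- plan_tree(512, 8)
#' top$n_levels  # 4
#' top$n_nodes   # 585
#' @export
plan_tree <- function(n_leaves, k) {
  if (length(n_leaves) != 1L || !is.finite(n_leaves) || n_leaves < 1 ||
      n_leaves != floor(n_leaves)) {
    stop("`n_leaves` must be a single integer >= 1", call. = FALSE)
  }
  if (length(k) != 1L || !is.finite(k) || k < 2 || k != floor(k)) {
    stop("`k` must be a single integer >= 2", call. = FALSE)
  }
  n_leaves <- as.integer(n_leaves)
  k <- as.integer(k)
  if (n_leaves > 1L && k > n_leaves) {
    stop("`k` must not exceed `n_leaves`", call. = FALSE)
  }

  # exact integer ceil(log_k(N)): smallest m with k^m >= N
  m <- 0L
  p <- 1
  while (p < n_leaves) {
    p <- p * k
    m <- m + 1L
  }
  n_levels <- 1L + m

  # level l holds ceil(N / k^(L - l)) nodes, root level 1 down to leaves
  level_sizes <- integer(n_levels)
  d <- 1
  for (l in seq(n_levels, 1L)) {
    level_sizes[l] <- as.integer(ceiling(n_leaves / d))
    d <- d * k
  }
  n_nodes <- sum(level_sizes)

  parent <- rep(NA_integer_, n_nodes)
  level <- rep(NA_integer_, n_nodes)
  offset <- c(0L, cumsum(level_sizes))
  level_nodes <- vector("list", n_levels)
  for (l in seq_len(n_levels)) {
    level_nodes[[l]] <- seq.int(offset[l] + 1L, offset[l + 1L])
    level[level_nodes[[l]]] <- l
  }

  if (n_levels > 1L) {
    for (l in seq_len(n_levels - 1L)) {
      parents <- level_nodes[[l]]
      kids <- level_nodes[[l + 1L]]
      c_n <- length(kids)
      full <- c_n %/% k
      counts <- rep.int(k, full)
      if (c_n %% k > 0L) counts <- c(counts, c_n %% k)
      stopifnot(length(counts) == length(parents))
      parent[kids] <- rep.int(parents, counts)
    }
  }

  children <- vector("list", n_nodes)
  nr <- which(!is.na(parent))
  for (x in nr) children[[parent[x]]] <- c(children[[parent[x]]], x)

  structure(
    list(
      n_leaves = n_leaves, k = k, n_levels = n_levels, n_nodes = n_nodes,
      level_sizes = level_sizes, parent = parent, level = level,
      children = children, level_nodes = level_nodes,
      leaf_ids = level_nodes[[n_levels]]
    ),
    class = "anvn_topology"
  )
}

#' @export
print.anvn_topology <- function(x, ...) {
  cat("anvn vascular tree topology\n")
  cat("  leaves:", x$n_leaves, " branching factor:", x$k, "\n")
  cat("  levels:", x$n_levels, " nodes:", x$n_nodes, "\n")
  cat("  level sizes:", paste(x$level_sizes, collapse = " "), "\n")
  invisible(x)
}

# identical static structure (ignores weights)
same_topology <- function(a, b) {
  a$n_leaves == b$n_leaves && a$k == b$k && a$n_nodes == b$n_nodes &&
    identical(a$parent, b$parent)
}
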