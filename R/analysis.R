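#' Classification accuracy in percent
#'
#' @param predictions Integer class labels (0-based).
#' @param labels True labels, same length, each in `0..(n_classes - 1)`.
#' @param n_classes Number of classes (default 10).
#' @return `100 * correct / total`.
#' @export
accuracy <- function(predictions, labels, n_classes = 10) {
  if (length(predictions) == 0L || length(predictions) != length(labels)) {
    stop("`predictions` and `labels` must be nonempty and of equal length",
         call. = FALSE)
  }
  if (any(labels < 0 | labels >= n_classes | labels != floor(labels))) {
    stop("labels must be integers in 0..", n_classes - 1, call. = FALSE)
  }
  100 * mean(predictions == labels)
}

#' Energy efficiency
#'
#' The accuracy gain over a baseline, divided by the energy consumed:
#' `psi = (alpha - alpha_baseline) / xi`, with accuracies carried in
#' percent (the default convention; set `percent = FALSE` for fractional
#' accuracies).
#'
#' @param alpha Accuracy at the probed condition.
#' @param alpha_baseline Baseline accuracy (at root energy 1 for energy
#'   sweeps; at the minimum network size for size sweeps).
#' @param xi Consumed energy, > 0 (vectorized).
#' @param percent If `FALSE`, divide the accuracy difference by 100.
#' @return Efficiency value(s); zero when `alpha == alpha_baseline`.
#' @export
efficiency <- function(alpha, alpha_baseline, xi, percent = TRUE) {
  if (any(!is.finite(xi)) || any(xi <= 0)) {
    stop("`xi` must be positive", call. = FALSE)
  }
  d <- alpha - alpha_baseline
  if (!percent) d <- d / 100
  d / xi
}

#' Energy deficit of a pretrained network under a vascular supply
#'
#' The desired energy is read off the trained biases through the
#' bias-energy law: `E_D = sum(1 - b_j)`. The available energy is the sum
#' of leaf energies; the deficit is their difference (sign-indefinite).
#'
#' @param trained_biases Trained hidden biases `b^D`.
#' @param leaf_energies Delivered leaf energies, same length.
#' @return List of class `anvn_deficit` with `E_D`, `E_A`, `deficit`.
#' @export
energy_deficit <- function(trained_biases, leaf_energies) {
  if (length(trained_biases) != length(leaf_energies)) {
    stop("`trained_biases` and `leaf_energies` must have equal length",
         call. = FALSE)
  }
  E_D <- sum(1 - trained_biases)
  E_A <- sum(leaf_energies)
  structure(list(E_D = E_D, E_A = E_A, deficit = E_D - E_A),
            class = "anvn_deficit")
}

#' @export
print.anvn_deficit <- function(x, ...) {
  cat("energy deficit: desired", format(x$E_D), "- available",
      format(x$E_A), "=", format(x$deficit), "\n")
  invisible(x)
}

# mean per-class squared prediction error over a test set (the printed
# "RMSE": mean squared error without a root; `rooted` takes the square root)
prediction_mse <- function(Y, D, rooted = FALSE) {
  v <- mean(rowMeans((D - Y)^2))
  if (rooted) sqrt(v) else v
}

#' Ablate hidden neurons one at a time and correlate error with energy
#'
#' With all neurons active, the control error is the mean per-class squared
#' prediction error over the test set. Each hidden neuron is then switched
#' off by zeroing its activation, the outputs are recomputed, and the
#' neuron's error contribution is `dRMSE_k = RMSE_k - RMSE_control`. The
#' Energy Error Correlation Coefficient (EECC) is the Pearson correlation
#' between the error contributions and the per-neuron consumed energies.
#'
#' @param mlp A trained `anvn_mlp`.
#' @param X,y Test inputs and 0-based labels.
#' @param leaf_energies Per-neuron consumed energy (sets the biases and is
#'   correlated against the error contributions).
#' @param n_classes Number of classes (default 10).
#' @param rooted Take the square root of the mean squared errors
#'   (default `FALSE`, the printed convention).
#' @return List of class `anvn_ablation` with `table` (data frame: neuron,
#'   delta_rmse, energy), `rmse_control` and `eecc`.
#' @export
ablate_and_score <- function(mlp, X, y, leaf_energies, n_classes = 10,
                             rooted = FALSE) {
  stopifnot(inherits(mlp, "anvn_mlp"))
  if (mlp$n_hidden < 3L) {
    stop("correlation undefined: need at least 3 hidden neurons",
         call. = FALSE)
  }
  D <- one_hot(y, n_classes)
  cache <- mlp_forward(mlp, X, leaf_energies = leaf_energies)
  rmse0 <- prediction_mse(cache$Y, D, rooted = rooted)
  drmse <- vapply(seq_len(mlp$n_hidden), function(k) {
    # zeroing V_k removes its contribution V_k * W_s[, k] from every output
    Hs_k <- cache$Hs - tcrossprod(cache$V[, k], mlp$W_s[, k])
    Yk <- logistic(Hs_k, mlp$slope2)
    prediction_mse(Yk, D, rooted = rooted) - rmse0
  }, numeric(1))
  eecc <- pearson(drmse, leaf_energies)
  structure(
    list(table = data.frame(neuron = seq_len(mlp$n_hidden),
                            delta_rmse = drmse, energy = leaf_energies),
         rmse_control = rmse0, eecc = eecc),
    class = "anvn_ablation"
  )
}

#' @export
print.anvn_ablation <- function(x, ...) {
  cat("ablation of", nrow(x$table), "hidden neurons\n")
  cat("  control error:", format(x$rmse_control),
      " EECC:", format(x$eecc), "\n")
  invisible(x)
}

#' Pearson product-moment correlation with an explicit degeneracy error
#'
#' Wraps [stats::cor()] but fails loudly when either input has zero
#' variance (where the correlation is undefined) instead of returning `NA`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Per-level vascular weight drift between two trained trees
#'
#' For two weight assignments on the same topology, sums the squared
#' differences of the branch weights emerging from the nodes of each level
#' (root = level 1; level `L - 1` is leaf-adjacent, the microvasculature).
#' For reservoir-carrying states, the squared difference of the
#' source-to-root weights is reported as attribute `source_drift`.
#'
#' @param state_a,state_b Two `anvn_vasculature` objects on an identical
#'   topology.
#' @return Data frame with columns `level` (1..L-1) and `drift`.
#' @export
transfer_drift <- function(state_a, state_b) {
  stopifnot(inherits(state_a, "anvn_vasculature"),
            inherits(state_b, "anvn_vasculature"))
  if (!same_topology(state_a$topology, state_b$topology)) {
    stop("the two states must share the same topology", call. = FALSE)
  }
  top <- state_a$topology
  if (top$n_levels < 2L) {
    stop("tree has no branches to compare", call. = FALSE)
  }
  drift <- vapply(seq_len(top$n_levels - 1L), function(l) {
    kids <- top$level_nodes[[l + 1L]]  # edges emerging from level l
    sum((state_a$U[kids] - state_b$U[kids])^2)
  }, numeric(1))
  out <- data.frame(level = seq_len(top$n_levels - 1L), drift = drift)
  if (!is.null(state_a$source_weight) && !is.null(state_b$source_weight)) {
    attr(out, "source_drift") <-
      (state_a$source_weight - state_b$source_weight)^2
  }
  out
}

#' Spread of steady-state per-capita energy across initial conditions
#'
#' Summarizes the settling points of several training runs launched from
#' different initial per-capita energies. A small spread indicates a
#' fixed-point attractor (the network forgets its initial energy); a large
#' spread indicates a line of attractors.
#'
#' @param traces List of >= 3 trace data frames from runs on the same
#'   network size.
#' @param column Trace column to summarize (default `"per_capita"`).
#' @param tail_frac Steady-state window as a fraction of epochs.
#' @return List with `median`, `min`, `max` and `spread = max - min` of the
#'   steady-state values.
#' @export
attractor_spread <- function(traces, column = "per_capita",
                             tail_frac = 0.05) {
  if (!is.list(traces) || length(traces) < 3L) {
    stop("need at least 3 traces", call. = FALSE)
  }
  s <- vapply(traces, steady_state, numeric(1), column = column,
              tail_frac = tail_frac)
  list(median = stats::median(s), min = min(s), max = max(s),
       spread = max(s) - min(s))
}
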