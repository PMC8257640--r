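# logistic activation with optional slope; derivative expressed via the
# activation value (a = g(z) => g'(z) = slope * a * (1 - a))
logistic <- function(z, slope = 1) 1 / (1 + exp(-slope * z))

#' Hidden-neuron bias from delivered energy
#'
#' The bias-energy law: `b = 1 - E` for `0 <= E <= 2`, saturating at `-1`
#' for `E > 2`. More energy lowers the firing threshold; beyond 2 units a
#' neuron is already at its lowest threshold and extra energy has no effect.
#'
#' @param E Nonnegative energy (vectorized).
#' @return Bias value(s) in `[-1, 1]`.
#' @examples
#' bias_from_energy(c(0, 1, 2, 3))  # 1 0 -1 -1
#' @export
bias_from_energy <- function(E) {
  if (any(!is.finite(E)) || any(E < 0)) {
    stop("energies must be finite and nonnegative", call. = FALSE)
  }
  ifelse(E <= 2, 1 - E, -1)
}

#' Initialize a single-hidden-layer perceptron
#'
#' Weights are drawn uniformly in (-0.5, 0.5); the input-to-hidden rows are
#' absolute-normalized (each row's absolute values sum to one), mirroring
#' the sibling normalization of the vascular tree. Hidden biases `b_f` are
#' free parameters only when the net is trained standalone; in an
#' energy-coupled network they are derived from leaf energies.
#'
#' @param n_in,n_hidden,n_out Layer sizes.
#' @param seed Optional integer seed.
#' @param normalize Normalize input-weight rows at initialization
#'   (default `TRUE`).
#' @param slope1,slope2 Slopes of the hidden/output logistic activations
#'   (default 1, the standard logistic).
#' @return An object of class `anvn_mlp` with matrices `W_f`
#'   (`n_hidden x n_in`), `W_s` (`n_out x n_hidden`), vectors `b_f`, `b_s`,
#'   and the activation slopes.
#' @export
init_mlp <- function(n_in, n_hidden, n_out, seed = NULL, normalize = TRUE,
                     slope1 = 1, slope2 = 1) {
  if (!is.null(seed)) set.seed(seed)
  mlp <- structure(
    list(
      n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
      n_out = as.integer(n_out),
      W_f = matrix(stats::runif(n_hidden * n_in, -0.5, 0.5), n_hidden, n_in),
      W_s = matrix(stats::runif(n_out * n_hidden, -0.5, 0.5), n_out, n_hidden),
      b_f = stats::runif(n_hidden, -0.5, 0.5),
      b_s = stats::runif(n_out, -0.5, 0.5),
      slope1 = slope1, slope2 = slope2
    ),
    class = "anvn_mlp"
  )
  if (normalize) mlp <- normalize_input_weights(mlp) else mlp
}

#' Absolute-normalize the input-to-hidden weight rows
#'
#' Each hidden neuron's incoming weights are divided by the sum of their
#' absolute values, so every row's absolute sum is one.
#'
#' @param mlp An `anvn_mlp`.
#' @return The normalized `anvn_mlp`.
#' @export
normalize_input_weights <- function(mlp) {
  stopifnot(inherits(mlp, "anvn_mlp"))
  s <- rowSums(abs(mlp$W_f))
  if (any(s == 0)) {
    stop("degenerate weights: an input-weight row is all zero", call. = FALSE)
  }
  mlp$W_f <- mlp$W_f / s
  mlp
}

#' Forward pass
#'
#' Computes, per the printed sign convention, hidden net input
#' `h_f = W_f x - b_f`, hidden activation `V = g1(h_f)`, output net input
#' `h_s = W_s V - b_s` and output `y = g2(h_s)`. When `leaf_energies` is
#' supplied the hidden biases are derived from it via [bias_from_energy()];
#' otherwise the net's own `b_f` is used (standalone mode).
#'
#' @param mlp An `anvn_mlp`.
#' @param X Input matrix, samples in rows (`n x n_in`); a single vector is
#'   promoted to one row.
#' @param leaf_energies Optional vector of length `n_hidden`.
#' @return A list (class `anvn_forward`) with batch matrices `Hf`, `V`,
#'   `Hs`, `Y` (samples in rows) and the `b_f` used.
#' @export
mlp_forward <- function(mlp, X, leaf_energies = NULL) {
  stopifnot(inherits(mlp, "anvn_mlp"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != mlp$n_in) stop("input dimension mismatch", call. = FALSE)
  b_f <- if (is.null(leaf_energies)) mlp$b_f else {
    if (length(leaf_energies) != mlp$n_hidden) {
      stop("`leaf_energies` must have one entry per hidden neuron",
           call. = FALSE)
    }
    bias_from_energy(leaf_energies)
  }
  Hf <- tcrossprod(X, mlp$W_f)
  Hf <- Hf - rep(b_f, each = nrow(X))
  V <- logistic(Hf, mlp$slope1)
  Hs <- tcrossprod(V, mlp$W_s)
  Hs <- Hs - rep(mlp$b_s, each = nrow(X))
  Y <- logistic(Hs, mlp$slope2)
  structure(list(Hf = Hf, V = V, Hs = Hs, Y = Y, b_f = b_f),
            class = "anvn_forward")
}

#' Quadratic cost with optional regularization
#'
#' `C = 1/2 sum (d - y)^2`, plus `lambda_w/2 * sum(W^2)` over both weight
#' layers when `lambda_w > 0`, plus `lambda_E * sum |E|` when `lambda_E > 0`.
#' Summed over all samples in the batch.
#'
#' @param Y,D Output and target matrices of equal shape (samples in rows).
#' @param mlp The net (needed for the weight penalty); may be `NULL` when
#'   `lambda_w = 0`.
#' @param lambda_w,lambda_E Regularization strengths (default 0).
#' @param leaf_energies Energies entering the L1 penalty.
#' @return Nonnegative scalar; zero iff `Y == D` when both lambdas are zero.
#' @export
mlp_cost <- function(Y, D, mlp = NULL, lambda_w = 0, lambda_E = 0,
                     leaf_energies = NULL) {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  if (is.null(dim(D))) D <- matrix(D, nrow = 1L)
  stopifnot(all(dim(Y) == dim(D)))
  cost <- 0.5 * sum((D - Y)^2)
  if (lambda_w > 0) {
    cost <- cost + lambda_w * 0.5 * (sum(mlp$W_s^2) + sum(mlp$W_f^2))
  }
  if (lambda_E > 0) cost <- cost + lambda_E * sum(abs(leaf_energies))
  cost
}

#' Backward pass: neural updates and the energy-demand gradient
#'
#' Computes the printed update quantities (learning rate included, batch
#' averaged): output error terms `delta_s = e * g2'(h_s)` with `e = d - y`,
#' hidden error terms `delta_f = (t(W_s) delta_s) * g1'(h_f)`, and
#'
#' * `dW_s = eta * (delta_s V - lambda_w W_s)`
#' * `db_s = -eta * delta_s`
#' * `dW_f = eta * (delta_f x - lambda_w W_f)`
#' * `db_f = -eta * delta_f` (used only in standalone training)
#' * `dE_j`: the energy-demand gradient, `eta * delta_f` on the linear
#'   branch `0 <= E <= 2`, and above 2 units either `0` (plain coupling) or
#'   `-gamma` (reservoir coupling, returning excess energy). With
#'   `lambda_E > 0` the penalty contributes `-eta * lambda_E` on the linear
#'   branch, giving `eta * (delta_f - lambda_E)`.
#'
#' @param mlp An `anvn_mlp`.
#' @param cache Forward cache from [mlp_forward()] on the same `X`.
#' @param X Input batch (samples in rows).
#' @param D Target batch.
#' @param leaf_energies Energies that set the hidden biases (`NULL` in
#'   standalone mode: `dE` is then omitted).
#' @param eta Neural learning rate.
#' @param lambda_w,lambda_E Regularization strengths.
#' @param coupling `"anvn"` (zero gradient above 2 units) or `"reservoir"`
#'   (`-gamma` above 2 units).
#' @param gamma Excess-return slope for the reservoir coupling.
#' @return List with `dW_s`, `db_s`, `dW_f`, `db_f` and (when coupled) `dE`.
#' @export
mlp_backward <- function(mlp, cache, X, D, leaf_energies = NULL, eta = 0.1,
                         lambda_w = 0, lambda_E = 0,
                         coupling = c("anvn", "reservoir"), gamma = 0.005) {
  stopifnot(inherits(mlp, "anvn_mlp"), inherits(cache, "anvn_forward"))
  coupling <- match.arg(coupling)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (is.null(dim(D))) D <- matrix(D, nrow = 1L)
  n <- nrow(X)
  e <- D - cache$Y
  Ds <- e * (mlp$slope2 * cache$Y * (1 - cache$Y))
  Df <- (Ds %*% mlp$W_s) * (mlp$slope1 * cache$V * (1 - cache$V))
  out <- list(
    dW_s = eta * (crossprod(Ds, cache$V) / n - lambda_w * mlp$W_s),
    db_s = -eta * colMeans(Ds),
    dW_f = eta * (crossprod(Df, X) / n - lambda_w * mlp$W_f),
    db_f = -eta * colMeans(Df)
  )
  if (!is.null(leaf_energies)) {
    df_bar <- colMeans(Df)
    on_linear <- leaf_energies <= 2
    dE <- numeric(mlp$n_hidden)
    dE[on_linear] <- eta * df_bar[on_linear]
    if (coupling == "reservoir") {
      dE[!on_linear] <- -gamma
      # the excess-return slope replaces the cost gradient above 2 units;
      # the energy penalty applies on the coupled branch only
      if (lambda_E > 0) dE[on_linear] <- dE[on_linear] - eta * lambda_E
    } else if (lambda_E > 0) {
      dE <- dE - eta * lambda_E
    }
    out$dE <- dE
  }
  out
}

# apply neural updates in place; renormalize input rows unless disabled
apply_updates <- function(mlp, upd, standalone = FALSE, renormalize = TRUE) {
  mlp$W_s <- mlp$W_s + upd$dW_s
  mlp$b_s <- mlp$b_s + upd$db_s
  mlp$W_f <- mlp$W_f + upd$dW_f
  if (standalone) mlp$b_f <- mlp$b_f + upd$db_f
  if (renormalize) mlp <- normalize_input_weights(mlp)
  mlp
}

#' Predicted class labels from network outputs
#'
#' Output unit `i` codes class `i - 1` (one-hot targets put the 1 at index
#' `class + 1`), so the label is the argmax index minus one. Ties break
#' toward the lowest class index.
#'
#' @param Y Output matrix (samples in rows) or a single output vector.
#' @return Integer vector of class labels starting at 0.
#' @export
predict_class <- function(Y) {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  max.col(Y, ties.method = "first") - 1L
}

#' @export
print.anvn_mlp <- function(x, ...) {
  cat("anvn perceptron:", x$n_in, "->", x$n_hidden, "->", x$n_out, "\n")
  invisible(x)
}

#' Serialize a perceptron checkpoint to JSON
#'
#' All weight tables, biases and activation slopes, written with 17
#' significant digits for an exact round trip.
#'
#' @param mlp An `anvn_mlp`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
mlp_to_json <- function(mlp, path = NULL) {
  stopifnot(inherits(mlp, "anvn_mlp"))
  obj <- list(
    n_in = mlp$n_in, n_hidden = mlp$n_hidden, n_out = mlp$n_out,
    W_f = mlp$W_f, W_s = mlp$W_s, b_f = mlp$b_f, b_s = mlp$b_s,
    slope1 = mlp$slope1, slope2 = mlp$slope2
  )
  js <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize a perceptron checkpoint
#'
#' @param x JSON string or path produced by [mlp_to_json()].
#' @return An `anvn_mlp`.
#' @export
mlp_from_json <- function(x) {
  if (length(x) == 1L && file.exists(x)) x <- paste(readLines(x), collapse = "")
  obj <- jsonlite::fromJSON(x)
  structure(
    list(
      n_in = as.integer(obj$n_in), n_hidden = as.integer(obj$n_hidden),
      n_out = as.integer(obj$n_out),
      W_f = matrix(obj$W_f, obj$n_hidden, obj$n_in),
      W_s = matrix(obj$W_s, obj$n_out, obj$n_hidden),
      b_f = as.numeric(obj$b_f), b_s = as.numeric(obj$b_s),
      slope1 = obj$slope1, slope2 = obj$slope2
    ),
    class = "anvn_mlp"
  )
}
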