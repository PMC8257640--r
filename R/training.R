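#' Train a standalone perceptron (no vasculature)
#'
#' Full-batch gradient training of the perceptron alone, with the hidden
#' biases as ordinary free parameters. Used as the "pretrained" network for
#' the untrained and sequential vascular regimes.
#'
#' @param data An `anvn_dataset` (see [make_synthetic()]).
#' @param n_hidden Number of hidden neurons.
#' @param epochs Number of full-batch epochs.
#' @param eta Neural learning rate (default 0.05).
#' @param seed Optional seed for weight initialization.
#' @param renormalize Renormalize input-weight rows after every update
#'   (default `TRUE`).
#' @param slope1,slope2 Activation slopes (hidden default 5, a sharp
#'   threshold on the scale of the bias-energy law; output default 1).
#' @param eval_every Record train/test accuracy every this many epochs
#'   (default 100; use `Inf` to skip).
#' @return List with `mlp` (trained, class `anvn_mlp`) and `trace`
#'   (data frame of epoch, cost, train/test accuracy).
#' @export
train_mlp <- function(data, n_hidden, epochs, eta = 0.05, seed = NULL,
                      renormalize = TRUE, slope1 = 5, slope2 = 1,
                      eval_every = 100) {
  stopifnot(inherits(data, "anvn_dataset"))
  mlp <- init_mlp(ncol(data$X_train), n_hidden, data$n_classes, seed = seed,
                  slope1 = slope1, slope2 = slope2)
  D <- one_hot(data$y_train, data$n_classes)
  rows <- list()
  for (ep in seq_len(epochs)) {
    cache <- mlp_forward(mlp, data$X_train)
    upd <- mlp_backward(mlp, cache, data$X_train, D, eta = eta)
    mlp <- apply_updates(mlp, upd, standalone = TRUE,
                         renormalize = renormalize)
    if (ep %% eval_every == 0 || ep == epochs) {
      rows[[length(rows) + 1L]] <- data.frame(
        epoch = ep,
        cost = mlp_cost(cache$Y, D),
        train_acc = accuracy(predict_class(cache$Y), data$y_train,
                             n_classes = data$n_classes),
        test_acc = evaluate_accuracy(mlp, data)
      )
    }
  }
  list(mlp = mlp, trace = do.call(rbind, rows))
}

#' Test-set accuracy of a perceptron, optionally under an energy supply
#'
#' @param mlp An `anvn_mlp`.
#' @param data An `anvn_dataset`.
#' @param leaf_energies Optional energies overriding the hidden biases via
#'   the bias-energy law.
#' @return Accuracy in percent on the test split.
#' @export
evaluate_accuracy <- function(mlp, data, leaf_energies = NULL) {
  cache <- mlp_forward(mlp, data$X_test, leaf_energies = leaf_energies)
  accuracy(predict_class(cache$Y), data$y_test, n_classes = data$n_classes)
}

new_trace <- function() {
  data.frame(epoch = integer(), xi = double(), per_capita = double(),
             train_acc = double(), test_acc = double(), reservoir = double())
}

#' Evaluate a pretrained perceptron under an untrained vascular tree
#'
#' The vascular weights are fixed so the root energy is split equally over
#' the leaves (`E_s / N` each); hidden biases are overridden by the
#' bias-energy law and test accuracy is evaluated for each root energy.
#' Efficiency is the accuracy gain over the accuracy at root energy 1,
#' divided by consumed energy.
#'
#' @param mlp A trained `anvn_mlp`.
#' @param topology An `anvn_topology` with `n_leaves == mlp$n_hidden`.
#' @param E_s_values Root energies to probe.
#' @param data An `anvn_dataset`.
#' @return Data frame with columns `E_s`, `xi`, `per_capita`, `accuracy`,
#'   `efficiency` (accuracy in percent).
#' @export
run_untrained <- function(mlp, topology, E_s_values, data) {
  stopifnot(inherits(mlp, "anvn_mlp"), inherits(topology, "anvn_topology"))
  if (topology$n_leaves != mlp$n_hidden) {
    stop("topology leaf count must equal the hidden-layer size",
         call. = FALSE)
  }
  N <- topology$n_leaves
  acc <- vapply(E_s_values, function(E_s) {
    evaluate_accuracy(mlp, data, leaf_energies = rep(E_s / N, N))
  }, numeric(1))
  acc0 <- evaluate_accuracy(mlp, data, leaf_energies = rep(1 / N, N))
  data.frame(E_s = E_s_values, xi = E_s_values,
             per_capita = E_s_values / N, accuracy = acc,
             efficiency = efficiency(acc, acc0, E_s_values))
}

#' Sequentially train the vascular tree under a frozen perceptron
#'
#' The perceptron is trained first ([train_mlp()]) and its hidden biases
#' `b^T` are frozen. Each epoch the tree delivers energies, the realized
#' biases `b^E` are read off the bias-energy law, and the demand gradient
#' `dE = eta * (b^E - b^T)` (the linear branch has slope -1; zero where
#' `E > 2`; `eta` keeps the gradient on the same scale as the
#' backpropagated energy gradients of the other regimes) is sent up the
#' tree. Only vascular weights change.
#'
#' @param mlp A trained `anvn_mlp` (its `b_f` is the trained bias).
#' @param vasculature An `anvn_vasculature` on a tree with
#'   `n_leaves == mlp$n_hidden`.
#' @param E_s Root energy.
#' @param epochs Vascular training epochs.
#' @param eta Scale of the demand gradient (default 0.05).
#' @param eta_v Vascular learning rate (default 0.5).
#' @param data Optional `anvn_dataset` for periodic accuracy evaluation.
#' @param eval_every Evaluate accuracy every this many epochs (default 200).
#' @return List with `vasculature` (trained), `trace` (epoch, xi,
#'   per_capita, mean absolute bias mismatch `bias_gap`, accuracies).
#' @export
run_sequential <- function(mlp, vasculature, E_s, epochs, eta = 0.05,
                           eta_v = 0.5, data = NULL, eval_every = 200) {
  stopifnot(inherits(mlp, "anvn_mlp"),
            inherits(vasculature, "anvn_vasculature"))
  N <- vasculature$topology$n_leaves
  if (N != mlp$n_hidden) {
    stop("topology leaf count must equal the hidden-layer size",
         call. = FALSE)
  }
  b_T <- mlp$b_f
  rows <- vector("list", epochs)
  state <- vasculature
  for (ep in seq_len(epochs)) {
    state <- propagate_energy(state, E_s)
    E <- leaf_energies(state)
    b_E <- bias_from_energy(E)
    dE <- ifelse(E <= 2, eta * (b_E - b_T), 0)
    state <- backpropagate_energy(state, dE, eta_v = eta_v)
    acc <- if (!is.null(data) && (ep %% eval_every == 0 || ep == epochs)) {
      evaluate_accuracy(mlp, data, leaf_energies = E)
    } else NA_real_
    rows[[ep]] <- c(ep, sum(E), sum(E) / N, mean(abs(b_T - b_E)), acc)
  }
  trace <- as.data.frame(do.call(rbind, c(rows, list(matrix(0, 0, 5)))))
  names(trace) <- c("epoch", "xi", "per_capita", "bias_gap", "test_acc")
  list(vasculature = state, trace = trace)
}

#' Simultaneously train the perceptron and the vascular tree
#'
#' Each epoch: energies propagate root to leaves and set the hidden biases;
#' a full-batch forward/backward pass yields the neural updates and the
#' leaf energy-demand gradients (batch averaged); neural weights are
#' updated and renormalized; the energy gradients are backpropagated up the
#' tree and the vascular weights updated and renormalized.
#'
#' @param topology An `anvn_topology`.
#' @param E_s Root energy (fixed; the network consumes all of it).
#' @param epochs Training epochs.
#' @param data An `anvn_dataset`.
#' @param eta,eta_v Neural and vascular learning rates (defaults 0.05 and
#'   0.5).
#' @param lambda_w,lambda_E Optional regularization strengths.
#' @param slope1,slope2 Activation slopes (hidden default 5, output 1).
#' @param seed Optional seed (weights of both subnetworks).
#' @param eval_every Record accuracies every this many epochs (default 200).
#' @return List with `mlp`, `vasculature`, and per-epoch `trace`
#'   (epoch, xi, per_capita, train_acc, test_acc).
#' @export
run_simultaneous <- function(topology, E_s, epochs, data, eta = 0.05,
                             eta_v = 0.5, lambda_w = 0, lambda_E = 0,
                             slope1 = 5, slope2 = 1,
                             seed = NULL, eval_every = 200) {
  stopifnot(inherits(topology, "anvn_topology"),
            inherits(data, "anvn_dataset"))
  if (!is.null(seed)) set.seed(seed)
  N <- topology$n_leaves
  mlp <- init_mlp(ncol(data$X_train), N, data$n_classes,
                  slope1 = slope1, slope2 = slope2)
  state <- init_vasculature(topology)
  D <- one_hot(data$y_train, data$n_classes)
  rows <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    state <- propagate_energy(state, E_s)
    E <- leaf_energies(state)
    cache <- mlp_forward(mlp, data$X_train, leaf_energies = E)
    upd <- mlp_backward(mlp, cache, data$X_train, D, leaf_energies = E,
                        eta = eta, lambda_w = lambda_w, lambda_E = lambda_E)
    mlp <- apply_updates(mlp, upd)
    state <- backpropagate_energy(state, upd$dE, eta_v = eta_v)
    if (ep %% eval_every == 0 || ep == epochs) {
      rows[[ep]] <- c(ep, sum(E), sum(E) / N,
                      accuracy(predict_class(cache$Y), data$y_train,
                               n_classes = data$n_classes),
                      evaluate_accuracy(mlp, data, leaf_energies = E))
    } else {
      rows[[ep]] <- c(ep, sum(E), sum(E) / N, NA_real_, NA_real_)
    }
  }
  trace <- as.data.frame(do.call(rbind, c(rows, list(matrix(0, 0, 5)))))
  names(trace) <- c("epoch", "xi", "per_capita", "train_acc", "test_acc")
  list(mlp = mlp, vasculature = state, trace = trace)
}

#' Simultaneously train an ANVN with an energy reservoir (ANVN_R)
#'
#' The tree root hangs off a constant 5000-unit source through a trainable
#' weight `U_0`; the complementary weight `1 - U_0` feeds a reservoir. Leaf
#' gradients follow the reservoir coupling (`-gamma` for leaves above 2
#' energy units, returning excess energy); the root-level gradient also
#' updates `U_0`, and pairwise normalization keeps `U_0 + reservoir = 1`,
#' so leaf energy plus reservoir energy is always 5000.
#'
#' @param topology An `anvn_topology`.
#' @param per_capita0 Initial mean energy per leaf; `U_0` starts at
#'   `N * per_capita0 / source_energy` (must not exceed 1).
#' @param epochs Training epochs.
#' @param data An `anvn_dataset`.
#' @param eta,eta_v Neural and vascular learning rates (defaults 0.05 and
#'   0.5).
#' @param gamma Excess-return slope (default 0.005).
#' @param source_energy Source value (default 5000 units).
#' @param lambda_w,lambda_E Optional regularization strengths.
#' @param slope1,slope2 Activation slopes (hidden default 5, output 1).
#' @param seed Optional seed.
#' @param eval_every Record accuracies every this many epochs (default 200).
#' @return List with `mlp`, `vasculature` (carrying `source_weight` and
#'   `source_energy`) and per-epoch `trace`
#'   (epoch, xi, per_capita, train_acc, test_acc, reservoir).
#' @export
run_reservoir <- function(topology, per_capita0, epochs, data, eta = 0.05,
                          eta_v = 0.5, gamma = 0.005, source_energy = 5000,
                          lambda_w = 0, lambda_E = 0, slope1 = 5, slope2 = 1,
                          seed = NULL, eval_every = 200) {
  stopifnot(inherits(topology, "anvn_topology"),
            inherits(data, "anvn_dataset"))
  N <- topology$n_leaves
  U0 <- N * per_capita0 / source_energy
  if (U0 > 1) {
    stop("initial per-capita energy implies a source weight above 1",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  mlp <- init_mlp(ncol(data$X_train), N, data$n_classes,
                  slope1 = slope1, slope2 = slope2)
  state <- init_vasculature(topology)
  state$source_weight <- U0
  state$source_energy <- source_energy
  D <- one_hot(data$y_train, data$n_classes)
  rows <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    U0_now <- state$source_weight
    state <- propagate_energy(state, U0_now * source_energy)
    E <- leaf_energies(state)
    cache <- mlp_forward(mlp, data$X_train, leaf_energies = E)
    upd <- mlp_backward(mlp, cache, data$X_train, D, leaf_energies = E,
                        eta = eta, lambda_w = lambda_w, lambda_E = lambda_E,
                        coupling = "reservoir", gamma = gamma)
    mlp <- apply_updates(mlp, upd)
    state <- backpropagate_energy(state, upd$dE, eta_v = eta_v)
    # source's two children: root (U0) and reservoir (1 - U0); only the
    # root edge receives a gradient, the pair is then renormalized
    w_res <- 1 - state$source_weight
    u <- max(state$source_weight + eta_v * state$root_gradient, 0)
    if (u + w_res == 0) {
      stop("degenerate weights: source sibling group sums to zero",
           call. = FALSE)
    }
    state$source_weight <- u / (u + w_res)
    # snapshot the reservoir at the same instant as the leaf energies
    res_now <- source_energy * (1 - U0_now)
    if (ep %% eval_every == 0 || ep == epochs) {
      rows[[ep]] <- c(ep, sum(E), sum(E) / N,
                      accuracy(predict_class(cache$Y), data$y_train,
                               n_classes = data$n_classes),
                      evaluate_accuracy(mlp, data, leaf_energies = E),
                      res_now)
    } else {
      rows[[ep]] <- c(ep, sum(E), sum(E) / N, NA_real_, NA_real_, res_now)
    }
  }
  trace <- as.data.frame(do.call(rbind, c(rows, list(matrix(0, 0, 6)))))
  names(trace) <- c("epoch", "xi", "per_capita", "train_acc", "test_acc",
                    "reservoir")
  list(mlp = mlp, vasculature = state, trace = trace)
}

#' Continue training a reservoir model on a new dataset
#'
#' Takes a trained reservoir model (from [run_reservoir()]) and continues
#' simultaneous neural + vascular training on a different dataset, keeping
#' the learned weights as the starting point. Used for transfer-learning
#' runs, where the per-level drift of the vascular weights between the two
#' trained states is of interest (see [transfer_drift()]).
#'
#' @param model List with `mlp` and `vasculature` as returned by
#'   [run_reservoir()].
#' @param data The new `anvn_dataset` to train on.
#' @param epochs Additional training epochs.
#' @param eta,eta_v Neural and vascular learning rates.
#' @param gamma Excess-return slope.
#' @param eval_every Record accuracies every this many epochs.
#' @return List with `mlp`, `vasculature` and `trace` as in
#'   [run_reservoir()].
#' @export
retrain_reservoir <- function(model, data, epochs, eta = 0.05, eta_v = 0.5,
                              gamma = 0.005, eval_every = 200) {
  stopifnot(inherits(data, "anvn_dataset"),
            inherits(model$mlp, "anvn_mlp"),
            inherits(model$vasculature, "anvn_vasculature"),
            !is.null(model$vasculature$source_weight))
  mlp <- model$mlp
  state <- model$vasculature
  source_energy <- state$source_energy
  N <- state$topology$n_leaves
  D <- one_hot(data$y_train, data$n_classes)
  rows <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    U0_now <- state$source_weight
    state <- propagate_energy(state, U0_now * source_energy)
    E <- leaf_energies(state)
    cache <- mlp_forward(mlp, data$X_train, leaf_energies = E)
    upd <- mlp_backward(mlp, cache, data$X_train, D, leaf_energies = E,
                        eta = eta, coupling = "reservoir", gamma = gamma)
    mlp <- apply_updates(mlp, upd)
    state <- backpropagate_energy(state, upd$dE, eta_v = eta_v)
    w_res <- 1 - state$source_weight
    u <- max(state$source_weight + eta_v * state$root_gradient, 0)
    state$source_weight <- u / (u + w_res)
    res_now <- source_energy * (1 - U0_now)
    if (ep %% eval_every == 0 || ep == epochs) {
      rows[[ep]] <- c(ep, sum(E), sum(E) / N,
                      accuracy(predict_class(cache$Y), data$y_train,
                               n_classes = data$n_classes),
                      evaluate_accuracy(mlp, data, leaf_energies = E),
                      res_now)
    } else {
      rows[[ep]] <- c(ep, sum(E), sum(E) / N, NA_real_, NA_real_, res_now)
    }
  }
  trace <- as.data.frame(do.call(rbind, c(rows, list(matrix(0, 0, 6)))))
  names(trace) <- c("epoch", "xi", "per_capita", "train_acc", "test_acc",
                    "reservoir")
  list(mlp = mlp, vasculature = state, trace = trace)
}

#' Steady-state summary of a training trace
#'
#' Averages a trace column over the final fraction of epochs (default the
#' last 5%), the window used to read off attractor settling points.
#'
#' @param trace A trace data frame with an `epoch` column.
#' @param column Column to summarize (default `"per_capita"`).
#' @param tail_frac Final fraction of epochs to average (default 0.05).
#' @return Scalar mean over the steady-state window.
#' @export
steady_state <- function(trace, column = "per_capita", tail_frac = 0.05) {
  stopifnot(is.data.frame(trace), column %in% names(trace))
  n <- nrow(trace)
  keep <- seq.int(max(1L, n - ceiling(tail_frac * n) + 1L), n)
  mean(trace[[column]][keep], na.rm = TRUE)
}

#' Write a training trace to CSV
#'
#' @param trace Trace data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
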