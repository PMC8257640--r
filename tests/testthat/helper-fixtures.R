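# small dataset reused across tests (generated once per session)
tiny_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_synthetic(n_train = 120, n_test = 60, n_classes = 10,
                               n_features = 64, noise_sd = 0.3, seed = 42)
    }
    cache
  }
})

# nearest-prototype classifier on the generator's true prototypes
prototype_predict <- function(data, X = data$X_test) {
  apply(X, 1, function(r) {
    which.min(colSums((t(data$prototypes) - r)^2)) - 1L
  })
}

# brute-force node count: repeated ceil-division from the leaf level up,
# independent of the closed form used by plan_tree
enumerate_nodes <- function(n_leaves, k) {
  count <- n_leaves
  m <- n_leaves
  while (m > 1) {
    m <- ceiling(m / k)
    count <- count + m
  }
  count
}

# central finite differences of the cost wrt every parameter and the leaf
# energies; returns the same structure as mlp_backward (update convention:
# delta = -eta * dC/dtheta)
numeric_updates <- function(mlp, X, D, E, eta = 1, lambda_w = 0,
                            lambda_E = 0, h = 1e-6) {
  # data term averaged over the batch (matching the batch-mean updates);
  # penalties enter once, not per sample
  cost_at <- function(m, En) {
    cache <- mlp_forward(m, X, leaf_energies = En)
    mlp_cost(cache$Y, D) / nrow(X) +
      mlp_cost(matrix(0, 1, 1), matrix(0, 1, 1), m, lambda_w = lambda_w,
               lambda_E = lambda_E, leaf_energies = En)
  }
  fd_mat <- function(field) {
    g <- mlp[[field]] * 0
    for (i in seq_along(g)) {
      mp <- mlp; mp[[field]][i] <- mp[[field]][i] + h
      mm <- mlp; mm[[field]][i] <- mm[[field]][i] - h
      g[i] <- (cost_at(mp, E) - cost_at(mm, E)) / (2 * h)
    }
    -eta * g
  }
  dE <- vapply(seq_along(E), function(j) {
    Ep <- E; Ep[j] <- Ep[j] + h
    Em <- E; Em[j] <- Em[j] - h
    (cost_at(mlp, Ep) - cost_at(mlp, Em)) / (2 * h)
  }, numeric(1))
  list(dW_s = fd_mat("W_s"), db_s = fd_mat("b_s"), dW_f = fd_mat("W_f"),
       dE = -eta * dE)
}

expect_rel_equal <- function(got, want, tol = 1e-4) {
  scale <- pmax(abs(want), 1e-6)
  expect_lt(max(abs(got - want) / scale), tol)
}
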