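test_that("bias-energy law is the saturating linear threshold rule", {
  expect_equal(bias_from_energy(c(0, 1, 2, 3)), c(1, 0, -1, -1))
  # continuity at the elbow
  expect_equal(bias_from_energy(2 - 1e-12), bias_from_energy(2 + 1e-12),
               tolerance = 1e-9)
  expect_error(bias_from_energy(-0.1), "nonnegative")
})

test_that("input-weight rows are absolute-normalized", {
  mlp <- init_mlp(2, 2, 1, seed = 1)
  mlp$W_f <- rbind(c(1, -1), c(3, 1))
  mlp <- normalize_input_weights(mlp)
  expect_equal(mlp$W_f, rbind(c(0.5, -0.5), c(0.75, 0.25)))
  expect_equal(normalize_input_weights(mlp)$W_f, mlp$W_f)
  mlp$W_f[1, ] <- 0
  expect_error(normalize_input_weights(mlp), "degenerate")
})

test_that("forward pass follows the printed subtractive-bias convention", {
  g <- function(z) 1 / (1 + exp(-z))
  mlp <- init_mlp(1, 1, 1, seed = 2, slope1 = 1, slope2 = 1)
  mlp$W_f[] <- 1; mlp$W_s[] <- 1; mlp$b_s[] <- 0
  # one-unit chain: y = g2(g1(x - b)) with b = 1 - E
  cache <- mlp_forward(mlp, 0.4, leaf_energies = 1)
  expect_equal(cache$Y[1, 1], g(g(0.4)))
  # zero input, E = 1 so b = 0: hidden activation is g1(0) = 0.5
  cache0 <- mlp_forward(mlp, 0, leaf_energies = 1)
  expect_equal(cache0$V[1, 1], 0.5)
  expect_equal(cache0$Y[1, 1], g(0.5))
  # E = 0 raises the bias to 1, shifting the hidden net input down by 1
  cache_low <- mlp_forward(mlp, 0, leaf_energies = 0)
  expect_equal(cache_low$Hf[1, 1], cache0$Hf[1, 1] - 1)
  expect_error(mlp_forward(mlp, c(1, 2)), "dimension")
  expect_error(mlp_forward(mlp, 0.4, leaf_energies = c(1, 1)),
               "one entry per hidden neuron")
})

test_that("hidden activation is monotone in delivered energy", {
  mlp <- init_mlp(3, 4, 2, seed = 5)
  x <- stats::runif(3)
  E_grid <- seq(0, 3, by = 0.25)
  V <- sapply(E_grid, function(E) {
    mlp_forward(mlp, x, leaf_energies = rep(E, 4))$V[1, ]
  })
  expect_true(all(diff(t(V)) >= 0))
  expect_true(all(diff(bias_from_energy(E_grid)) <= 0))
})

test_that("cost is the half squared error plus optional penalties", {
  expect_equal(mlp_cost(c(1, 0), c(1, 0)), 0)
  expect_equal(mlp_cost(c(0, 0), c(1, 0)), 0.5)
  mlp <- init_mlp(1, 1, 1, seed = 1)
  mlp$W_s[] <- 2; mlp$W_f[] <- 0
  expect_equal(mlp_cost(1, 1, mlp, lambda_w = 0.1), 0.2)
  expect_equal(mlp_cost(1, 1, lambda_E = 0.5, leaf_energies = c(1, 2)), 1.5)
})

test_that("class prediction uses the one-hot offset and lowest-index ties", {
  expect_equal(predict_class(c(0, 0, 0, 1, 0, 0, 0, 0, 0, 0)), 3L)
  expect_equal(predict_class(c(0.2, 0.7, 0.7, 0.1)), 1L)
  expect_equal(predict_class(rep(0.1, 10)), 0L)
})

test_that("updates vanish at a perfect fit and above the energy elbow", {
  mlp <- init_mlp(2, 3, 2, seed = 9)
  x <- c(0.3, 0.6)
  E <- c(0.5, 2.5, 1.0)
  cache <- mlp_forward(mlp, x, leaf_energies = E)
  upd <- mlp_backward(mlp, cache, x, cache$Y, leaf_energies = E)
  expect_equal(max(abs(upd$dW_s)), 0)
  expect_equal(max(abs(upd$dW_f)), 0)
  expect_equal(max(abs(upd$dE)), 0)
  # a saturated neuron sends no demand gradient even with a real error
  upd2 <- mlp_backward(mlp, cache, x, c(1, 0), leaf_energies = E)
  expect_equal(upd2$dE[2], 0)
  expect_false(upd2$dE[1] == 0)
})

test_that("analytic updates match central finite differences", {
  set.seed(31)
  configs <- list(
    list(lambda_w = 0, lambda_E = 0),
    list(lambda_w = 0.05, lambda_E = 0),
    list(lambda_w = 0, lambda_E = 0.03),
    list(lambda_w = 0.05, lambda_E = 0.03)
  )
  for (rep in 1:4) {
    n_in <- sample(1:3, 1); n_h <- sample(2:3, 1); n_out <- sample(1:2, 1)
    slope <- sample(c(1, 5), 1)
    mlp <- init_mlp(n_in, n_h, n_out, slope1 = slope)
    X <- matrix(stats::runif(2 * n_in), 2, n_in)
    D <- matrix(stats::runif(2 * n_out), 2, n_out)
    E <- stats::runif(n_h, 0.1, 2.6)
    for (cf in configs) {
      cache <- mlp_forward(mlp, X, leaf_energies = E)
      got <- mlp_backward(mlp, cache, X, D, leaf_energies = E, eta = 1,
                          lambda_w = cf$lambda_w, lambda_E = cf$lambda_E)
      want <- numeric_updates(mlp, X, D, E, eta = 1,
                              lambda_w = cf$lambda_w,
                              lambda_E = cf$lambda_E)
      expect_rel_equal(got$dW_s, want$dW_s)
      expect_rel_equal(got$db_s, want$db_s)
      expect_rel_equal(got$dW_f, want$dW_f)
      # exclude leaves within finite-difference reach of the elbow at 2
      ok <- abs(E - 2) > 1e-3
      expect_rel_equal(got$dE[ok], want$dE[ok])
    }
  }
})

test_that("a small full-batch step does not increase the cost", {
  for (seed in 1:5) {
    set.seed(seed)
    mlp <- init_mlp(5, 4, 3, seed = seed)
    X <- matrix(stats::runif(40), 8, 5)
    D <- matrix(stats::runif(24), 8, 3)
    c0 <- mlp_cost(mlp_forward(mlp, X)$Y, D)
    upd <- mlp_backward(mlp, mlp_forward(mlp, X), X, D, eta = 0.01)
    mlp2 <- mlp
    mlp2$W_s <- mlp2$W_s + upd$dW_s
    mlp2$b_s <- mlp2$b_s + upd$db_s
    mlp2$W_f <- mlp2$W_f + upd$dW_f
    mlp2$b_f <- mlp2$b_f + upd$db_f
    c1 <- mlp_cost(mlp_forward(mlp2, X)$Y, D)
    expect_lte(c1, c0)
  }
})

test_that("perceptron JSON checkpoints round-trip exactly", {
  mlp <- init_mlp(4, 3, 2, seed = 6, slope1 = 5)
  path <- withr::local_tempfile(fileext = ".json")
  mlp_to_json(mlp, path)
  back <- mlp_from_json(path)
  expect_identical(back$W_f, mlp$W_f)
  expect_identical(back$W_s, mlp$W_s)
  expect_identical(back$b_f, mlp$b_f)
  expect_identical(back$b_s, mlp$b_s)
  expect_equal(back$slope1, mlp$slope1)
})
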