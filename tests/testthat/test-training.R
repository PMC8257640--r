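test_that("untrained regime splits energy equally and reports conservation", {
  d <- tiny_data()
  fit <- train_mlp(d, 8, 50, seed = 1, eval_every = 50)
  top <- plan_tree(8, 2)
  tab <- run_untrained(fit$mlp, top, c(1, 8, 16), d)
  expect_equal(tab$xi, c(1, 8, 16))
  expect_equal(tab$per_capita, c(1, 8, 16) / 8)
  # E_s = 2N saturates every bias at -1; E_s = N puts every bias at 0
  expect_equal(bias_from_energy(rep(16 / 8, 8)), rep(-1, 8))
  expect_equal(bias_from_energy(rep(8 / 8, 8)), rep(0, 8))
  # efficiency is zero at the baseline energy
  expect_equal(tab$efficiency[1], 0)
})

test_that("standalone training reduces cost and reaches sane accuracy", {
  d <- tiny_data()
  fit <- train_mlp(d, 16, 800, seed = 2, eval_every = 200)
  expect_lt(tail(fit$trace$cost, 1), fit$trace$cost[1])
  expect_gt(tail(fit$trace$test_acc, 1), 50)
})

test_that("sequential training leaves matched biases untouched", {
  d <- tiny_data()
  top <- plan_tree(8, 2)
  st <- init_vasculature(top, seed = 3)
  st <- propagate_energy(st, 8)
  mlp <- init_mlp(64, 8, 10, seed = 3)
  mlp$b_f <- bias_from_energy(leaf_energies(st))  # demand already satisfied
  r <- run_sequential(mlp, st, 8, 5)
  expect_equal(r$vasculature$U, st$U)
  expect_equal(r$trace$bias_gap, rep(0, 5))
})

test_that("sequential training shrinks the bias mismatch monotonically", {
  d <- tiny_data()
  fit <- train_mlp(d, 8, 200, seed = 4, eval_every = 200)
  # ample energy: desired energy is sum(1 - b^T) <= 2N
  E_s <- sum(1 - fit$mlp$b_f)
  r <- run_sequential(fit$mlp, init_vasculature(plan_tree(8, 2), seed = 4),
                      E_s, 400)
  gap <- r$trace$bias_gap
  expect_lt(tail(gap, 1), 0.05 * gap[1])
  expect_lt(stats::cor(seq_along(gap), gap, method = "spearman"), -0.9)
})

test_that("simultaneous training consumes exactly the root energy", {
  d <- tiny_data()
  r <- run_simultaneous(plan_tree(8, 2), 6, 40, d, seed = 5,
                        eval_every = 40)
  expect_equal(r$trace$xi, rep(6, 40))
  expect_equal(nrow(r$trace), 40)
})

test_that("zero training epochs return the initialized parameters", {
  d <- tiny_data()
  r <- run_simultaneous(plan_tree(8, 2), 6, 0, d, seed = 6)
  set.seed(6)
  mlp0 <- init_mlp(64, 8, 10, slope1 = 5)
  st0 <- init_vasculature(plan_tree(8, 2))
  expect_equal(r$mlp$W_f, mlp0$W_f)
  expect_equal(r$mlp$W_s, mlp0$W_s)
  expect_equal(r$vasculature$U, st0$U)
  expect_equal(nrow(r$trace), 0)
})

test_that("simultaneous training beats the untrained split at equal energy", {
  d <- make_synthetic(seed = 21)
  top <- plan_tree(32, 4)
  E_s <- 64
  fit <- train_mlp(d, 32, 1500, seed = 21, eval_every = 1500)
  unt_acc <- run_untrained(fit$mlp, top, E_s, d)$accuracy
  sim <- run_simultaneous(top, E_s, 1500, d, seed = 21, eval_every = 1500)
  expect_gt(tail(sim$trace$test_acc, 1), unt_acc)
})

test_that("final performance is robust to the branching factor", {
  # seed-averaged final accuracy for trees of different depth agrees
  # within run-to-run noise at a fixed energy budget
  d <- tiny_data()
  means <- vapply(c(2, 4, 8), function(k) {
    mean(vapply(1:3, function(s) {
      r <- run_simultaneous(plan_tree(16, k), 16, 2000, d, seed = s,
                            eval_every = 2000)
      tail(r$trace$test_acc, 1)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(max(means) - min(means), 15)
  expect_gt(min(means), 50)
})

test_that("reservoir conserves source energy and tracks its split", {
  d <- tiny_data()
  r <- run_reservoir(plan_tree(8, 2), 0.6, 60, d, seed = 8, eval_every = 60)
  total <- r$trace$xi + r$trace$reservoir
  expect_true(all(abs(total - 5000) / 5000 < 1e-6))
  expect_true(r$vasculature$source_weight >= 0 &&
                r$vasculature$source_weight <= 1)
  # over-committed initialization is rejected
  expect_error(run_reservoir(plan_tree(8, 2), 700, 5, d),
               "source weight")
})

test_that("saturated leaves return energy at the excess-return slope", {
  mlp <- init_mlp(3, 3, 2, seed = 9)
  x <- stats::runif(3)
  E <- c(2.4, 1.0, 3.1)
  cache <- mlp_forward(mlp, x, leaf_energies = E)
  upd <- mlp_backward(mlp, cache, x, c(1, 0), leaf_energies = E,
                      coupling = "reservoir", gamma = 0.005)
  expect_equal(upd$dE[c(1, 3)], c(-0.005, -0.005))
  expect_false(upd$dE[2] == -0.005)
})

test_that("steady-state summary averages the trailing window", {
  tr <- data.frame(epoch = 1:100, per_capita = c(rep(1, 95), rep(0.5, 5)))
  expect_equal(steady_state(tr), 0.5)
  expect_equal(steady_state(tr, tail_frac = 0.10), 0.75)
})
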