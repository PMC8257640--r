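test_that("accuracy is percent correct with strict label validation", {
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(accuracy(rep(0, 200), c(rep(0, 160), rep(1, 40))), 80)
  expect_error(accuracy(integer(), integer()), "nonempty")
  expect_error(accuracy(c(1, 2), c(1)), "equal length")
  expect_error(accuracy(c(1, 2), c(1, 10)), "labels must be")
  expect_error(accuracy(c(1, 2), c(1, -1)), "labels must be")
})

test_that("efficiency is relative accuracy per unit energy", {
  expect_equal(efficiency(80, 18, 100), 0.62)
  expect_equal(efficiency(50, 50, 7), 0)
  expect_equal(efficiency(80, 18, 200), efficiency(80, 18, 100) / 2)
  expect_equal(efficiency(80, 18, 100, percent = FALSE), 0.0062)
  expect_error(efficiency(80, 18, 0), "positive")
  expect_error(efficiency(80, 18, -5), "positive")
})

test_that("energy deficit compares desired and delivered energy", {
  d <- energy_deficit(rep(0, 4), rep(1, 4))
  expect_equal(d$E_D, 4)
  expect_equal(d$E_A, 4)
  expect_equal(d$deficit, 0)
  d2 <- energy_deficit(rep(-1, 6), rep(0, 6))
  expect_equal(d2$deficit, 12)  # 2N at the saturated extreme
  expect_error(energy_deficit(1:3, 1:2), "equal length")
})

test_that("pearson correlation flags degenerate inputs", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson(c(1, 2, 3), c(-2, -4, -6)), -1)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson(c(1, 2), c(1, 2)), "length >= 3")
})

test_that("ablating a disconnected neuron changes nothing", {
  d <- tiny_data()
  mlp <- init_mlp(64, 5, 10, seed = 11)
  mlp$W_s[, 2] <- 0  # neuron 2 feeds nothing downstream
  E <- c(0.5, 1, 1.5, 0.8, 1.2)
  ab <- ablate_and_score(mlp, d$X_test, d$y_test, E)
  expect_equal(ab$table$delta_rmse[2], 0)
  expect_true(any(ab$table$delta_rmse[-2] != 0))
  expect_true(ab$eecc >= -1 && ab$eecc <= 1)
})

test_that("ablation scoring enforces its preconditions", {
  d <- tiny_data()
  small <- init_mlp(64, 2, 10, seed = 12)
  expect_error(ablate_and_score(small, d$X_test, d$y_test, c(1, 1)),
               "at least 3")
  # all-zero output weights: every ablation is a no-op, correlation
  # undefined and flagged rather than silently zero
  flat <- init_mlp(64, 4, 10, seed = 13)
  flat$W_s[] <- 0
  expect_error(ablate_and_score(flat, d$X_test, d$y_test, c(1, 1, 1, 2)),
               "zero variance")
})

test_that("ablation error matches a from-scratch forward pass", {
  d <- tiny_data()
  mlp <- init_mlp(64, 4, 10, seed = 14)
  E <- c(0.3, 0.9, 1.4, 1.9)
  ab <- ablate_and_score(mlp, d$X_test, d$y_test, E)
  # recompute neuron 3's ablated error by zeroing V directly
  cache <- mlp_forward(mlp, d$X_test, leaf_energies = E)
  V <- cache$V; V[, 3] <- 0
  Hs <- tcrossprod(V, mlp$W_s) - rep(mlp$b_s, each = nrow(V))
  Y <- 1 / (1 + exp(-Hs))
  D <- matrix(0, nrow(V), 10)
  D[cbind(seq_len(nrow(V)), d$y_test + 1L)] <- 1
  rmse3 <- mean(rowMeans((D - Y)^2))
  expect_equal(ab$table$delta_rmse[3], rmse3 - ab$rmse_control)
})

test_that("transfer drift sums squared differences per originating level", {
  top <- plan_tree(8, 2)
  a <- init_vasculature(top, seed = 15)
  b <- a
  dr0 <- transfer_drift(a, b)
  expect_equal(dr0$drift, rep(0, top$n_levels - 1))
  expect_equal(dr0$level, seq_len(top$n_levels - 1))
  # a single leaf-level edge difference of size d lands in the last level
  b$U[top$leaf_ids[1]] <- b$U[top$leaf_ids[1]] + 0.1
  dr <- transfer_drift(a, b)
  expect_equal(dr$drift[top$n_levels - 1], 0.1^2)
  expect_equal(dr$drift[-(top$n_levels - 1)], rep(0, top$n_levels - 2))
  expect_error(transfer_drift(a, init_vasculature(plan_tree(8, 4))),
               "same topology")
})

test_that("attractor spread summarizes steady states across traces", {
  mk <- function(v) data.frame(epoch = 1:40, per_capita = rep(v, 40))
  same <- attractor_spread(list(mk(0.7), mk(0.7), mk(0.7)))
  expect_equal(same$spread, 0)
  sp <- attractor_spread(list(mk(0.5), mk(0.7), mk(0.9)))
  expect_equal(sp$min, 0.5)
  expect_equal(sp$max, 0.9)
  expect_equal(sp$median, 0.7)
  expect_equal(sp$spread, 0.4)
  expect_error(attractor_spread(list(mk(1), mk(2))), "at least 3")
})

test_that("analysis statistics are pure functions of their inputs", {
  d <- tiny_data()
  mlp <- init_mlp(64, 4, 10, seed = 16)
  E <- c(0.5, 1, 1.5, 2)
  a1 <- ablate_and_score(mlp, d$X_test, d$y_test, E)
  a2 <- ablate_and_score(mlp, d$X_test, d$y_test, E)
  expect_identical(a1$eecc, a2$eecc)
  expect_identical(a1$table, a2$table)
})
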