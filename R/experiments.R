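#' Run a named experiment from a config
#'
#' Drives the scaled-down experiment grids: each run writes per-run trace
#' CSVs, a `summary.csv`, and a `manifest.json` recording the full config,
#' seed and package version, so the same spec and seed regenerate all
#' numbers. The config is a named list (or a YAML file path) with at least
#' `experiment` and `outdir`; grid fields default to small sizes that run
#' in minutes on one CPU.
#'
#' Experiments: `regime_compare` (efficiency curves of the untrained,
#' sequential and simultaneous regimes over a root-energy grid),
#' `branching_sweep` (simultaneous training across branching factors),
#' `deficit_sweep` (sequential energy deficit and accuracy over root
#' energies), `reservoir_size_sweep` (reservoir efficiency across hidden
#' sizes), `attractor_sweep` (reservoir trajectories across initial
#' per-capita energies), `transfer` (per-level weight drift after
#' retraining on a correlated dataset), `eecc_size` / `eecc_energy`
#' (energy-error correlation across sizes / root energies).
#'
#' @param spec Named list or path to a YAML config file.
#' @return The summary data frame, invisibly; files under `spec$outdir`.
#' @export
run_experiment <- function(spec) {
  if (is.character(spec) && length(spec) == 1L) {
    spec <- yaml::read_yaml(spec)
  }
  stopifnot(is.list(spec), !is.null(spec$experiment))
  defaults <- list(
    outdir = "anvn-results", seed = 1L, n_hidden = 32L, k = 4L,
    epochs = 500L, eta = 0.05, eta_v = 0.5, gamma = 0.005,
    n_train = 200L, n_test = 100L, n_features = 196L, n_classes = 10L,
    noise_sd = 1.0,
    E_s = NULL, N_grid = NULL, k_grid = NULL, per_capita = NULL
  )
  cfg <- utils::modifyList(defaults, spec)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  data <- make_synthetic(cfg$n_train, cfg$n_test, cfg$n_classes,
                         cfg$n_features, cfg$noise_sd, seed = cfg$seed)
  summary_df <- switch(
    cfg$experiment,
    regime_compare = exp_regime_compare(cfg, data),
    branching_sweep = exp_branching_sweep(cfg, data),
    deficit_sweep = exp_deficit_sweep(cfg, data),
    reservoir_size_sweep = exp_reservoir_size_sweep(cfg, data),
    attractor_sweep = exp_attractor_sweep(cfg, data),
    transfer = exp_transfer(cfg, data),
    eecc_size = exp_eecc_size(cfg, data),
    eecc_energy = exp_eecc_energy(cfg, data),
    stop("unknown experiment: ", cfg$experiment, call. = FALSE)
  )
  utils::write.csv(summary_df, file.path(cfg$outdir, "summary.csv"),
                   row.names = FALSE)
  manifest <- list(
    experiment = cfg$experiment, config = cfg, seed = cfg$seed,
    package_version = as.character(utils::packageVersion("anvn"))
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"),
             file.path(cfg$outdir, "manifest.json"))
  invisible(summary_df)
}

exp_regime_compare <- function(cfg, data) {
  E_grid <- cfg$E_s %||% c(1, cfg$n_hidden / 2, cfg$n_hidden,
                           2 * cfg$n_hidden)
  top <- plan_tree(cfg$n_hidden, cfg$k)
  fit <- train_mlp(data, cfg$n_hidden, cfg$epochs, eta = cfg$eta,
                   seed = cfg$seed)
  unt <- run_untrained(fit$mlp, top, E_grid, data)
  rows <- list(cbind(regime = "untrained", unt[c("E_s", "xi", "accuracy",
                                                 "efficiency")]))
  for (regime in c("sequential", "simultaneous")) {
    acc <- vapply(E_grid, function(E_s) {
      if (regime == "sequential") {
        r <- run_sequential(fit$mlp, init_vasculature(top, seed = cfg$seed),
                            E_s, cfg$epochs, eta_v = cfg$eta_v)
        evaluate_accuracy(fit$mlp, data,
                          leaf_energies = leaf_energies(
                            propagate_energy(r$vasculature, E_s)))
      } else {
        r <- run_simultaneous(top, E_s, cfg$epochs, data, eta = cfg$eta,
                              eta_v = cfg$eta_v, seed = cfg$seed,
                              eval_every = cfg$epochs)
        write_trace_csv(r$trace,
                        file.path(cfg$outdir,
                                  sprintf("trace_%s_Es%g.csv", regime, E_s)))
        utils::tail(r$trace$test_acc[!is.na(r$trace$test_acc)], 1)
      }
    }, numeric(1))
    base <- if (any(E_grid == 1)) acc[which(E_grid == 1)[1]] else
      acc[which.min(E_grid)]
    psi <- efficiency(acc, base, E_grid)
    rows[[length(rows) + 1L]] <-
      data.frame(regime = regime, E_s = E_grid, xi = E_grid,
                 accuracy = acc, efficiency = psi)
  }
  do.call(rbind, rows)
}

exp_branching_sweep <- function(cfg, data) {
  ks <- cfg$k_grid %||% c(2, 4, 8)
  E_s <- (cfg$E_s %||% cfg$n_hidden)[1]
  do.call(rbind, lapply(ks, function(k) {
    r <- run_simultaneous(plan_tree(cfg$n_hidden, k), E_s, cfg$epochs,
                          data, eta = cfg$eta, eta_v = cfg$eta_v,
                          seed = cfg$seed, eval_every = cfg$epochs)
    write_trace_csv(r$trace, file.path(cfg$outdir,
                                       sprintf("trace_k%d.csv", k)))
    data.frame(k = k, E_s = E_s, xi = utils::tail(r$trace$xi, 1),
               test_acc = utils::tail(
                 r$trace$test_acc[!is.na(r$trace$test_acc)], 1))
  }))
}

exp_deficit_sweep <- function(cfg, data) {
  E_grid <- cfg$E_s %||% cfg$n_hidden * c(0.25, 0.5, 1, 1.5, 2, 3)
  top <- plan_tree(cfg$n_hidden, cfg$k)
  fit <- train_mlp(data, cfg$n_hidden, cfg$epochs, eta = cfg$eta,
                   seed = cfg$seed)
  do.call(rbind, lapply(E_grid, function(E_s) {
    r <- run_sequential(fit$mlp, init_vasculature(top, seed = cfg$seed),
                        E_s, cfg$epochs, eta_v = cfg$eta_v)
    st <- propagate_energy(r$vasculature, E_s)
    d <- energy_deficit(fit$mlp$b_f, leaf_energies(st))
    data.frame(E_s = E_s, deficit = d$deficit,
               accuracy = evaluate_accuracy(fit$mlp, data,
                                            leaf_energies =
                                              leaf_energies(st)))
  }))
}

exp_reservoir_size_sweep <- function(cfg, data) {
  Ns <- cfg$N_grid %||% c(16, 24, 32, 48, 64)
  pc <- (cfg$per_capita %||% 0.6)[1]
  rows <- lapply(Ns, function(N) {
    r <- run_reservoir(plan_tree(N, min(cfg$k, N)), pc, cfg$epochs, data,
                       eta = cfg$eta, eta_v = cfg$eta_v, gamma = cfg$gamma,
                       seed = cfg$seed, eval_every = cfg$epochs)
    write_trace_csv(r$trace, file.path(cfg$outdir,
                                       sprintf("trace_N%d.csv", N)))
    data.frame(N = N, xi = utils::tail(r$trace$xi, 1),
               per_capita = utils::tail(r$trace$per_capita, 1),
               test_acc = utils::tail(
                 r$trace$test_acc[!is.na(r$trace$test_acc)], 1))
  })
  out <- do.call(rbind, rows)
  out$efficiency <- efficiency(out$test_acc, out$test_acc[1], out$xi)
  out
}

exp_attractor_sweep <- function(cfg, data) {
  pcs <- cfg$per_capita %||% c(0.2, 0.6, 1.0)
  top <- plan_tree(cfg$n_hidden, cfg$k)
  traces <- lapply(pcs, function(pc) {
    r <- run_reservoir(top, pc, cfg$epochs, data, eta = cfg$eta,
                       eta_v = cfg$eta_v, gamma = cfg$gamma,
                       seed = cfg$seed, eval_every = cfg$epochs)
    write_trace_csv(r$trace,
                    file.path(cfg$outdir,
                              sprintf("trajectory_pc%g.csv", pc)))
    r$trace
  })
  sp <- attractor_spread(traces)
  data.frame(N = cfg$n_hidden, median = sp$median, min = sp$min,
             max = sp$max, spread = sp$spread)
}

exp_transfer <- function(cfg, data) {
  top <- plan_tree(cfg$n_hidden, cfg$k)
  pc <- (cfg$per_capita %||% 0.6)[1]
  a <- run_reservoir(top, pc, cfg$epochs, data, eta = cfg$eta,
                     eta_v = cfg$eta_v, gamma = cfg$gamma, seed = cfg$seed,
                     eval_every = cfg$epochs)
  data_b <- make_transfer_variant(data, seed = cfg$seed + 1L)
  b <- retrain_reservoir(a, data_b, cfg$epochs, eta = cfg$eta,
                         eta_v = cfg$eta_v, gamma = cfg$gamma,
                         eval_every = cfg$epochs)
  transfer_drift(a$vasculature, b$vasculature)
}

exp_eecc_size <- function(cfg, data) {
  Ns <- cfg$N_grid %||% c(16, 32, 64)
  pc <- (cfg$per_capita %||% 0.6)[1]
  do.call(rbind, lapply(Ns, function(N) {
    r <- run_reservoir(plan_tree(N, min(cfg$k, N)), pc, cfg$epochs, data,
                       eta = cfg$eta, eta_v = cfg$eta_v, gamma = cfg$gamma,
                       seed = cfg$seed, eval_every = cfg$epochs)
    E <- leaf_energies(r$vasculature)
    ab <- ablate_and_score(r$mlp, data$X_test, data$y_test, E,
                           n_classes = data$n_classes)
    data.frame(N = N, eecc = ab$eecc)
  }))
}

exp_eecc_energy <- function(cfg, data) {
  E_grid <- cfg$E_s %||% cfg$n_hidden * c(0.5, 1, 2)
  top <- plan_tree(cfg$n_hidden, cfg$k)
  do.call(rbind, lapply(E_grid, function(E_s) {
    r <- run_simultaneous(top, E_s, cfg$epochs, data, eta = cfg$eta,
                          eta_v = cfg$eta_v, seed = cfg$seed,
                          eval_every = cfg$epochs)
    E <- leaf_energies(r$vasculature)
    ab <- ablate_and_score(r$mlp, data$X_test, data$y_test, E,
                           n_classes = data$n_classes)
    data.frame(E_s = E_s, eecc = ab$eecc)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
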