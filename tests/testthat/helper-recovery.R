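# Recovery harness: a feasible 6-reaction ground truth with clamped and
# irreversible features, two experimental conditions, Gaussian observation
# noise, and a perturbed starting model (log-parameters offset by N(0, 0.3),
# i.e. the order-of-magnitude prior knowledge typical for rate constants).

recovery_fixture <- function() {
  base_net <- make_random_network(n_species = 4, n_reactions = 6,
                                  fraction_clamped = 0.25,
                                  fraction_irreversible = 1 / 6, seed = 103)
  rep0 <- default_reparam(base_net)
  truth <- sample_feasible_params(base_net, rep0, scale = 0.4, seed = 1)
  dyn <- base_net$species$id[!base_net$species$clamped]
  flipped <- stats::setNames(
    rev(truth$species$initial_concentration[!truth$species$clamped]), dyn)
  designs <- list(
    experiment_design("e1", seq(0.25, 4, 0.75), dyn),
    experiment_design("e2", seq(0.25, 4, 0.75), dyn, initial_overrides = flipped)
  )
  list(truth = truth, designs = designs, noise_sd = 0.05)
}

recovery_run <- function(fx, seed, no_thermo = FALSE) {
  dat <- generate_data(fx$truth, fx$designs, noise_sd = fx$noise_sd, seed = seed)
  kref <- log_parameters(fx$truth)
  set.seed(1000 + seed)
  pert <- kref + ifelse(is.na(kref), 0, stats::rnorm(length(kref), 0, 0.3))
  start <- apply_log_parameters(fx$truth, pert)
  res <- calibrate(start, dat, fx$designs, no_thermo = no_thermo,
                   cfg = sa_config(iterations = 250, restarts = 2, seed = seed,
                                   proposal_scale = 0.2,
                                   initial_temperature = 0.5))
  list(result = res, rmse = sqrt(res$final_cost / nrow(dat)), data = dat)
}
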