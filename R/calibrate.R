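#' Simulated-annealing configuration
#'
#' @param initial_temperature starting Metropolis temperature (cost units).
#' @param cooling geometric cooling factor per iteration, in (0, 1).
#' @param proposal_scale standard deviation of the isotropic Gaussian step
#'   in the reduced coordinates `v`.
#' @param iterations Metropolis iterations per restart.
#' @param restarts number of annealing restarts; each restart re-heats from
#'   the best point found so far and the overall best is returned.
#' @param seed integer RNG seed; identical config + seed reproduces the run.
#' @return an `sa_config` object.
#' @export
sa_config <- function(initial_temperature = 1, cooling = 0.995,
                      proposal_scale = 0.1, iterations = 500,
                      restarts = 5, seed = 1L) {
  stopifnot(initial_temperature > 0, cooling > 0, cooling < 1,
            proposal_scale > 0, iterations >= 0, restarts >= 1)
  structure(list(initial_temperature = initial_temperature, cooling = cooling,
                 proposal_scale = proposal_scale, iterations = as.integer(iterations),
                 restarts = as.integer(restarts), seed = as.integer(seed)),
            class = "sa_config")
}

#' Least-squares fit cost
#'
#' Sum over experiments, observed species and observation times of squared
#' differences between measured and simulated concentrations, optionally
#' weighted per point.  This is the maximum-likelihood cost under i.i.d.
#' Gaussian observation error.  A failed integration yields an infinite
#' cost (with the cause attached as an attribute) rather than an error, so
#' stochastic optimizers can reject such proposals and move on.
#'
#' @param network a `reaction_network` carrying the parameters to evaluate.
#' @param data tidy measurement tibble: `experiment_id`, `time`,
#'   `species_id`, `value`, optional `weight`.
#' @param designs list of [experiment_design()] objects covering every
#'   experiment id in `data`.
#' @param ... passed to [simulate_network()] (solver tolerances).
#' @return a single number (possibly `Inf`).
#' @export
calibration_cost <- function(network, data, designs, ...) {
  stopifnot(all(c("experiment_id", "time", "species_id", "value") %in% names(data)))
  design_ids <- vapply(designs, function(d) d$experiment_id, character(1))
  total <- 0
  for (eid in unique(data$experiment_id)) {
    d <- designs[[match(eid, design_ids)]]
    if (is.null(d)) stop("no design for experiment '", eid, "'", call. = FALSE)
    traj <- tryCatch(
      suppressWarnings(simulate_network(network, design = d, ...)),
      error = function(e) e
    )
    if (inherits(traj, "error")) {
      out <- Inf
      attr(out, "failure") <- conditionMessage(traj)
      return(out)
    }
    obs <- data[data$experiment_id == eid, ]
    sim <- dplyr::inner_join(
      obs, dplyr::rename(traj, sim = "concentration"),
      by = c("experiment_id", "time", "species_id")
    )
    if (nrow(sim) != nrow(obs))
      stop("observations at times/species absent from the simulation grid",
           call. = FALSE)
    w <- if ("weight" %in% names(sim)) sim$weight else 1
    total <- total + sum(w * (sim$value - sim$sim)^2)
  }
  total
}

#' Reduced cost over the feasible manifold
#'
#' The fit cost as a function of the reduced coordinates `v`:
#' `reduced_cost(v) = calibration_cost(kappa0 + B v)`.  Every evaluation is
#' at a feasible parameter vector by construction.
#'
#' @param v length-d numeric vector.
#' @param network,data,designs as in [calibration_cost()].
#' @param rep a [reparameterization()].
#' @param ... passed to [calibration_cost()].
#' @return a single number (possibly `Inf`).
#' @export
reduced_cost <- function(v, network, data, designs, rep, ...) {
  calibration_cost(apply_log_parameters(network, to_kappa(v, rep)),
                   data, designs, ...)
}

#' Simulated annealing minimizer
#'
#' Metropolis search with Gaussian proposals and geometric cooling: a
#' proposal `v' = v + N(0, s_t^2 I)` is accepted with probability
#' `min(1, exp(-(C(v') - C(v)) / T))`, `T` shrinking by the cooling factor
#' each iteration.  The proposal width is annealed with the temperature,
#' `s_t = proposal_scale * sqrt(T / T_0)`, so the search takes large
#' exploratory steps while hot and refines locally when cold.  Restarts
#' re-heat from the best point seen.  The best visited point is returned,
#' with the best-so-far cost trace.
#'
#' @param objective function of a length-d numeric vector returning a cost
#'   (may return `Inf`).
#' @param v_init starting point; the objective must be finite here.
#' @param cfg an [sa_config()].
#' @return list with `v_hat`, `cost` (best), `cost_trace` (best-so-far per
#'   iteration, nonincreasing), `n_evaluations`.
#' @export
simulated_annealing <- function(objective, v_init, cfg = sa_config()) {
  stopifnot(inherits(cfg, "sa_config"))
  d <- length(v_init)
  c0 <- objective(v_init)
  if (!is.finite(c0)) stop("objective not finite at the starting point", call. = FALSE)
  best_v <- v_init; best_c <- c0
  trace <- numeric(0)
  n_eval <- 1L
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(cfg$seed)
  for (r in seq_len(cfg$restarts)) {
    v <- best_v; cc <- best_c
    temp <- cfg$initial_temperature
    for (it in seq_len(cfg$iterations)) {
      step <- cfg$proposal_scale * sqrt(temp / cfg$initial_temperature)
      prop <- v + stats::rnorm(d, 0, step)
      cp <- objective(prop)
      n_eval <- n_eval + 1L
      if (is.finite(cp) && (cp < cc || stats::runif(1) < exp(-(cp - cc) / temp))) {
        v <- prop; cc <- cp
        if (cc < best_c) { best_c <- cc; best_v <- v }
      }
      temp <- temp * cfg$cooling
      trace <- c(trace, best_c)
    }
  }
  list(v_hat = best_v, cost = best_c, cost_trace = trace, n_evaluations = n_eval)
}

#' Thermodynamically consistent model calibration
#'
#' The full pipeline: prune the open network to its closed subsystem,
#' extract the reaction-cycle basis, assemble the Wegscheider constraints
#' together with any extra log-linear constraints, reparameterize the
#' feasible manifold as `kappa0 + B v`, and minimise the least-squares fit
#' cost over `v` by simulated annealing.  Every parameter vector visited
#' during the search satisfies all constraints, so the returned model is
#' thermodynamically feasible by construction.
#'
#' With `no_thermo = TRUE` the Wegscheider rows are omitted (extra
#' constraints and zero-fixing are kept): this is the unconstrained
#' "collective fitting" comparator, and its result is audited against the
#' true cycle basis so infeasibility is flagged in the report.
#'
#' @param network a `reaction_network` whose current parameter values serve
#'   as the reference (`kappa_ref`) unless overridden.
#' @param data tidy measurement tibble (see [calibration_cost()]).
#' @param designs list of [experiment_design()] objects.
#' @param extra list of [log_linear_constraint()] objects.
#' @param annotations a [pruning_annotations()] object.
#' @param cfg an [sa_config()].
#' @param kappa_ref optional named log-parameter reference vector.
#' @param no_thermo omit the thermodynamic constraint block (ablation mode).
#' @param volume system volume forwarded to the entropy audit.
#' @param ... solver options passed through to [simulate_network()].
#' @return a `calibration_result`: calibrated network and `kappa_hat`,
#'   initial/final costs, cost trace, the audit of the result, and the
#'   pipeline objects (`closed`, `basis`, `constraints`, `reparam`).
#' @export
calibrate <- function(network, data, designs, extra = list(),
                      annotations = pruning_annotations(),
                      cfg = sa_config(), kappa_ref = NULL,
                      no_thermo = FALSE, volume = 1, ...) {
  closed <- prune_to_closed(network, annotations)
  basis <- cycle_basis(closed)
  used_basis <- if (no_thermo) empty_basis(closed) else basis
  cs <- assemble_constraints(used_basis, network, extra)
  fc <- feasibility_check(cs)
  if (fc$status == "infeasible")
    stop("constraint system is infeasible; conflicting rows: ",
         paste(conflicting_rows(cs), collapse = ", "), call. = FALSE)
  if (is.null(kappa_ref)) kappa_ref <- log_parameters(network)
  rep <- reparameterization(cs, kappa_ref)

  v0 <- numeric(rep$d)
  objective <- function(v) reduced_cost(v, network, data, designs, rep, ...)
  initial_cost <- objective(v0)
  if (fc$status == "unique" || rep$d == 0L || cfg$iterations == 0L) {
    sa <- list(v_hat = v0, cost = initial_cost, cost_trace = numeric(0),
               n_evaluations = 1L)
  } else {
    sa <- simulated_annealing(objective, v0, cfg)
  }
  kappa_hat <- to_kappa(sa$v_hat, rep)
  net_hat <- apply_log_parameters(network, kappa_hat)
  audit <- if (basis$M2 > 0L)
    entropy_production_audit(basis, net_hat, volume = volume)
  else
    entropy_production_audit(basis, net_hat, volume = volume)[0, ]

  structure(
    list(network = net_hat, kappa_hat = kappa_hat, v_hat = sa$v_hat,
         initial_cost = initial_cost, final_cost = sa$cost,
         cost_trace = sa$cost_trace, n_evaluations = sa$n_evaluations,
         audit = audit, feasible = all(audit$satisfied),
         closed = closed, basis = basis, constraints = cs, reparam = rep,
         feasibility = fc, no_thermo = no_thermo, seed = cfg$seed),
    class = "calibration_result"
  )
}

empty_basis <- function(closed) {
  structure(list(vectors = matrix(0, length(closed$reaction_ids), 0),
                 rank_M1 = NA_integer_, M2 = 0L,
                 reaction_ids = closed$reaction_ids),
            class = "cycle_basis")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>", if (x$no_thermo) " (ablation: no thermodynamic constraints)",
      "\n", sep = "")
  cat("  d = ", x$reparam$d, " free directions over J = ",
      length(x$reparam$param_ids), " parameters\n", sep = "")
  cat("  cost: ", format(x$initial_cost, digits = 6), " -> ",
      format(x$final_cost, digits = 6), "\n", sep = "")
  cat("  thermodynamically feasible: ",
      if (nrow(x$audit) == 0L) "trivially (no cycles)" else x$feasible, "\n", sep = "")
  invisible(x)
}
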