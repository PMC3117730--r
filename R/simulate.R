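#' Experiment design
#'
#' Describes one experimental condition: initial-concentration overrides,
#' clamped-concentration overrides, the observation time grid and which
#' species are observed.
#'
#' @param experiment_id identifier used to join designs with data.
#' @param observation_times strictly increasing nonnegative times.
#' @param observed_species ids of the measured species.
#' @param initial_overrides named numeric vector overriding the network's
#'   initial concentrations for this experiment.
#' @param clamp_overrides named numeric vector overriding the held
#'   concentration of clamped species.
#' @return an `experiment_design` object.
#' @export
experiment_design <- function(experiment_id, observation_times, observed_species,
                              initial_overrides = numeric(0),
                              clamp_overrides = numeric(0)) {
  stopifnot(all(diff(observation_times) > 0), all(observation_times >= 0))
  structure(
    list(experiment_id = as.character(experiment_id),
         observation_times = as.numeric(observation_times),
         observed_species = as.character(observed_species),
         initial_overrides = initial_overrides,
         clamp_overrides = clamp_overrides),
    class = "experiment_design"
  )
}

# Evaluate the modulation factor f(x, pi) at a state; 1 for mass action.
eval_modulation <- function(f_expr, state, pi) {
  if (is.null(f_expr)) return(1)
  env <- list2env(as.list(c(state, pi)), parent = baseenv())
  val <- eval(f_expr, env)
  if (!is.finite(val) || val <= 0)
    stop("modulation factor nonpositive or nonfinite at state", call. = FALSE)
  val
}

#' Forward/reverse flux split of reactions at a state
#'
#' Generalized mass-action fluxes: `J+ = kf * f(x) * prod(x^nu)` and
#' `J- = kr * f(x) * prod(x^nu')`; the net flux is `J+ - J-`.  Irreversible
#' reactions have `J- = 0`.
#'
#' @param network a `reaction_network`.
#' @param state named numeric vector of nonnegative concentrations covering
#'   every species the requested reactions touch.
#' @param reaction_ids subset of reactions (default all).
#' @return tibble with columns `reaction_id`, `forward`, `backward`, `net`.
#' @export
net_flux <- function(network, state, reaction_ids = NULL) {
  if (is.null(reaction_ids)) reaction_ids <- network$reactions$id
  check_ids(reaction_ids, network$reactions$id, "reaction")
  rx <- network$reactions
  idx <- match(reaction_ids, rx$id)
  fwd <- numeric(length(idx)); bwd <- numeric(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    if (!is.null(rx$rate_expr[[i]])) {
      # raw rate law: only the net flux is defined
      env <- list2env(as.list(c(state, rx$pi[[i]])), parent = baseenv())
      fwd[j] <- eval(rx$rate_expr[[i]], env)
      bwd[j] <- 0
      next
    }
    f <- eval_modulation(
      rx$f_expr[[i]], state,
      c(rx$pi[[i]], stats::setNames(c(rx$kf[i], rx$kr[i]),
                                    paste0(rx$id[i], c("_kf", "_kr")))))
    nu <- rx$reactants[[i]]; nup <- rx$products[[i]]
    fwd[j] <- rx$kf[i] * f * prod(state[names(nu)]^nu)
    bwd[j] <- if (rx$reversible[i]) rx$kr[i] * f * prod(state[names(nup)]^nup) else 0
  }
  tibble::tibble(reaction_id = reaction_ids, forward = fwd, backward = bwd,
                 net = fwd - bwd)
}

reaction_fluxes <- net_flux

# Precompiled net-flux evaluator: index-based numeric computation with no
# per-call data-frame construction, so the ODE right-hand side stays cheap
# inside optimization loops.  Returns function(x) -> numeric vector of net
# fluxes in reaction-table order; x must be ordered as the species table.
compile_fluxes <- function(network) {
  rx <- network$reactions
  sp_ids <- network$species$id
  M <- nrow(rx)
  ri <- lapply(rx$reactants, function(s) match(names(s), sp_ids))
  rs <- lapply(rx$reactants, as.numeric)
  pi_ <- lapply(rx$products, function(s) match(names(s), sp_ids))
  ps <- lapply(rx$products, as.numeric)
  kf <- rx$kf; kr <- rx$kr; rev <- rx$reversible
  has_f <- !vapply(rx$f_expr, is.null, logical(1))
  has_raw <- !vapply(rx$rate_expr, is.null, logical(1))
  extra <- lapply(seq_len(M), function(i)
    c(rx$pi[[i]], stats::setNames(c(rx$kf[i], rx$kr[i]),
                                  paste0(rx$id[i], c("_kf", "_kr")))))
  function(x) {
    phi <- numeric(M)
    for (i in seq_len(M)) {
      if (has_raw[i]) {
        env <- list2env(as.list(c(stats::setNames(x, sp_ids), rx$pi[[i]])),
                        parent = baseenv())
        phi[i] <- eval(rx$rate_expr[[i]], env)
        next
      }
      fwd <- kf[i] * prod(x[ri[[i]]]^rs[[i]])
      bwd <- if (rev[i]) kr[i] * prod(x[pi_[[i]]]^ps[[i]]) else 0
      if (has_f[i]) {
        f <- eval_modulation(rx$f_expr[[i]], stats::setNames(x, sp_ids), extra[[i]])
        fwd <- fwd * f; bwd <- bwd * f
      }
      phi[i] <- fwd - bwd
    }
    phi
  }
}

#' Simulate the reaction-rate ODEs of a network
#'
#' Integrates `dx_n/dt = sum_m S[n, m] * phi_m(x)` with generalized
#' mass-action net fluxes, holding clamped species exactly constant (their
#' rows of the right-hand side are zeroed, so clamping is enforced rather
#' than integrated).  Uses a stiff-capable adaptive integrator
#' ([deSolve::lsoda]), appropriate for signalling-cascade models whose rate
#' constants span many orders of magnitude.
#'
#' @param network a `reaction_network`.
#' @param times output time grid (first entry is the initial time), or
#'   `NULL` to use the design's observation times augmented with 0.
#' @param design optional [experiment_design()] supplying initial/clamp
#'   overrides.
#' @param rtol,atol relative/absolute solver tolerances.
#' @param negative_tol concentrations below `-negative_tol` abort the run
#'   (no silent clipping; small negative solver noise within the tolerance
#'   is truncated to zero).
#' @return a tidy trajectory tibble: `experiment_id`, `time`, `species_id`,
#'   `concentration`.
#' @export
simulate_network <- function(network, times = NULL, design = NULL,
                             rtol = 1e-8, atol = 1e-12, negative_tol = 1e-8) {
  sp <- network$species
  x0 <- stats::setNames(sp$initial_concentration, sp$id)
  clamped <- stats::setNames(sp$clamped, sp$id)
  exp_id <- "default"
  if (!is.null(design)) {
    stopifnot(inherits(design, "experiment_design"))
    exp_id <- design$experiment_id
    if (length(design$initial_overrides) > 0L) {
      check_ids(names(design$initial_overrides), sp$id, "species")
      x0[names(design$initial_overrides)] <- design$initial_overrides
    }
    if (length(design$clamp_overrides) > 0L) {
      check_ids(names(design$clamp_overrides), sp$id, "species")
      x0[names(design$clamp_overrides)] <- design$clamp_overrides
    }
    if (is.null(times)) times <- union(0, design$observation_times)
  }
  stopifnot(!is.null(times), length(times) >= 2L)
  times <- sort(as.numeric(times))

  S <- stoichiometry_matrix(network)
  dyn <- !clamped[rownames(S)]
  flux_fn <- compile_fluxes(network)

  rhs <- function(t, x, parms) {
    dx <- as.numeric(S %*% flux_fn(x))
    dx[!dyn] <- 0
    list(dx)
  }

  sol <- deSolve::lsoda(y = x0, times = times, func = rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed; last time reached: ", max(sol[, "time"]),
         call. = FALSE)
  m <- as.matrix(sol)
  conc <- m[, sp$id, drop = FALSE]
  if (min(conc) < -negative_tol)
    stop("negative concentration excursion beyond tolerance (min = ",
         signif(min(conc), 3), ")", call. = FALSE)
  conc[conc < 0] <- 0
  # clamped species exactly constant, by construction of the RHS
  if (any(clamped)) {
    cl_ids <- sp$id[clamped[sp$id]]
    conc[, cl_ids] <- matrix(x0[cl_ids], nrow(conc), length(cl_ids), byrow = TRUE)
  }

  tibble::tibble(
    experiment_id = exp_id,
    time = rep(m[, "time"], times = ncol(conc)),
    species_id = rep(colnames(conc), each = nrow(conc)),
    concentration = as.numeric(conc)
  )
}

#' Integrated response of a species
#'
#' Trapezoidal time-integral of one species' concentration trace over the
#' trajectory window (units: concentration x time).  Used as a cumulative
#' activity summary, e.g. integrated ERK-PP response across input doses.
#'
#' @param traj a trajectory tibble from [simulate_network()].
#' @param species_id the species to integrate.
#' @return a single number.
#' @export
integrated_response <- function(traj, species_id) {
  tr <- traj[traj$species_id == species_id, ]
  if (nrow(tr) == 0L) stop("species not present in trajectory", call. = FALSE)
  tr <- tr[order(tr$time), ]
  if (nrow(tr) < 2L) stop("trajectory has fewer than two time points", call. = FALSE)
  sum(diff(tr$time) * (utils::head(tr$concentration, -1) +
                         utils::tail(tr$concentration, -1)) / 2)
}

#' Per-reaction detailed-balance check at a state
#'
#' At chemical equilibrium of a closed feasible system every reversible
#' reaction is individually balanced (`J+ = J-`), not merely stationary in
#' the aggregate.  Infeasible parameter sets can instead reach a stationary
#' state carrying a persistent circulating flux around a cycle.  This
#' reports the flux split and relative imbalance per reversible reaction.
#'
#' @param network a `reaction_network`.
#' @param state named concentration vector.
#' @param reaction_ids reactions to check (default: all reversible ones).
#' @param tol relative-imbalance threshold for calling a reaction balanced.
#' @return tibble `reaction_id`, `forward`, `backward`, `imbalance`
#'   (relative), `balanced`; the `all_balanced` attribute summarises.
#' @export
detailed_balance_check <- function(network, state, reaction_ids = NULL, tol = 1e-8) {
  if (is.null(reaction_ids))
    reaction_ids <- network$reactions$id[network$reactions$reversible]
  fl <- net_flux(network, state, reaction_ids)
  denom <- pmax(fl$forward, fl$backward, .Machine$double.xmin)
  out <- dplyr::mutate(fl,
                       imbalance = abs(.data$forward - .data$backward) / denom,
                       balanced = .data$imbalance <= tol)
  attr(out, "all_balanced") <- all(out$balanced)
  out
}
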