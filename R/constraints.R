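# Physical constants as printed to the precision used throughout:
# Avogadro number (1/mol) and Boltzmann constant (J/K).
AVOGADRO <- 6.02214084e23
BOLTZMANN <- 1.3806504e-23

#' Reaction-cycle basis of a closed subsystem
#'
#' A reaction cycle is a set of reactions whose net fluxes, set equal to the
#' components of a null vector of the closed stoichiometry matrix, leave all
#' concentrations unchanged.  The number of independent cycles is
#' `M2 = M0 - rank(N)`; both the rank and a basis of the null space are
#' computed in exact rational arithmetic, so `N %*% b == 0` holds exactly
#' (not merely to tolerance) and the cycle count is a discrete invariant of
#' the network.
#'
#' The basis is canonical: derived from the reduced row echelon form with
#' unit free-variable assignment, rescaled to integer vectors with gcd 1 and
#' first nonzero entry positive, so identical inputs give identical bases.
#'
#' @param closed a `closed_subsystem` from [prune_to_closed()].
#' @return a `cycle_basis` object: integer matrix `vectors` (M0 x M2, one
#'   column per cycle), `rank_M1`, `M2`, and the reaction id ordering.
#' @export
cycle_basis <- function(closed) {
  stopifnot(inherits(closed, "closed_subsystem"))
  m0 <- length(closed$reaction_ids)
  if (m0 == 0L) {
    return(structure(list(vectors = matrix(0, 0, 0), rank_M1 = 0L, M2 = 0L,
                          reaction_ids = character(0)), class = "cycle_basis"))
  }
  B <- rational_nullspace(closed$stoich)
  rk <- m0 - ncol(B)
  rownames(B) <- closed$reaction_ids
  structure(
    list(vectors = B, rank_M1 = as.integer(rk), M2 = ncol(B),
         reaction_ids = closed$reaction_ids),
    class = "cycle_basis"
  )
}

#' @export
print.cycle_basis <- function(x, ...) {
  cat("<cycle_basis> M0 = ", length(x$reaction_ids), ", rank M1 = ", x$rank_M1,
      ", independent cycles M2 = ", x$M2, "\n", sep = "")
  invisible(x)
}

# forward/reverse rate constants of the named reactions, with domain checks
closed_rates <- function(network, reaction_ids) {
  pt <- network$parameters
  kf <- pt$value[match(paste0(reaction_ids, "_kf"), pt$id)]
  kr <- pt$value[match(paste0(reaction_ids, "_kr"), pt$id)]
  bad <- reaction_ids[!(kf > 0) | !(kr > 0) | is.na(kf) | is.na(kr)]
  if (length(bad) > 0L)
    stop("nonpositive rate constant in closed-subsystem reaction(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  list(kf = kf, kr = kr)
}

#' Wegscheider condition residuals
#'
#' For every basis cycle `b`, detailed balance requires the product of
#' equilibrium constants around the cycle to equal one; on the log scale,
#' `sum_m b_m * (log kf_m - log kr_m) = 0`.  This evaluates that sum per
#' cycle; the parameter set is thermodynamically feasible for the closed
#' subsystem if and only if every residual is zero.
#'
#' @param basis a [cycle_basis()].
#' @param network the `reaction_network` carrying the rate constants.
#' @return numeric vector of length M2 (one residual per cycle).
#' @export
wegscheider_residuals <- function(basis, network) {
  stopifnot(inherits(basis, "cycle_basis"))
  if (basis$M2 == 0L) return(numeric(0))
  r <- closed_rates(network, basis$reaction_ids)
  z <- log(r$kf) - log(r$kr)
  as.numeric(crossprod(basis$vectors, z))
}

#' Entropy-production audit of reaction cycles
#'
#' The entropy production rate associated with driving the closed subsystem
#' so that reaction net fluxes equal a cycle vector `b` is
#' `sigma(b) = A * V * kB * sum_m b_m * log(J+_m / J-_m)`; because
#' `N %*% b = 0` the state-dependent terms cancel and the sum reduces to the
#' Wegscheider residual of the cycle.  The second law requires
#' `sigma(b) >= 0` with equality exactly at thermodynamic equilibrium, so a
#' cycle with a negative entry here certifies that the parameter set is
#' physically impossible (a "chemical perpetuum mobile"), while `sigma = 0`
#' for all cycles is equivalent to the Wegscheider conditions.
#'
#' @param basis a [cycle_basis()].
#' @param network the `reaction_network` carrying the rate constants.
#' @param volume system volume (m^3) used in the prefactor.
#' @param tol zero-classification tolerance on the log-residual scale;
#'   residuals with `|residual| <= tol` count as satisfied.
#' @return tibble with one row per cycle: `cycle`, `residual` (log scale),
#'   `sigma` (J K^-1 s^-1 per unit cycle flux), `sign`
#'   (`"negative"`/`"zero"`/`"positive"`), and `satisfied`.
#' @export
entropy_production_audit <- function(basis, network, volume = 1, tol = 1e-9) {
  stopifnot(volume > 0)
  res <- wegscheider_residuals(basis, network)
  sigma <- AVOGADRO * volume * BOLTZMANN * res
  tibble::tibble(
    cycle = seq_along(res),
    residual = res,
    sigma = sigma,
    sign = dplyr::case_when(
      abs(res) <= tol ~ "zero",
      res < 0 ~ "negative",
      TRUE ~ "positive"
    ),
    satisfied = abs(res) <= tol
  )
}

#' Define one log-linear parameter constraint
#'
#' Additional (non-thermodynamic) constraints are linear in the logarithms
#' of the kinetic parameters: measured equilibrium constants
#' (`log kf - log kr = log R`), Haldane relations between the parameters of
#' a reversible enzymatic mechanism, individually measured parameters
#' (`log k_j = log k_meas`), ties that share one value across reactions, and
#' parameters fixed to exactly zero (which live outside log space and are
#' handled by elimination, never as `-Inf`).
#'
#' @param kind one of `"equilibrium_constant"`, `"haldane"`, `"fixed_value"`,
#'   `"tie"`.
#' @param coefficients named numeric vector: coefficient per parameter id on
#'   the log scale.
#' @param rhs right-hand side on the log scale, or the string `"zero"`
#'   (allowed only with `kind = "fixed_value"` and a single unit coefficient)
#'   to fix the parameter's value to exactly 0.
#' @return a `log_linear_constraint` object.
#' @export
log_linear_constraint <- function(kind, coefficients, rhs = 0) {
  kind <- match.arg(kind, c("equilibrium_constant", "haldane", "fixed_value", "tie"))
  stopifnot(!is.null(names(coefficients)), any(coefficients != 0))
  fixed_to_zero <- identical(rhs, "zero")
  if (fixed_to_zero) {
    if (kind != "fixed_value" || length(coefficients) != 1L)
      stop('rhs = "zero" requires kind = "fixed_value" with one coefficient',
           call. = FALSE)
  } else {
    stopifnot(is.numeric(rhs), length(rhs) == 1L, is.finite(rhs))
  }
  structure(
    list(kind = kind, coefficients = coefficients,
         rhs = if (fixed_to_zero) NA_real_ else as.numeric(rhs),
         fixed_to_zero = fixed_to_zero),
    class = "log_linear_constraint"
  )
}

#' Assemble the full log-linear constraint system
#'
#' Stacks the Wegscheider cycle constraints (first) and any extra log-linear
#' constraints into a single system `A %*% kappa = c` over the network's
#' global parameter ordering.  Parameters fixed to exactly zero -- reverse
#' rates of irreversible reactions plus any `fixed_value`/`"zero"`
#' constraints -- are eliminated before the log transform: their columns are
#' excluded from the effective system and recorded in `zero_fixed_params`.
#' A row that places a nonzero coefficient on a zero-fixed parameter cannot
#' be satisfied by any finite log value and is reported as contradictory.
#'
#' @param basis a [cycle_basis()] (possibly with `M2 = 0`).
#' @param network the `reaction_network` (supplies the parameter ordering).
#' @param extra list of [log_linear_constraint()] objects.
#' @return a `constraint_system`: matrix `A` (L x J, zero-fixed columns
#'   identically 0), vector `c` (length L), `zero_fixed_params`,
#'   `free_params` (ids of the J_eff effective columns), and a
#'   `row_provenance` tibble (`row`, `kind`, `contradictory`).
#' @export
assemble_constraints <- function(basis, network, extra = list()) {
  pt <- network$parameters
  ids <- pt$id
  J <- length(ids)

  zero_fixed <- pt$id[pt$fixed_zero | pt$value == 0]
  for (cn in extra) {
    stopifnot(inherits(cn, "log_linear_constraint"))
    check_ids(names(cn$coefficients), ids, "parameter")
    if (cn$fixed_to_zero) zero_fixed <- union(zero_fixed, names(cn$coefficients))
  }

  rows <- list(); rhs <- numeric(0); kinds <- character(0)
  if (basis$M2 > 0L) {
    for (i in seq_len(basis$M2)) {
      b <- basis$vectors[, i]
      coef <- numeric(J); names(coef) <- ids
      coef[paste0(basis$reaction_ids, "_kf")] <- b
      coef[paste0(basis$reaction_ids, "_kr")] <- -b
      rows[[length(rows) + 1L]] <- coef
      rhs <- c(rhs, 0)
      kinds <- c(kinds, "wegscheider")
    }
  }
  for (cn in extra) {
    if (cn$fixed_to_zero) next  # handled by elimination, not by a row
    coef <- numeric(J); names(coef) <- ids
    coef[names(cn$coefficients)] <- cn$coefficients
    rows[[length(rows) + 1L]] <- coef
    rhs <- c(rhs, cn$rhs)
    kinds <- c(kinds, cn$kind)
  }

  A <- if (length(rows) > 0L) do.call(rbind, rows) else
    matrix(0, 0, J, dimnames = list(NULL, ids))
  colnames(A) <- ids

  contradictory <- rep(FALSE, nrow(A))
  if (length(zero_fixed) > 0L && nrow(A) > 0L) {
    contradictory <- apply(A[, zero_fixed, drop = FALSE] != 0, 1L, any)
    A[, zero_fixed] <- 0
  }

  structure(
    list(A = A, c = rhs,
         zero_fixed_params = zero_fixed,
         free_params = setdiff(ids, zero_fixed),
         param_ids = ids,
         row_provenance = tibble::tibble(
           row = seq_len(nrow(A)), kind = kinds, contradictory = contradictory)),
    class = "constraint_system"
  )
}

#' @export
print.constraint_system <- function(x, ...) {
  cat("<constraint_system> L = ", nrow(x$A), " rows x J = ", ncol(x$A),
      " parameters (", length(x$free_params), " effective, ",
      length(x$zero_fixed_params), " fixed to zero)\n", sep = "")
  if (any(x$row_provenance$contradictory))
    cat("  ", sum(x$row_provenance$contradictory),
        " contradictory row(s) referencing zero-fixed parameters\n", sep = "")
  invisible(x)
}

#' Cycle flux residuals along a trajectory
#'
#' For feasible parameters the identity
#' `sum_m b_m * log(J+_m(t) / J-_m(t)) = 0` holds for every cycle `b` at
#' every time point, arbitrarily far from equilibrium, because the
#' state-dependent parts cancel over the cycle.  The residual therefore
#' equals the cycle's Wegscheider residual at any strictly positive state --
#' evaluating it on simulated (or even arbitrary) states is a dynamic audit
#' of thermodynamic feasibility.
#'
#' @param traj a trajectory tibble from [simulate_network()] (columns
#'   `time`, `species_id`, `concentration`), or any tibble of positive
#'   states in that shape.
#' @param basis a [cycle_basis()].
#' @param network the `reaction_network`.
#' @return tibble with columns `cycle`, `time`, `residual`.  Time points at
#'   which any cycle-member flux vanishes are excluded and recorded in the
#'   `excluded_times` attribute.
#' @export
flux_cycle_residuals <- function(traj, basis, network) {
  stopifnot(inherits(basis, "cycle_basis"))
  times <- sort(unique(traj$time))
  out <- vector("list", length(times))
  excluded <- numeric(0)
  for (ti in seq_along(times)) {
    st <- traj[traj$time == times[ti], ]
    state <- stats::setNames(st$concentration, st$species_id)
    fl <- reaction_fluxes(network, state, basis$reaction_ids)
    if (any(fl$forward <= 0 | fl$backward <= 0)) {
      excluded <- c(excluded, times[ti])
      next
    }
    lr <- log(fl$forward / fl$backward)
    out[[ti]] <- tibble::tibble(
      cycle = seq_len(basis$M2),
      time = times[ti],
      residual = as.numeric(crossprod(basis$vectors, lr))
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "excluded_times") <- excluded
  res
}
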