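#' Three-species reaction triangle
#'
#' The minimal network with a reaction cycle: `A <-> B`, `B <-> C`,
#' `C <-> A`, plain mass action, six rate constants, one independent cycle
#' (`M2 = 1`).  With all rates equal the parameters are thermodynamically
#' feasible; the classic infeasible variant scales one forward rate so the
#' product of equilibrium constants around the loop differs from one.
#'
#' @param kf,kr length-3 forward/reverse rate constants for (A->B, B->C,
#'   C->A).
#' @param initial length-3 initial concentrations of (A, B, C).
#' @return a `reaction_network`.
#' @export
make_triangle <- function(kf = c(1, 1, 1), kr = c(1, 1, 1),
                          initial = c(2, 1, 0.5)) {
  stopifnot(length(kf) == 3L, length(kr) == 3L, length(initial) == 3L)
  sp <- species_table(c("A", "B", "C"), initial_concentration = initial)
  rx <- dplyr::bind_rows(
    reaction("r1", c(A = 1), c(B = 1), kf = kf[1], kr = kr[1]),
    reaction("r2", c(B = 1), c(C = 1), kf = kf[2], kr = kr[2]),
    reaction("r3", c(C = 1), c(A = 1), kf = kf[3], kr = kr[3])
  )
  reaction_network(sp, rx)
}

#' Seeded random mass-action fixture network
#'
#' Builds a connected mass-action network for exercising the whole pipeline:
#' a reversible ring backbone through all species (so cycles are possible),
#' plus random extra uni/bimolecular reactions.  A fraction of reactions is
#' then made irreversible and a fraction of species clamped, and optionally
#' a null-species exchange (source) reaction is appended, so that every
#' pruning rule can fire.  Structure and rate constants are reproducible
#' from the seed; the true cycle count of the pruned subsystem is attached
#' as the `M2` attribute.
#'
#' @param n_species number of species (>= 3).
#' @param n_reactions total reactions before the optional exchange reaction;
#'   at least `n_species` (the backbone ring).
#' @param fraction_clamped,fraction_irreversible fractions in `[0, 1]`.
#' @param n_null_exchange number of irreversible source reactions appended.
#' @param seed integer seed.
#' @return a `reaction_network` with attribute `M2`.
#' @export
make_random_network <- function(n_species = 5, n_reactions = 6,
                                fraction_clamped = 0.2,
                                fraction_irreversible = 0.2,
                                n_null_exchange = 0, seed = 1L) {
  stopifnot(n_species >= 3, n_reactions >= n_species,
            fraction_clamped >= 0, fraction_clamped <= 1,
            fraction_irreversible >= 0, fraction_irreversible <= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  ids <- sprintf("X%d", seq_len(n_species))
  rates <- function() exp(stats::rnorm(1, 0, 0.5))
  rows <- list()
  # ring backbone: guarantees connectivity and a potential cycle
  for (i in seq_len(n_species)) {
    j <- if (i == n_species) 1L else i + 1L
    rows[[i]] <- reaction(sprintf("r%d", i), stats::setNames(1, ids[i]),
                          stats::setNames(1, ids[j]), kf = rates(), kr = rates())
  }
  # random extra reactions (uni- or bimolecular on each side)
  side_key <- function(re, pr)
    paste(paste(sort(re), collapse = "+"), "->", paste(sort(pr), collapse = "+"))
  for (m in seq_len(n_reactions - n_species)) {
    repeat {
      nr <- sample(1:2, 1); np <- sample(1:2, 1)
      re <- sample(ids, nr); pr <- sample(setdiff(ids, re), np)
      if (!side_key(re, pr) %in% vapply(rows, function(r)
        side_key(names(r$reactants[[1]]), names(r$products[[1]])),
        character(1))) break
    }
    rows[[length(rows) + 1L]] <- reaction(
      sprintf("r%d", n_species + m),
      stats::setNames(rep(1, nr), re), stats::setNames(rep(1, np), pr),
      kf = rates(), kr = rates())
  }
  rx <- dplyr::bind_rows(rows)

  n_irr <- round(fraction_irreversible * nrow(rx))
  if (n_irr > 0L) {
    irr <- sample(nrow(rx), n_irr)
    rx$reversible[irr] <- FALSE
    rx$kr[irr] <- NA_real_
  }
  if (n_null_exchange > 0L) {
    for (q in seq_len(n_null_exchange)) {
      rx <- dplyr::bind_rows(rx, reaction(
        sprintf("rin%d", q), stats::setNames(numeric(0), character(0)),
        stats::setNames(1, ids[q]), reversible = FALSE, kf = rates()))
    }
  }

  clamped <- rep(FALSE, n_species)
  n_cl <- round(fraction_clamped * n_species)
  if (n_cl > 0L) clamped[sample(n_species, n_cl)] <- TRUE
  sp <- species_table(ids, initial_concentration = stats::runif(n_species, 0.5, 2),
                      clamped = clamped)
  net <- reaction_network(sp, rx)
  attr(net, "M2") <- cycle_basis(prune_to_closed(net))$M2
  net
}

#' Sample thermodynamically feasible parameters
#'
#' Draws `v ~ N(0, scale^2 I)` in the reduced coordinates and maps it
#' through the reparameterization, so every draw satisfies all constraints
#' by construction (`scale = 0` returns the particular solution itself).
#'
#' @param network a `reaction_network`.
#' @param rep a [reparameterization()] for this network's constraints.
#' @param scale standard deviation of the draw in `v`-space (log units).
#' @param seed integer seed.
#' @return the network with its parameter table replaced by the draw.
#' @export
sample_feasible_params <- function(network, rep, scale = 0.5, seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  v <- stats::rnorm(rep$d, 0, scale)
  apply_log_parameters(network, to_kappa(v, rep))
}

#' Generate noisy synthetic measurements
#'
#' Simulates each experiment and adds i.i.d. Gaussian noise at the
#' observation points -- the same observation model whose likelihood the
#' least-squares cost maximises.  Noisy values are truncated at zero
#' (concentrations are nonnegative); the pre-truncation value is kept in
#' `value_raw`.
#'
#' @param network a `reaction_network` (the ground truth).
#' @param designs list of [experiment_design()] objects.
#' @param noise_sd observation noise standard deviation.
#' @param seed integer seed.
#' @param ... solver options for [simulate_network()].
#' @return tidy tibble `experiment_id`, `time`, `species_id`, `value`,
#'   `value_raw`.
#' @export
generate_data <- function(network, designs, noise_sd = 0.05, seed = 1L, ...) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  out <- lapply(designs, function(d) {
    traj <- simulate_network(network, design = d, ...)
    obs <- traj[traj$species_id %in% d$observed_species &
                  traj$time %in% d$observation_times, ]
    raw <- obs$concentration + stats::rnorm(nrow(obs), 0, noise_sd)
    tibble::tibble(experiment_id = d$experiment_id, time = obs$time,
                   species_id = obs$species_id,
                   value = pmax(raw, 0), value_raw = raw)
  })
  dplyr::bind_rows(out)
}
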