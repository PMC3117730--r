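# Shared fixtures and independent oracles used across the suite.

# A triangle with unequal rates whose loop product of equilibrium constants
# is exactly one (feasible by construction).
feasible_triangle <- function() {
  kf <- c(1.5, 0.8, 1.2)
  kr <- c(0.9, 1.1, (1.5 * 0.8 * 1.2) / (0.9 * 1.1))
  make_triangle(kf = kf, kr = kr)
}

# Infeasible triangle: one forward rate scaled so the loop residual is log(2).
infeasible_triangle <- function() make_triangle(kf = c(2, 1, 1))

triangle_designs <- function(tmax = 3) {
  list(
    experiment_design("e1", seq(0.2, tmax, by = 0.4), c("A", "B", "C")),
    experiment_design("e2", seq(0.2, tmax, by = 0.4), c("A", "B", "C"),
                      initial_overrides = c(A = 0.5, B = 2, C = 1))
  )
}

# Independent brute-force cycle oracle: enumerate every integer vector with
# entries in [-3, 3] over the closed subsystem's reactions and keep those in
# the null space of the stoichiometry matrix (exact integer arithmetic via
# doubles).  The number of independent cycles is the rank of the found set,
# computed by QR -- a fully separate path from the package's rational
# elimination.
brute_force_cycles <- function(stoich) {
  m <- ncol(stoich)
  if (m == 0L) return(list(M2 = 0L, vectors = matrix(0, 0, 0)))
  grids <- rep(list(-3:3), m)
  V <- as.matrix(do.call(expand.grid, grids))
  keep <- rowSums(abs(V %*% t(stoich))) == 0 & rowSums(abs(V)) > 0
  V <- V[keep, , drop = FALSE]
  M2 <- if (nrow(V) == 0L) 0L else qr(t(V))$rank
  list(M2 = M2, vectors = t(V))
}

# A small connected fixture whose pruned subsystem has at least one cycle.
cyclic_random_network <- function(seed) {
  n_sp <- 3 + seed %% 3
  make_random_network(n_species = n_sp,
                      n_reactions = min(6, n_sp + seed %% 3),
                      fraction_clamped = 0.25,
                      fraction_irreversible = 0.2,
                      n_null_exchange = seed %% 2,
                      seed = seed)
}

# Reparameterization of a network under its Wegscheider constraints alone.
default_reparam <- function(network) {
  cl <- prune_to_closed(network)
  cb <- cycle_basis(cl)
  cs <- assemble_constraints(cb, network)
  reparameterization(cs, log_parameters(network))
}

expect_tibble_cols <- function(x, cols) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(cols %in% names(x)))
}
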