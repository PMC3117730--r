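test_that("cost is the sum of squared residuals over observed points", {
  net <- make_triangle()
  # single observed point: simulate to get x, then shift y to make residual 2
  d <- experiment_design("e1", 1, "A")
  traj <- simulate_network(net, design = d)
  x1 <- traj$concentration[traj$time == 1 & traj$species_id == "A"]
  dat <- tibble::tibble(experiment_id = "e1", time = 1, species_id = "A",
                        value = x1 + 2)
  expect_equal(calibration_cost(net, dat, list(d)), 4, tolerance = 1e-6)
  # doubling all residuals quadruples the cost
  dat2 <- dat
  dat2$value <- x1 + 4
  expect_equal(calibration_cost(net, dat2, list(d)) /
                 calibration_cost(net, dat, list(d)), 4, tolerance = 1e-6)
  # per-point weights scale linearly
  dat$weight <- 0.5
  expect_equal(calibration_cost(net, dat, list(d)), 2, tolerance = 1e-6)
})

test_that("noise-free self-fit cost is at the solver noise floor", {
  net <- feasible_triangle()
  des <- triangle_designs()
  dat <- generate_data(net, des, noise_sd = 0, seed = 1)
  expect_lt(calibration_cost(net, dat, des), 1e-10)
})

test_that("a failed integration yields an infinite-cost sentinel, not an error", {
  sp <- species_table(c("A", "B"), c(1, 1))
  # second-order autocatalysis dx/dt = x^2: finite-time blow-up before t = 5
  net <- reaction_network(sp, reaction("r1", c(A = 2), c(A = 3), kf = 1,
                                       reversible = FALSE))
  d <- experiment_design("e1", c(5, 10), "A")
  dat <- tibble::tibble(experiment_id = "e1", time = c(5, 10),
                        species_id = "A", value = c(1, 1))
  cost <- calibration_cost(net, dat, list(d))
  expect_true(is.infinite(cost))
  expect_false(is.null(attr(cost, "failure")))
})

test_that("reduced cost equals cost composed with the affine map", {
  net <- feasible_triangle()
  des <- triangle_designs()
  dat <- generate_data(net, des, noise_sd = 0.05, seed = 2)
  rep_ <- default_reparam(net)
  expect_equal(reduced_cost(numeric(rep_$d), net, dat, des, rep_),
               calibration_cost(apply_log_parameters(net, rep_$kappa0), dat, des))
  set.seed(3)
  for (i in 1:20) {
    v <- rnorm(rep_$d, 0, 0.3)
    expect_equal(reduced_cost(v, net, dat, des, rep_),
                 calibration_cost(apply_log_parameters(net, to_kappa(v, rep_)),
                                  dat, des))
  }
})

test_that("simulated annealing solves a convex quadratic and respects its budget", {
  target <- c(1, 2, -1, 0.5, 0)
  obj <- function(v) sum((v - target)^2)
  res <- simulated_annealing(obj, rep(0, 5),
                             sa_config(iterations = 800, restarts = 3, seed = 7,
                                       proposal_scale = 0.3, cooling = 0.99))
  expect_lt(res$cost, 1e-3)
  expect_true(all(diff(res$cost_trace) <= 0))      # best-so-far nonincreasing
  # zero iterations returns the start unchanged
  res0 <- simulated_annealing(obj, rep(0, 5), sa_config(iterations = 0))
  expect_identical(res0$v_hat, rep(0, 5))
})

test_that("simulated annealing escapes local minima on a rugged 2-d surface", {
  # Rastrigin-like: global minimum 0 at the origin, many local basins
  obj <- function(v) sum(v^2) + 3 * sum(1 - cos(2 * pi * v))
  hits <- 0L
  for (seed in 1:50) {
    res <- simulated_annealing(obj, c(2.1, -1.9),
                               sa_config(iterations = 800, restarts = 3,
                                         seed = seed, proposal_scale = 0.7,
                                         cooling = 0.993,
                                         initial_temperature = 5))
    if (sum(res$v_hat^2) < 0.25) hits <- hits + 1L
  }
  expect_gte(hits, 40L)   # reaches the global basin in >= 80% of runs
})

test_that("annealing is reproducible from the seed", {
  obj <- function(v) sum((v - 1)^2) + 0.1 * sin(10 * sum(v))
  r1 <- simulated_annealing(obj, c(0, 0), sa_config(iterations = 200, seed = 5))
  r2 <- simulated_annealing(obj, c(0, 0), sa_config(iterations = 200, seed = 5))
  expect_identical(r1$v_hat, r2$v_hat)
  expect_identical(r1$cost_trace, r2$cost_trace)
})

test_that("calibration recovers triangle dynamics below the noise floor", {
  truth <- feasible_triangle()
  des <- triangle_designs()
  dat <- generate_data(truth, des, noise_sd = 0.05, seed = 3)
  start <- make_triangle()    # all rates 1: wrong but feasible
  res <- calibrate(start, dat, des,
                   cfg = sa_config(iterations = 250, restarts = 2, seed = 11,
                                   proposal_scale = 0.15,
                                   initial_temperature = 0.5))
  noise_floor <- 0.05^2 * nrow(dat)
  expect_lt(res$final_cost, 2 * noise_floor)
  expect_lte(res$final_cost, res$initial_cost)
  expect_true(res$feasible)
  cb <- cycle_basis(prune_to_closed(truth))
  expect_lt(max(abs(wegscheider_residuals(cb, res$network))), 1e-9)
  g <- glance(res)
  expect_equal(g$d, 5)
  expect_identical(g$feasible, TRUE)
  td <- tidy(res)
  expect_tibble_cols(td, c("id", "reference", "estimate", "log_shift"))
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("the ablation arm fits but is flagged thermodynamically infeasible", {
  truth <- infeasible_triangle()    # ground truth violates the cycle condition
  des <- triangle_designs()
  dat <- generate_data(truth, des, noise_sd = 0.02, seed = 4)
  start <- make_triangle()
  res <- calibrate(start, dat, des, no_thermo = TRUE,
                   cfg = sa_config(iterations = 250, restarts = 2, seed = 11,
                                   proposal_scale = 0.15,
                                   initial_temperature = 0.5))
  expect_equal(res$reparam$d, 6)    # no Wegscheider row removed a dimension
  expect_false(res$feasible)        # audit against the true basis flags it
  expect_gt(max(abs(res$audit$residual)), 0.1)
})

test_that("every annealing iterate stays on the feasible manifold", {
  net <- feasible_triangle()
  des <- triangle_designs()
  dat <- generate_data(net, des, noise_sd = 0.05, seed = 6)
  rep_ <- default_reparam(net)
  cb <- cycle_basis(prune_to_closed(net))
  seen <- new.env(); seen$max_resid <- 0
  obj <- function(v) {
    n <- apply_log_parameters(net, to_kappa(v, rep_))
    seen$max_resid <- max(seen$max_resid, abs(wegscheider_residuals(cb, n)))
    reduced_cost(v, net, dat, des, rep_)
  }
  simulated_annealing(obj, numeric(rep_$d),
                      sa_config(iterations = 50, restarts = 1, seed = 8))
  expect_lt(seen$max_resid, 1e-9)
})
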