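test_that("triangle has one cycle spanning (1,1,1)", {
  cb <- cycle_basis(prune_to_closed(make_triangle()))
  expect_equal(cb$M2, 1)
  expect_equal(cb$rank_M1, 2)
  expect_equal(unname(cb$vectors[, 1]), c(1, 1, 1))
  expect_true(all(prune_to_closed(make_triangle())$stoich %*% cb$vectors == 0))
})

test_that("two uncoupled reactions have no cycles", {
  sp <- species_table(c("A", "B", "C", "D"))
  rx <- dplyr::bind_rows(reaction("r1", c(A = 1), c(B = 1)),
                         reaction("r2", c(C = 1), c(D = 1)))
  cb <- cycle_basis(prune_to_closed(reaction_network(sp, rx)))
  expect_equal(cb$M2, 0)
  expect_length(wegscheider_residuals(cb, reaction_network(sp, rx)), 0)
})

test_that("Wegscheider residuals evaluate the cycle log-equilibrium sum", {
  net1 <- make_triangle()                          # all rates 1
  cb <- cycle_basis(prune_to_closed(net1))
  expect_equal(wegscheider_residuals(cb, net1), 0)
  net2 <- infeasible_triangle()                    # forward (2,1,1), reverse 1s
  expect_equal(wegscheider_residuals(cb, net2), log(2))
  expect_equal(wegscheider_residuals(cb, feasible_triangle()), 0, tolerance = 1e-12)
})

test_that("nonpositive closed-subsystem rates raise a domain error naming the reaction", {
  net <- make_triangle()
  net$reactions$kr[2] <- 0
  net <- reaction_network(net$species, net$reactions, net$compartments)
  cb <- cycle_basis(prune_to_closed(net))
  expect_error(wegscheider_residuals(cb, net), "r2")
})

test_that("entropy production is zero iff the cycle condition holds, with sign semantics", {
  cb <- cycle_basis(prune_to_closed(make_triangle()))
  aud_feas <- entropy_production_audit(cb, feasible_triangle())
  expect_true(all(aud_feas$sign == "zero"))
  expect_true(all(abs(aud_feas$sigma) <= 6.02214084e23 * 1.3806504e-23 * 1e-9))

  up <- entropy_production_audit(cb, make_triangle(kf = c(2, 1, 1)))
  down <- entropy_production_audit(cb, make_triangle(kr = c(2, 1, 1)))
  expect_identical(up$sign, "positive")
  expect_identical(down$sign, "negative")     # sign flips under fwd/rev swap
  expect_equal(up$sigma, -down$sigma)
  expect_equal(up$sigma, 6.02214084e23 * 1.3806504e-23 * log(2))
  # volume scales the prefactor linearly
  expect_equal(entropy_production_audit(cb, make_triangle(kf = c(2, 1, 1)),
                                        volume = 2)$sigma, 2 * up$sigma)
})

test_that("feasibility verdict is invariant to the choice of null-space basis", {
  set.seed(11)
  for (seed in 1:10) {
    net <- cyclic_random_network(seed)
    cl <- prune_to_closed(net)
    cb <- cycle_basis(cl)
    if (cb$M2 == 0) next
    rep <- default_reparam(net)
    net_f <- sample_feasible_params(net, rep, scale = 0.7, seed = seed)
    # randomized integer recombination of the basis is still a basis
    U <- matrix(sample(-2:2, cb$M2^2, replace = TRUE), cb$M2)
    while (abs(det(U)) < 0.5) U <- matrix(sample(-2:2, cb$M2^2, replace = TRUE), cb$M2)
    cb2 <- cb
    cb2$vectors <- cb$vectors %*% U
    r1 <- wegscheider_residuals(cb, net_f)
    r2 <- wegscheider_residuals(cb2, net_f)
    expect_lt(max(abs(r1)), 1e-9)
    expect_lt(max(abs(r2)), 1e-9)
    # and an infeasible verdict transfers too
    r1i <- wegscheider_residuals(cb, net)
    r2i <- wegscheider_residuals(cb2, net)
    expect_equal(max(abs(r1i)) > 1e-9, max(abs(r2i)) > 1e-9)
  }
})

test_that("triangle constraint system is the alternating +/- row over six parameters", {
  net <- make_triangle()
  cb <- cycle_basis(prune_to_closed(net))
  cs <- assemble_constraints(cb, net)
  expect_equal(dim(cs$A), c(1, 6))
  expect_equal(unname(cs$A[1, ]), c(1, -1, 1, -1, 1, -1))
  expect_equal(cs$c, 0)
  expect_identical(cs$row_provenance$kind, "wegscheider")
})

test_that("extra constraints append after the Wegscheider block; unit rows for fixed values", {
  net <- make_triangle()
  cb <- cycle_basis(prune_to_closed(net))
  fix <- log_linear_constraint("fixed_value", c(r2_kf = 1), rhs = 0.5)
  eq <- log_linear_constraint("equilibrium_constant", c(r1_kf = 1, r1_kr = -1),
                              rhs = log(3))
  cs <- assemble_constraints(cb, net, extra = list(fix, eq))
  expect_equal(dim(cs$A), c(3, 6))
  expect_identical(cs$row_provenance$kind,
                   c("wegscheider", "fixed_value", "equilibrium_constant"))
  expect_equal(unname(cs$A[2, ]), c(0, 0, 1, 0, 0, 0))   # e_j row
  expect_equal(cs$c, c(0, 0.5, log(3)))
})

test_that("zero-fixed parameters are eliminated, and rows needing them are contradictory", {
  sp <- species_table(c("A", "B"))
  rx <- dplyr::bind_rows(reaction("r1", c(A = 1), c(B = 1)),
                         reaction("deg", c(B = 1), c(A = 1), reversible = FALSE,
                                  kf = 0.2))
  net <- reaction_network(sp, rx)
  cb <- cycle_basis(prune_to_closed(net))
  tie <- log_linear_constraint("tie", c(r1_kf = 1, deg_kr = -1), rhs = 0)
  cs <- assemble_constraints(cb, net, extra = list(tie))
  expect_true("deg_kr" %in% cs$zero_fixed_params)
  expect_true(all(cs$A[, "deg_kr"] == 0))
  expect_true(cs$row_provenance$contradictory[1])
  expect_identical(feasibility_check(cs)$status, "infeasible")
  # fixing a parameter's value to exactly zero via a constraint works the same way
  cs2 <- assemble_constraints(cb, net, extra = list(
    log_linear_constraint("fixed_value", c(r1_kr = 1), rhs = "zero")))
  expect_true("r1_kr" %in% cs2$zero_fixed_params)
})

test_that("cycle flux residuals are state-independent and equal the Wegscheider residual", {
  net_f <- feasible_triangle()
  net_i <- infeasible_triangle()
  cb <- cycle_basis(prune_to_closed(net_f))
  # random positive states (not on any trajectory)
  set.seed(5)
  states <- tibble::tibble(
    time = rep(1:100, each = 3),
    species_id = rep(c("A", "B", "C"), 100),
    concentration = runif(300, 0.1, 5)
  )
  rf <- flux_cycle_residuals(states, cb, net_f)
  expect_equal(nrow(rf), 100)
  expect_lt(max(abs(rf$residual)), 1e-8)
  ri <- flux_cycle_residuals(states, cb, net_i)
  expect_equal(ri$residual, rep(log(2), 100), tolerance = 1e-9)
  # and along an actual trajectory of the feasible system
  traj <- simulate_network(net_f, times = seq(0, 2, 0.25))
  rt <- flux_cycle_residuals(traj, cb, net_f)
  expect_lt(max(abs(rt$residual)), 1e-8)
})
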