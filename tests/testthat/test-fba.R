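test_that("capacity-limited chain optima are exact", {
  m <- chain_model(uptake_lb = -5)
  sol <- solve_fba(m, "EX_b_e", "maximize")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 5)
  # no input, no output
  expect_equal(solve_fba(chain_model(0), "EX_b_e", "maximize")$objective_value, 0)
  # irreversible reaction capped at 7 with unconstrained supply
  m2 <- chain_model(uptake_lb = -1000)
  m2 <- set_reaction_bounds(m2, "A2B", 0, 7)
  expect_equal(max_flux(m2, "A2B"), 7)
  expect_error(solve_fba(m, "NOPE"), "unknown objective")
})

test_that("optimal solutions satisfy steady state and bounds", {
  m <- build_toy_model(small_toy_spec())
  m <- apply_exchange_bounds(m, diet_to_bounds(toy_diet()), quiet = TRUE)
  for (rid in c("EX_glc_e", "EX_cm_e", "SGLT1", "OXPHOS")) {
    sol <- solve_fba(m, rid, "maximize")
    expect_equal(sol$status, "optimal")
    res <- solution_residuals(m, sol)
    expect_lte(res$steady_state, 1e-6)
    expect_lte(res$bound_violation, 1e-9)
  }
})

test_that("LP optima equal the brute-force vertex oracle on mini networks", {
  models <- list(chain_model(-5), parallel_model(),
                 sglt_mini_model(sigma = 2, apical_glut2 = FALSE),
                 sglt_mini_model(sigma = 2, apical_glut2 = TRUE),
                 sglt_mini_model(sigma = 1, glc_lb = -3, na_lb = -10))
  for (m in models) {
    for (rid in m$reactions$id) {
      expect_equal(max_flux(m, rid), oracle_fba_value(m, rid, "maximize"),
                   tolerance = 1e-8, info = rid)
      expect_equal(min_flux(m, rid), oracle_fba_value(m, rid, "minimize"),
                   tolerance = 1e-8, info = rid)
    }
  }
})

test_that("Na+-limited glucose transport follows the SGLT1 stoichiometry", {
  # without apical GLUT2: absorption = Na bound / sigma
  m <- sglt_mini_model(sigma = 2, apical_glut2 = FALSE, glc_lb = -4, na_lb = -2)
  expect_equal(-min_flux(m, "EX_glc_u"), 2 / 2)
  # with apical GLUT2 all luminal glucose is absorbed
  m2 <- sglt_mini_model(sigma = 2, apical_glut2 = TRUE, glc_lb = -4, na_lb = -2)
  expect_equal(-min_flux(m2, "EX_glc_u"), 4)
})

test_that("relaxing a bound never decreases a maximization optimum", {
  m <- sglt_mini_model(sigma = 2, apical_glut2 = FALSE)
  base <- max_flux(m, "EX_glc_e")
  ex <- m$reactions$id[m$reactions$is_exchange]
  for (rid in ex) {
    relaxed <- set_reaction_bounds(m, rid,
                                   lower = reaction_bounds(m, rid)[1] - 10)
    expect_gte(max_flux(relaxed, "EX_glc_e") + 1e-9, base)
  }
})

test_that("lexicographic optimization fixes the primary optimum", {
  m <- sglt_mini_model(sigma = 2, apical_glut2 = FALSE, glc_lb = -4, na_lb = -2)
  lex <- lexicographic_optimize(
    m, primary = list(reaction = "EX_glc_e", direction = "maximize"),
    secondary = list(reaction = "EX_na_u", direction = "maximize"))
  expect_equal(lex$status, "optimal")
  expect_equal(lex$primary_value, 1)          # Na-limited: 2/sigma
  expect_equal(lex$secondary_value, -2, tolerance = 1e-6)  # all Na consumed
  # secondary already unique at the primary optimum: same as plain FBA
  lex2 <- lexicographic_optimize(
    m, primary = list(reaction = "EX_glc_e", direction = "maximize"),
    secondary = list(reaction = "EX_glc_e", direction = "maximize"))
  expect_equal(lex2$objective_value, max_flux(m, "EX_glc_e"), tolerance = 1e-8)
  # primary infeasibility propagates
  bad <- set_reaction_bounds(m, "SGLT1", 2, 3)  # forced flux without Na supply
  bad <- set_reaction_bounds(bad, "EX_na_u", 0, 0)
  lex3 <- lexicographic_optimize(
    bad, primary = list(reaction = "EX_glc_e", direction = "maximize"),
    secondary = list(reaction = "EX_na_u", direction = "minimize"))
  expect_equal(lex3$status, "infeasible")
})

test_that("titration scans restore bounds and report per-point status", {
  m <- sglt_mini_model(sigma = 2, apical_glut2 = FALSE, glc_lb = -4, na_lb = 0)
  levels <- seq(0, 12, by = 2)
  curve <- titration_scan(m, "EX_na_u", -levels,
                          objective = list(reaction = "EX_glc_e",
                                           direction = "maximize"))
  expect_equal(length(curve$objective_values), length(levels))
  # piecewise linear: slope 1/sigma then plateau at total luminal glucose
  expect_equal(curve$objective_values, pmin(levels / 2, 4))
  # non-decreasing for uptake relaxation with a maximization objective
  expect_true(all(diff(curve$objective_values) >= -1e-9))
  # empty scan
  empty <- titration_scan(m, "EX_na_u", numeric(0),
                          objective = list(reaction = "EX_glc_e",
                                           direction = "maximize"))
  expect_length(empty$objective_values, 0)
})

test_that("flux variability brackets alternate optima", {
  m <- parallel_model(uptake_lb = -5, cap = 5)
  fva <- flux_variability(m, c("P1", "P2"),
                          objective = list(reaction = "EX_b_e",
                                           direction = "maximize"))
  # either route can carry anything from 0 to its capacity at the optimum
  expect_equal(fva$min, c(0, 0), tolerance = 1e-6)
  expect_equal(fva$max, c(5, 5), tolerance = 1e-6)
})
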