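test_that("a linear chain converts the uptake bound 1:1 into growth", {
  m <- chain_model(uptake = 10)
  sol <- solve_fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)
  # deleting the sole pathway gene abolishes growth but stays feasible
  ko <- solve_fba(m, deletions = "g1")
  expect_equal(ko$status, "optimal")
  expect_equal(ko$objective_value, 0)
})

test_that("branched optimum matches brute-force vertex enumeration", {
  m <- branched_model()
  sol <- solve_fba(m, pfba = FALSE)
  A <- stoichiometric_matrix(m)
  b <- design_bounds(m)
  obj <- rep(0, ncol(A))
  obj[match("GROWTH", colnames(A))] <- 1
  oracle <- vertex_oracle(obj, A, b$lb, pmin(b$ub, 1000))
  expect_true(oracle$feasible)
  expect_equal(sol$objective_value, oracle$best, tolerance = 1e-8)
  # the capped efficient route forces partial use of the half-yield branch
  expect_equal(sol$objective_value, 6 + 0.5 * 4)
  # a metric objective (flux through the inefficient branch) agrees too
  obj2 <- rep(0, ncol(A))
  obj2[match("R2", colnames(A))] <- 1
  ext <- theoretical_extreme(m, objective = "R2")
  oracle2 <- vertex_oracle(obj2, A, b$lb, pmin(b$ub, 1000))
  expect_equal(ext$objective_value, oracle2$best, tolerance = 1e-8)
})

test_that("viability thresholds growth at epsilon", {
  sol <- list(status = "optimal", objective_value = 0.12)
  expect_true(is_viable(sol, 1e-6))
  expect_false(is_viable(list(status = "optimal", objective_value = 0)))
  expect_false(is_viable(list(status = "infeasible", objective_value = 0)))
  expect_false(is_viable(list(status = "optimal", objective_value = 5e-7)))
})

test_that("infeasible designs report infeasible with zero fluxes", {
  toy <- toy_fixture()
  m <- toy$model
  i <- match("GROWTH", m$reactions$id)
  m$reactions$lower_bound[i] <- 50 # more growth than any medium supports
  sol <- solve_fba(m, toy_medium())
  expect_equal(sol$status, "infeasible")
  expect_true(all(sol$fluxes == 0))
})

test_that("adding a gene deletion never increases maximal growth", {
  toy <- toy_fixture()
  med <- toy_medium(ea = "EX_o2")
  genes <- central_genes(toy$model)
  wt <- solve_fba(toy$model, med, pfba = FALSE)$objective_value
  singles <- vapply(genes, function(g) {
    solve_fba(toy$model, med, g, pfba = FALSE)$objective_value
  }, numeric(1))
  expect_true(all(singles <= wt + 1e-7))
  set.seed(11)
  pairs <- utils::combn(genes, 2)
  pairs <- pairs[, sample(ncol(pairs), 40)] # sampled double deletions
  for (p in seq_len(ncol(pairs))) {
    dd <- solve_fba(toy$model, med, pairs[, p], pfba = FALSE)$objective_value
    expect_lte(dd, min(singles[pairs[1, p]], singles[pairs[2, p]]) + 1e-7)
  }
})

test_that("optimal solutions satisfy steady-state mass balance", {
  toy <- toy_fixture()
  for (med in list(toy_medium(), toy_medium(ea = "EX_o2"),
                   toy_medium(carbon = "EX_mel"),
                   toy_medium(carbon = "EX_glyc", ea = "EX_o2"))) {
    sol <- solve_fba(toy$model, med)
    expect_equal(sol$status, "optimal")
    expect_lt(mass_balance_residual(toy$model, sol), 1e-6)
    expect_true(all(sol$fluxes >= design_bounds(toy$model, med)$lb - 1e-7))
    expect_true(all(sol$fluxes <= design_bounds(toy$model, med)$ub + 1e-7))
  }
})

test_that("growth scales linearly with the carbon uptake bound", {
  toy <- toy_fixture()
  catalog2 <- toy$catalog
  catalog2$max_uptake[catalog2$exchange_id == "EX_glc"] <- 20
  med1 <- toy_medium()
  med2 <- medium_from_design(list(carbon = "EX_glc", electron_acceptor = NA,
                                  nitrogen = "EX_nh4", phosphorus = "EX_pi",
                                  sulfur = "EX_so4"), catalog2)
  b1 <- solve_fba(toy$model, med1)$objective_value
  b2 <- solve_fba(toy$model, med2)$objective_value
  expect_equal(b2, 2 * b1, tolerance = 1e-8)
})

test_that("carbon influx balances biomass plus effluxed carbon", {
  toy <- toy_fixture()
  sol <- solve_fba(toy$model, toy_medium())
  exf <- exchange_fluxes(toy$model, sol)
  carbon <- setNames(toy$model$metabolites$carbon, toy$model$metabolites$id)
  c_in <- sum(exf$uptake * carbon[exf$metabolite])
  c_out <- sum(exf$secretion * carbon[exf$metabolite])
  expect_equal(c_in, c_out, tolerance = 1e-6) # biomass carbon leaves via EX_biomass
})

test_that("the anaerobic design closes the electron acceptor entirely", {
  toy <- toy_fixture()
  b <- design_bounds(toy$model, toy_medium(ea = NA))
  i <- match("EX_o2", toy$model$reactions$id)
  expect_equal(b$lb[i], 0)
  sol <- solve_fba(toy$model, toy_medium(ea = NA))
  expect_equal(unname(sol$fluxes["EX_o2"]), 0)
})

test_that("the alternate-optima policy is reproducible and optional", {
  toy <- toy_fixture()
  med <- toy_medium()
  a <- solve_fba(toy$model, med, pfba = TRUE)
  b <- solve_fba(toy$model, med, pfba = TRUE)
  raw <- solve_fba(toy$model, med, pfba = FALSE)
  expect_identical(a$fluxes, b$fluxes)
  expect_equal(a$objective_value, raw$objective_value, tolerance = 1e-9)
  # the minimized-flux solution is never larger in total flux than the vertex
  expect_lte(sum(abs(a$fluxes)), sum(abs(raw$fluxes)) + 1e-6)
})

test_that("theoretical extremes respect an optional growth requirement", {
  toy <- toy_fixture()
  med <- toy_medium()
  free_max <- theoretical_extreme(toy$model, med, objective = "EX_lac")
  constrained <- theoretical_extreme(toy$model, med, objective = "EX_lac",
                                     growth_fraction = 0.9)
  expect_gte(free_max$objective_value, constrained$objective_value)
  # with no growth requirement and an empty medium, zero flux is optimal
  # for cost-like minimization
  empty <- medium_from_design(list(carbon = NA, electron_acceptor = NA,
                                   nitrogen = NA, phosphorus = NA,
                                   sulfur = NA), toy_fixture()$catalog)
  cost_obj <- setNames(-1, "EX_glc") # uptake = negative flux; minimize intake
  ext <- theoretical_extreme(toy$model, empty, objective = cost_obj,
                             sense = "max")
  expect_equal(ext$objective_value, 0)
})
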