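test_that("simplex agrees with vertex enumeration on random small LPs", {
  set.seed(11)
  n_checked <- 0
  for (i in 1:40) {
    lp <- random_box_lp(n_rows = sample(1:3, 1), n_cols = sample(2:6, 1))
    got <- solve_lp(lp$obj, lp$A, lb = lp$lb, ub = lp$ub)
    oracle <- vertex_enum_lp(lp$obj, lp$A, lp$lb, lp$ub)
    expect_identical(got$status, "optimal")
    expect_equal(got$objective, oracle, tolerance = 1e-8)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 40)
})

test_that("simplex detects infeasibility", {
  # x1 + x2 = 0 with both forced positive
  res <- solve_lp(c(1, 0), matrix(c(1, 1), 1, 2), lb = c(1, 1), ub = c(2, 2))
  expect_identical(res$status, "infeasible")
})

test_that("analytic toys reproduce closed-form optima", {
  toys <- analytic_fba_toys()
  chain <- toys$chain
  fm <- build_flux_model(chain$host, empty_pathway(chain$target), NULL,
                         chain$medium, chain$target)
  pr <- producibility(fm)
  expect_identical(pr$result$status, "optimal")
  expect_equal(pr$max_flux, 10, tolerance = 1e-8)
  expect_equal(yield_percent(pr$result, fm)$yield_percent, 100,
               tolerance = 1e-8)
  expect_lte(steady_state_residual(fm, pr$result), 1e-6)

  branch <- toys$branch
  fmb <- build_flux_model(branch$host, empty_pathway(branch$target), NULL,
                          branch$medium, branch$target)
  prb <- producibility(fmb)
  expect_equal(prb$max_flux, 5, tolerance = 1e-8)
  expect_equal(yield_percent(prb$result, fmb)$yield_percent, 50,
               tolerance = 1e-8)
  expect_lte(steady_state_residual(fmb, prb$result), 1e-6)

  # closing every uptake leaves the zero flux vector as the optimum
  closed <- fba_maximize(fm, fm$demand_col,
                         extra_lb = stats::setNames(0, "EX_A"))
  expect_identical(closed$status, "optimal")
  expect_equal(closed$objective_value, 0, tolerance = 1e-9)
})

test_that("flux model structure follows host + pathway + demand arithmetic", {
  for (cs in fixture_cases()) {
    fx <- table2_fixture(cs)
    r <- run_case(fx)
    fm <- build_flux_model(fx$host, r$pw, fx$db, fx$medium, fx$target)
    expect_equal(ncol(fm$S), length(fx$host$reactions) + r$pw$n_reactions + 1L,
                 label = cs)
    expect_length(fm$het_cols, r$pw$n_reactions)
    # demand column exports only the target
    dem <- fm$S[, fm$demand_col]
    expect_equal(sum(dem != 0), 1L)
    expect_equal(unname(dem[dem != 0]), -1)
    # heterologous columns are symmetric-bounded
    expect_true(all(fm$lb[fm$het_cols] == -1000 & fm$ub[fm$het_cols] == 1000))
  }
  # the single-reaction case adds exactly one non-demand column
  fx <- table2_fixture("pentanedione_ecoli")
  r <- run_case(fx)
  fm <- build_flux_model(fx$host, r$pw, fx$db, fx$medium, fx$target)
  expect_length(fm$het_cols, 1L)

  # empty pathway on a native-target model: host columns plus demand only
  toys <- analytic_fba_toys()
  fm0 <- build_flux_model(toys$chain$host, empty_pathway("K0002"), NULL,
                          toys$chain$medium, "K0002")
  expect_equal(ncol(fm0$S), length(toys$chain$host$reactions) + 1L)
  expect_error(build_flux_model(toys$chain$host, empty_pathway("K9999"), NULL,
                                toys$chain$medium, "K9999"),
               "neither in the host nor in the pathway")
})

test_that("producibility classifies connection through the flux cone", {
  # a target whose only producer consumes a compound with no source
  host <- local({
    hp <- tempfile(fileext = ".tsv")
    writeLines(c(
      "## metabolites", "model_id\tcompartment",
      "A_e\te", "A_c\tc", "orphan_c\tc", "T_c\tc",
      "## reactions", "id\tequation\tlb\tub\tis_biomass\tis_exchange",
      "EX_A\tA_e <=>\t-10\t1000\t0\t1",
      "T_A\tA_e <=> A_c\t-1000\t1000\t0\t0",
      "VT\tA_c + orphan_c <=> T_c\t-1000\t1000\t0\t0",
      "BIOMASS\tA_c <=>\t0\t1000\t1\t0"), hp)
    mp <- tempfile(fileext = ".tsv")
    utils::write.table(data.frame(
      model_id = c("A_e", "A_c", "T_c"),
      kegg_id = c("K0001", "K0001", "K0004"), stringsAsFactors = FALSE),
      mp, sep = "\t", quote = FALSE, row.names = FALSE)
    load_host_model(hp, mp)
  })
  med <- medium_spec(carbon_source = "K0001", free_exchanges = character())
  fm <- build_flux_model(host, empty_pathway("K0004"), NULL, med, "K0004")
  pr <- producibility(fm)
  expect_false(pr$producible)
  expect_equal(pr$max_flux, 0, tolerance = 1e-9)

  # the worked example is producible under the glucose medium
  fx <- table2_fixture("pentanedione_ecoli")
  r <- run_case(fx)
  fmp <- build_flux_model(fx$host, r$pw, fx$db, fx$medium, fx$target)
  expect_true(producibility(fmp)$producible)

  # closing the carbon source can never turn a target producible
  closed <- fba_maximize(fmp, fmp$demand_col,
                         extra_lb = stats::setNames(0, fmp$carbon_exchange_col))
  expect_lte(closed$objective_value,
             producibility(fmp)$max_flux + 1e-9)
})

test_that("heterologous additions never decrease the production optimum", {
  fx <- table2_fixture("pentanedione_cglut")
  r <- run_case(fx)
  fm <- build_flux_model(fx$host, r$pw, fx$db, fx$medium, fx$target)
  full <- producibility(fm)$max_flux
  # clamping the heterologous columns to zero mimics the un-expanded model
  clamp <- stats::setNames(rep(0, length(fm$het_cols)), fm$het_cols)
  reduced <- fba_maximize(fm, fm$demand_col, extra_lb = clamp,
                          extra_ub = clamp)
  expect_lte(reduced$objective_value, full + 1e-9)
})

test_that("lexicographic biomass fixing holds and separates the two toys", {
  toys <- analytic_fba_toys()
  comp <- toys$competition
  fmc <- build_flux_model(comp$host, empty_pathway(comp$target), NULL,
                          comp$medium, comp$target)
  bc <- biomass_coupled_production(fmc)
  expect_identical(bc$status, "optimal")
  expect_equal(bc$biomass_opt, 10, tolerance = 1e-8)
  expect_equal(bc$target_flux, 0, tolerance = 1e-8)
  expect_equal(bc$result$fluxes[[fmc$biomass_col]], bc$biomass_opt,
               tolerance = 1e-6)

  nadh <- toys$nadh
  fmn <- build_flux_model(nadh$host, empty_pathway(nadh$target), NULL,
                          nadh$medium, nadh$target)
  bcn <- biomass_coupled_production(fmn)
  expect_equal(bcn$biomass_opt, 4, tolerance = 1e-8)
  expect_equal(bcn$target_flux, 6, tolerance = 1e-8)
  expect_gt(bcn$target_flux, 0)

  # contract across every worked-example fixture: stage-2 biomass equals the
  # stage-1 optimum within relative 1e-6
  for (cs in fixture_cases()) {
    fx <- table2_fixture(cs)
    r <- run_case(fx)
    fm <- build_flux_model(fx$host, r$pw, fx$db, fx$medium, fx$target)
    b <- biomass_coupled_production(fm)
    if (!identical(b$status, "optimal")) next
    expect_equal(b$result$fluxes[[fm$biomass_col]], b$biomass_opt,
                 tolerance = 1e-6, label = cs)
    expect_lte(steady_state_residual(fm, b$result), 1e-6)
  }
})

test_that("yields are molar ratios against realized uptake", {
  toys <- analytic_fba_toys()
  chain <- toys$chain
  fm <- build_flux_model(chain$host, empty_pathway(chain$target), NULL,
                         chain$medium, chain$target)
  # demand 0.05 at uptake 10 -> 0.5%, below the 1% threshold
  half <- fba_maximize(fm, fm$demand_col,
                       extra_ub = stats::setNames(0.05, fm$demand_col))
  y <- yield_percent(half, fm)
  expect_equal(y$yield_percent, 0.5, tolerance = 1e-6)
  expect_false(y$produced)
  # demand 10 at uptake 10 -> 100%
  full <- fba_maximize(fm, fm$demand_col)
  yf <- yield_percent(full, fm)
  expect_equal(yf$yield_percent, 100, tolerance = 1e-8)
  expect_true(yf$produced)
})

test_that("medium bounds implement the stated uptake policy", {
  fx <- table2_fixture("pentanedione_ecoli")
  r <- run_case(fx)
  fm <- build_flux_model(fx$host, r$pw, fx$db, fx$medium, fx$target)
  expect_equal(unname(fm$lb["EX_glc"]), -10)   # sole carbon source
  expect_equal(unname(fm$lb["EX_o2"]), -2)     # micro-aerobic cap
  expect_equal(unname(fm$lb["EX_co2"]), -1000) # free transport
  expect_equal(unname(fm$lb["EX_h2o"]), -1000)
})
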