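# Chemostat specification, unit conversions, and the integration of a cell
# net with the tank mass balances.

test_that("unit conversions use the molar mass both ways", {
  expect_equal(convert_units(10, "g_per_L", "mM", 180.16), 10 / 180.16 * 1000,
               tolerance = 1e-12)
  expect_equal(convert_units(0, "g_per_L", "mM", 180.16), 0)
  x <- 3.7
  expect_equal(convert_units(convert_units(x, "g_per_L", "mM", 148.12),
                             "mM", "g_per_L", 148.12), x, tolerance = 1e-12)
  expect_equal(convert_units(5, "mM_per_h", "g_per_L_per_h", 148.12),
               5 * 148.12 / 1000)
  expect_error(convert_units(1, "g_per_L", "furlongs"), "unsupported")
  expect_error(convert_units(1, "g_per_L", "mM"), "molar mass")
})

test_that("chemostat specs validate their parameters", {
  expect_error(toy_producer_spec(D = 0), "D > 0")
  expect_error(toy_producer_spec(c_g = -1), "c_g >= 0")
  expect_error(chemostat_spec(10, 0.2, "u", "p", "g", Xmin = 5, Xmax = 2),
               "Xmin < Xmax")
  sp <- toy_producer_spec(c_g = 10)
  expect_equal(sp$Xmax, 7.5)   # default yield-based cap 0.75 * c_g
})

test_that("tank integration adds the documented net elements", {
  cell <- cbm_to_fn(make_toy_producer()$model)
  spec <- toy_producer_spec(c_g = 10, D = 0.1)
  mdl <- build_integrated_fn(cell, spec)
  net <- mdl$net
  expect_length(net$places, length(cell$places) + 3L)
  expect_length(net$transitions, length(cell$transitions) + 7L)
  expect_length(net$intensity_handlers, 6L)
  expect_setequal(mdl$bilinear_handlers, c("h_u", "h_r", "h_c"))
  # feed transition carries D * c_g in mM/h
  expect_equal(net$transitions$t_gin$l0_lo, 0.1 * 10 / 180.16 * 1000,
               tolerance = 1e-9)
  expect_equal(net$transitions$t_gin$l0_lo, net$transitions$t_gin$l0_hi)
  # biomass place carries the spec bounds
  expect_equal(net$places$X$conc_lo, spec$Xmin)
  expect_equal(net$places$X$conc_hi, spec$Xmax)
  # the steady-state system registers exactly three bilinear terms
  cs <- chemostat_steady_state(mdl)
  expect_length(cs$bilinear, 3L)
})

test_that("a missing interface reaction is reported by name", {
  cell <- cbm_to_fn(make_toy_producer()$model)
  spec <- chemostat_spec(10, 0.1, substrate_exchange = "NOPE",
                         product_exchange = "EX_prod",
                         growth_reaction = "GROWTH")
  expect_error(build_integrated_fn(cell, spec), "NOPE")
})

test_that("zero feed forces zero uptake and zero residual substrate", {
  tp <- make_toy_producer()
  spec <- toy_producer_spec(c_g = 0, D = 0.1, Xmax = 1)
  mdl <- build_integrated_fn(cbm_to_fn(tp$model), spec)
  # with no feed the only steady state is the washed-out culture X = 0
  sol <- solve_fixed_biomass(mdl, 0, c(t_ut = 1), "max")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 0, tolerance = 1e-9)
  expect_equal(unname(sol$variables["conc.G"]), 0, tolerance = 1e-9)
})

test_that("substrate mass balance D*c_g = D*s_g + u_t holds in every optimum", {
  tp <- make_toy_producer()
  for (D in c(0.1, 0.3, 0.6, 0.9)) {
    spec <- toy_producer_spec(c_g = 10, D = D)
    mdl <- build_integrated_fn(cbm_to_fn(tp$model), spec)
    sol <- solve_piecewise(mdl, partition_biomass(spec$Xmin, spec$Xmax, 20),
                           c(t_cout = 1), "max")
    expect_equal(sol$status, "optimal")
    c_g_mM <- convert_units(10, "g_per_L", "mM", spec$mw_substrate)
    lhs <- D * c_g_mM
    rhs <- D * unname(sol$variables["conc.G"]) + unname(sol$fluxes["t_ut"])
    expect_equal(lhs, rhs, tolerance = 1e-6)
    # product secretion is non-negative in the tank
    expect_gte(unname(sol$variables["conc.C"]), -1e-9)
  }
})

test_that("growth rate equals the dilution rate at steady state", {
  tp <- make_toy_producer()
  spec <- toy_producer_spec(c_g = 10, D = 0.4)
  mdl <- build_integrated_fn(cbm_to_fn(tp$model), spec)
  sol <- solve_piecewise(mdl, partition_biomass(0, spec$Xmax, 10),
                         c(t_cout = 1), "max")
  expect_equal(unname(sol$fluxes["GROWTH"]), 0.4, tolerance = 1e-9)
})

test_that("dilution above the maximal growth rate washes the culture out", {
  tp <- make_toy_producer(k = 0.1, u_max = 10)   # mu_max = 1.0 /h
  spec <- toy_producer_spec(c_g = 10, D = 1.2)
  res <- maximize_productivity(tp$model, spec, n_regions = 8)
  expect_equal(res$status, "infeasible")
  # and feasible just below
  spec2 <- toy_producer_spec(c_g = 10, D = 0.95)
  res2 <- maximize_productivity(tp$model, spec2, n_regions = 8)
  expect_equal(res2$status, "optimal")
})

test_that("chemostat specs load from YAML and JSON configs", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("c_g: 10", "D: 0.23", "substrate_exchange: GLC_upt",
               "product_exchange: EX_prod", "growth_reaction: GROWTH",
               "Xmax: 5"), yml)
  sp <- read_chemostat_spec(yml)
  expect_s3_class(sp, "chemostat_spec")
  expect_equal(sp$D, 0.23)
  expect_equal(sp$Xmax, 5)
  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(c_g = 10, D = 0.23,
                            substrate_exchange = "GLC_upt",
                            product_exchange = "EX_prod",
                            growth_reaction = "GROWTH"),
                       js, auto_unbox = TRUE)
  sp2 <- read_chemostat_spec(js)
  expect_equal(sp2$D, sp$D)
  expect_equal(sp2$Xmax, 7.5)   # default cap when unset
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("c_g: 10", "D: 0.2", "substrate_exchange: u",
               "product_exchange: p", "growth_reaction: g",
               "dillution: 0.3"), bad)
  expect_error(read_chemostat_spec(bad), "unknown chemostat config key")
})
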