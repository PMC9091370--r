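# Model I/O, reaction formula dialect, reversible unfolding and the
# conversion of constraint-based models to Flexible Nets.

test_that("the TSV dialect reads the four-reaction fixture", {
  path <- system.file("extdata", "table1.tsv", package = "fermenet")
  m <- load_model(path, quiet = TRUE)
  expect_s3_class(m, "cbm_model")
  expect_length(m$reactions, 4L)
  expect_setequal(m$metabolites, c("A", "B", "C"))
  expect_equal(m$reactions$R3$lb, -500)
  expect_equal(m$reactions$R3$ub, 1000)
  expect_equal(m$reactions$R3$stoich, c(A = -1, B = 2))
})

test_that("formula parsing handles coefficients, reversibility and boundaries", {
  pf <- parse_reaction_formula("2 A + B -> D")
  expect_equal(pf$stoich, c(A = -2, B = -1, D = 1))
  expect_false(pf$reversible)
  pf <- parse_reaction_formula("A <-> 2 B")
  expect_true(pf$reversible)
  expect_equal(pf$stoich, c(A = -1, B = 2))
  expect_equal(parse_reaction_formula("-> A")$stoich, c(A = 1))
  expect_equal(parse_reaction_formula("B + C ->")$stoich, c(B = -1, C = -1))
  expect_equal(parse_reaction_formula("0.5 X -> 1.5 Y")$stoich,
               c(X = -0.5, Y = 1.5))
  expect_error(parse_reaction_formula("A + B"), "parse")
})

test_that("degenerate and malformed model files are rejected", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("id\tformula\tlb\tub", empty)
  expect_error(load_model(empty, quiet = TRUE), "empty")
  nob <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tformula\tlb\tub", "R1\t-> A\tNA\t10"), nob)
  expect_error(load_model(nob, quiet = TRUE), "bounds")
})

test_that("the SBML (fbc) reader recovers the same model as the TSV", {
  m <- load_model(system.file("extdata", "table1_sbml.xml", package = "fermenet"),
                  quiet = TRUE)
  expect_length(m$reactions, 4L)
  expect_setequal(m$metabolites, c("A", "B", "C"))
  expect_equal(m$reactions$R1$lb, 5)
  expect_equal(m$reactions$R1$ub, 5)
  expect_equal(m$reactions$R3$lb, -500)
  expect_equal(m$objective, "R4")
  expect_equal(m$reactions$R4$stoich[order(names(m$reactions$R4$stoich))],
               c(B = -1, C = -1))
  sol <- optimize_fn(cbm_to_fn(m), c(R4 = 1))
  expect_equal(sol$objective, 10, tolerance = 1e-9)
})

test_that("the JSON dialect round-trips a model", {
  path <- withr::local_tempfile(fileext = ".json")
  m <- table1_model()
  write_cbm_json(m, path)
  m2 <- load_model(path, quiet = TRUE)
  expect_equal(names(m2$reactions), names(m$reactions))
  for (id in names(m$reactions)) {
    expect_equal(m2$reactions[[id]]$stoich, m$reactions[[id]]$stoich)
    expect_equal(m2$reactions[[id]]$lb, m$reactions[[id]]$lb)
    expect_equal(m2$reactions[[id]]$ub, m$reactions[[id]]$ub)
  }
})

test_that("reactions can be added once, with new metabolites declared", {
  m <- table1_model()
  m2 <- add_reaction(m, "R5", formula = "A -> E", lb = 0, ub = 10)
  expect_length(m2$reactions, 5L)
  expect_true("E" %in% m2$metabolites)
  expect_error(add_reaction(m2, "R5", formula = "A -> E"), "already")
})

test_that("the citramalate pathway insertion matches the synthase stoichiometry", {
  # precursor supply regenerating acetyl-CoA from free CoA, so the synthase
  # can turn over at steady state
  m <- cbm_model(list(
    list(id = "dummy", stoich = c(coa_c = -1, h_c = -1, accoa_c = 1,
                                  pyr_c = 1, h2o_c = 1),
         lb = 0, ub = 10)))
  m2 <- add_citramalate_pathway(m)
  expect_length(m2$reactions, 3L)
  expect_equal(m2$reactions$CIMA$stoich,
               c(accoa_c = -1, pyr_c = -1, h2o_c = -1,
                 citramalate_c = 1, coa_c = 1, h_c = 1))
  expect_equal(m2$reactions$EX_citramalate$stoich, c(citramalate_c = -1))
  expect_equal(m2$reactions$EX_citramalate$ub, 1000)
  # the extended model can actually export citramalate
  sol <- optimize_fn(cbm_to_fn(m2), c(EX_citramalate = 1))
  expect_equal(sol$status, "optimal")
  expect_gt(sol$objective, 0)
})

test_that("reversible unfolding splits ranges and leaves irreversibles alone", {
  m <- unfold_reversible(table1_model())
  expect_setequal(names(m$reactions), c("R1", "R2", "R3_f", "R3_b", "R4"))
  expect_equal(m$reactions$R3_f$lb, 0)
  expect_equal(m$reactions$R3_f$ub, 1000)
  expect_equal(m$reactions$R3_b$lb, 0)
  expect_equal(m$reactions$R3_b$ub, 500)
  expect_equal(m$reactions$R3_b$stoich, c(A = 1, B = -2))
  expect_equal(m$reactions$R4$lb, 0)
  expect_equal(m$reactions$R4$ub, 1000)
  expect_true(all(vapply(m$reactions, `[[`, numeric(1), "lb") >= 0))
})

test_that("LP optima are invariant under reversible unfolding", {
  set.seed(1107)
  for (rep in 1:8) {
    m <- random_cbm()
    direct <- fba_direct(m, c(SINK = 1), "max")
    expect_true(direct$ok)
    sol <- optimize_fn(cbm_to_fn(m), c(SINK = 1), "max")
    expect_equal(sol$status, "optimal")
    expect_equal(sol$objective, direct$objective, tolerance = 1e-6)
    # the unfolded optimum maps back to a feasible signed flux vector
    v <- net_fluxes(sol$fluxes, m)
    for (r in m$reactions) {
      expect_gte(v[[r$id]], r$lb - 1e-6)
      expect_lte(v[[r$id]], r$ub + 1e-6)
    }
  }
})

test_that("net conversion preserves counts, bounds and stoichiometry rows", {
  net <- cbm_to_fn(table1_model())
  expect_length(net$places, 3L)
  expect_length(net$transitions, 5L)
  expect_length(net$event_handlers, 5L)
  expect_length(net$intensity_handlers, 0L)
  # steady-state rows are exactly S.v = 0 of the unfolded model
  mu <- unfold_reversible(table1_model())
  S <- matrix(0, 3, 5, dimnames = list(c("A", "B", "C"), names(mu$reactions)))
  for (r in mu$reactions) S[names(r$stoich), r$id] <- r$stoich
  cs <- steady_state_constraints(net)
  A <- cs$A_eq[, paste0("flux.", colnames(S)), drop = FALSE]
  # match rows up to permutation
  perm <- apply(A, 1, function(row) which(apply(S, 1, function(s)
    all(abs(s - row) < 1e-12))))
  expect_setequal(perm, 1:3)
  expect_true(all(cs$b_eq == 0))
  # empty model converts to places only
  m0 <- cbm_model(list(), metabolites = c("A"))
  net0 <- cbm_to_fn(m0)
  expect_length(net0$places, 1L)
  expect_length(net0$transitions, 0L)
})

test_that("flux variability through the net agrees with the direct route", {
  m <- table1_model()
  fv_net <- flux_variability(cbm_to_fn(m))
  fv_ref <- fva_direct(m, names(m$reactions))
  for (id in c("R1", "R2", "R4")) {
    expect_equal(fv_net$min[fv_net$transition == id],
                 fv_ref$min[fv_ref$id == id], tolerance = 1e-6)
    expect_equal(fv_net$max[fv_net$transition == id],
                 fv_ref$max[fv_ref$id == id], tolerance = 1e-6)
  }
  # the reversible reaction is fully pinned here: its net flux equals the
  # direct route's (degenerate) variability range at any optimum
  expect_equal(fv_ref$min[fv_ref$id == "R3"], 5, tolerance = 1e-6)
  expect_equal(fv_ref$max[fv_ref$id == "R3"], 5, tolerance = 1e-6)
  sol <- optimize_fn(cbm_to_fn(m), c(R4 = 1))
  expect_equal(unname(sol$fluxes["R3_f"] - sol$fluxes["R3_b"]), 5,
               tolerance = 1e-6)
})
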