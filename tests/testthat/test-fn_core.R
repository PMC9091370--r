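# Core Flexible-Net semantics: event handlers, guarded intensity handlers,
# steady-state constraint assembly and LP optimization.

test_that("event handlers turn occurrences into signed place deltas", {
  v1 <- fn_event_handler("v1", "R1", c(A = -1, C = 2))
  v2 <- fn_event_handler("v2", "R2", c(A = -2, B = -1, D = 1))
  expect_equal(apply_event_handler(v1, 1), c(A = -1, C = 2))
  expect_equal(apply_event_handler(v2, 1), c(A = -2, B = -1, D = 1))
  expect_equal(apply_event_handler(v2, 3.5), c(A = -7, B = -3.5, D = 3.5))
  expect_true(all(apply_event_handler(v1, 0) == 0))
  expect_error(apply_event_handler(v1, -1), "non-negative")
})

test_that("guarded handler evaluation follows the three-region rule", {
  s2 <- figure1_net()$intensity_handlers$s2
  expect_equal(length(s2$guards), 3L)
  r <- active_region(s2, c(A = 5, B = 3))
  expect_equal(r$index, 1L); expect_equal(r$rate, 0)
  r <- active_region(s2, c(A = 20, B = 3))
  expect_equal(r$index, 2L); expect_equal(r$rate, 6)
  r <- active_region(s2, c(A = 50, B = 2))
  expect_equal(r$index, 3L); expect_equal(r$rate, 8)
  # half-open boundaries: the threshold belongs to the upper region
  expect_equal(active_region(s2, c(A = 10, B = 1))$index, 2L)
  expect_equal(active_region(s2, c(A = 30, B = 1))$index, 3L)
})

test_that("exactly one guard is active anywhere in the admissible range", {
  s2 <- figure1_net()$intensity_handlers$s2
  for (a in c(0, 1e-9, 9.999, 10, 15, 29.999, 30, 100, 1e6)) {
    r <- active_region(s2, c(A = a, B = 1))
    expect_length(r$index, 1L)
  }
  # a handler with finite coverage reports states outside it
  h <- fn_intensity_handler("h", "R1", on = "A", guards = list(
    fn_guard(0, 1, coef = c(A = 1)), fn_guard(1, 2, coef = c(A = 2))))
  expect_error(active_region(h, c(A = 5)), "coverage")
})

test_that("interval (uncertain-kinetics) relations evaluate to a rate interval", {
  h <- fn_intensity_handler("s1", "R1", guards = list(
    fn_guard(coef = c(A = 1.8), coef_hi = c(A = 2.2))))
  r <- active_region(h, c(A = 10))
  expect_equal(r$rate, c(18, 22))
})

test_that("steady-state constraints carry place balances and lambda0 bounds", {
  cs <- steady_state_constraints(cbm_to_fn(table1_model()))
  expect_s3_class(cs, "fn_constraints")
  # five unfolded transitions, bounded by their lambda0
  expect_equal(sort(cs$vars),
               sort(paste0("flux.", c("R1", "R2", "R3_f", "R3_b", "R4"))))
  expect_equal(unname(cs$lb["flux.R1"]), 5)
  expect_equal(unname(cs$ub["flux.R1"]), 5)
  expect_equal(unname(cs$ub["flux.R2"]), 20)
  expect_equal(unname(cs$ub["flux.R3_b"]), 500)
  # balance row for place A: v1 - v3f + v3b = 0
  expect_equal(nrow(cs$A_eq), 3L)   # one row per metabolite A, B, C
  rowA <- cs$A_eq[apply(cs$A_eq != 0, 1, function(z)
    all(names(which(z)) %in% paste0("flux.", c("R1", "R3_f", "R3_b")))), ]
  expect_equal(unname(rowA[c("flux.R1", "flux.R3_f", "flux.R3_b")]),
               c(1, -1, 1))
  expect_true(all(cs$b_eq == 0))
})

test_that("a source with no outflow is forced to zero flux at steady state", {
  net <- flexible_net(
    places = list(fn_place("A")),
    transitions = list(fn_transition("src", 0, 50)),
    event_handlers = list(fn_event_handler("v", "src", c(A = 1))))
  sol <- optimize_fn(net, c(src = 1), "max")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 0, tolerance = 1e-9)
})

test_that("the four-reaction model optimizes to its known optimum", {
  net <- cbm_to_fn(table1_model())
  sol <- optimize_fn(net, c(R4 = 1), "max")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 10, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["R1"]), 5, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["R2"]), 10, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["R3_f"] - sol$fluxes["R3_b"]), 5,
               tolerance = 1e-9)
})

test_that("every optimal solution conserves mass at each place", {
  set.seed(421)
  for (rep in 1:5) {
    m <- random_cbm()
    net <- cbm_to_fn(m)
    sol <- optimize_fn(net, c(SINK = 1), "max")
    expect_equal(sol$status, "optimal")
    cs <- steady_state_constraints(net)
    resid <- cs$A_eq %*% sol$variables[cs$vars] - cs$b_eq
    expect_lt(max(abs(resid)), 1e-6)
  }
})

test_that("scaling all lambda0 bounds scales the optimum linearly", {
  scale_model <- function(m, k) {
    for (i in seq_along(m$reactions)) {
      m$reactions[[i]]$lb <- m$reactions[[i]]$lb * k
      m$reactions[[i]]$ub <- m$reactions[[i]]$ub * k
    }
    m
  }
  base <- optimize_fn(cbm_to_fn(table1_model()), c(R4 = 1))$objective
  for (k in c(0.5, 2, 7)) {
    scaled <- optimize_fn(cbm_to_fn(scale_model(table1_model(), k)),
                          c(R4 = 1))$objective
    expect_equal(scaled, k * base, tolerance = 1e-8)
  }
})

test_that("unbounded objectives are reported explicitly", {
  m <- cbm_model(list(list(id = "in", stoich = c(A = 1), lb = 0, ub = Inf),
                      list(id = "out", stoich = c(A = -1), lb = 0, ub = Inf)))
  sol <- optimize_fn(cbm_to_fn(m), c(out = 1), "max")
  expect_equal(sol$status, "unbounded")
  expect_true(is.na(sol$objective))
})

test_that("net construction rejects dangling references and bad bounds", {
  expect_error(fn_transition("t", 3, 1), "l0_lo")
  expect_error(fn_transition("t", -1, 1), "l0_lo")
  expect_error(flexible_net(
    places = list(fn_place("A")),
    transitions = list(fn_transition("t")),
    event_handlers = list(fn_event_handler("v", "t", c(B = 1)))),
    "unknown place")
  expect_error(flexible_net(
    places = list(fn_place("A")),
    transitions = list(fn_transition("t")),
    event_handlers = list(fn_event_handler("v", "nope", c(A = 1)))),
    "unknown transition")
})
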