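## Built-in fixture models and the brute-force oracle.
##
## The toy producer is a 3-reaction cell whose integrated chemostat optimum
## has a closed form, so the whole pipeline (net construction, steady-state
## constraints, region-wise relaxation) can be validated against independent
## arithmetic.  The fixed-biomass grid oracle provides the matching lower
## bound: relaxation >= truth >= oracle, with both ends converging.

#' The four-reaction didactic model
#'
#' `R1: -> A` with flux fixed at 5; `R2: -> C` in `[0, 20]`;
#' `R3: A <-> 2 B` in `[-500, 1000]`; `R4: B + C -> ` in `[0, 1000]`
#' (all mmol gDW^-1 h^-1).  Maximizing R4 at steady state gives 10.
#'
#' @return A [cbm_model()].
#' @export
table1_model <- function() {
  cbm_model(list(
    list(id = "R1", stoich = c(A = 1), lb = 5, ub = 5),
    list(id = "R2", stoich = c(C = 1), lb = 0, ub = 20),
    list(id = "R3", stoich = c(A = -1, B = 2), lb = -500, ub = 1000),
    list(id = "R4", stoich = c(B = -1, C = -1), lb = 0, ub = 1000)),
    objective = "R4")
}

#' A small net exercising guarded intensity handlers
#'
#' Event net: `R1: A -> 2 C`, `R2: 2 A + B -> D`.  Intensity net: handler
#' `s1` sets the speed of R1 to twice the concentration of A; handler `s2`
#' sets the speed of R2 to 0 while `[A] < 10`, to `2 [B]` while
#' `10 <= [A] < 30`, and to `4 [B]` above.
#'
#' @return A [flexible_net()].
#' @export
figure1_net <- function() {
  flexible_net(
    places = list(fn_place("A"), fn_place("B"), fn_place("C"), fn_place("D")),
    transitions = list(fn_transition("R1"), fn_transition("R2")),
    event_handlers = list(
      fn_event_handler("v1", "R1", c(A = -1, C = 2)),
      fn_event_handler("v2", "R2", c(A = -2, B = -1, D = 1))),
    intensity_handlers = list(
      fn_intensity_handler("s1", "R1",
                           guards = list(fn_guard(coef = c(A = 2)))),
      fn_intensity_handler("s2", "R2", on = "A", guards = list(
        fn_guard(lo = -Inf, hi = 10, coef = numeric(0), const = 0),
        fn_guard(lo = 10, hi = 30, coef = c(B = 2)),
        fn_guard(lo = 30, hi = Inf, coef = c(B = 4))))))
}

#' Parametric toy producer cell with a closed-form chemostat optimum
#'
#' Three reactions: `GLC_upt` imports glucose (`[0, u_max]`), `GROWTH`
#' consumes `1/k` internal glucose per unit growth flux (so the growth rate
#' is `k` times the glucose devoted to biomass), and `EX_prod` exports the
#' remainder as product.  The internal balance is
#' `u_g = mu / k + v_p`.  In a chemostat at dilution rate D with feed
#' `c_g` (mM), the steady-state optimum of product outflow is
#' \deqn{VP^* = D c_g (1 - D / (k\,u_{max}))} (mM/h) attained at
#' \eqn{X^* = D c_g / u_{max}}, feasible for `0 < D < k * u_max`.
#'
#' @param k biomass yield coefficient (growth flux per unit glucose flux).
#' @param u_max maximal specific glucose uptake (mmol gDW^-1 h^-1).
#' @return A list with `model` (a [cbm_model()]) and `params`.
#' @export
make_toy_producer <- function(k = 0.1, u_max = 10) {
  stopifnot(k > 0, u_max > 0)
  model <- cbm_model(list(
    list(id = "GLC_upt", stoich = c(glc = 1), lb = 0, ub = u_max),
    list(id = "GROWTH", stoich = c(glc = -1 / k), lb = 0, ub = k * u_max),
    list(id = "EX_prod", stoich = c(glc = -1), lb = 0, ub = 1000)),
    objective = "EX_prod")
  list(model = model, params = list(k = k, u_max = u_max))
}

#' Chemostat spec for the toy producer
#'
#' Convenience wrapper wiring the toy producer's transition ids into a
#' [chemostat_spec()].  The molar masses default to glucose/citramalate so
#' toy results are on the same unit scale as the real study.
#'
#' @param c_g feed glucose (g/L).
#' @param D dilution rate (1/h).
#' @param ... passed on to [chemostat_spec()].
#' @export
toy_producer_spec <- function(c_g = 10, D = 0.5, ...) {
  chemostat_spec(c_g = c_g, D = D,
                 substrate_exchange = "GLC_upt",
                 product_exchange = "EX_prod",
                 growth_reaction = "GROWTH", ...)
}

#' Closed-form optimum of the toy producer chemostat
#'
#' @param params list with `k`, `u_max` (see [make_toy_producer()]).
#' @param spec a [chemostat_spec()].
#' @return A list with `VP_mM` (mM/h product outflow), `VP` (g/L/h),
#'   `PS` (1/h), `X_star` (gDW/L) and `feasible`.
#' @export
toy_producer_optimum <- function(params, spec) {
  c_g_mM <- convert_units(spec$c_g, "g_per_L", "mM", spec$mw_substrate)
  mu_max <- params$k * params$u_max
  if (spec$D >= mu_max)
    return(list(VP_mM = NA_real_, VP = NA_real_, PS = NA_real_,
                X_star = NA_real_, feasible = FALSE))
  VP_mM <- spec$D * c_g_mM * (1 - spec$D / mu_max)
  VP <- convert_units(VP_mM, "mM_per_h", "g_per_L_per_h", spec$mw_product)
  list(VP_mM = VP_mM, VP = VP, PS = VP / spec$c_g,
       X_star = spec$D * c_g_mM / params$u_max, feasible = TRUE)
}

#' Brute-force fixed-biomass grid oracle
#'
#' Enumerates the biomass on a uniform grid over `[Xmin, Xmax]`; each grid
#' point makes the bilinear relations linear, so each subproblem is a plain
#' LP.  The best grid point is a lower bound on the true bilinear optimum
#' and converges to it as the grid refines — the counterpart of the
#' region-wise relaxation's upper bound.
#'
#' @param model an [build_integrated_fn()] result.
#' @param objective named numeric over transition ids.
#' @param n_grid number of grid points (default 2001).
#' @return An `fn_solution` with extra fields `X_best` and `grid`
#'   (data frame of X, status, objective).
#' @export
oracle_solve <- function(model, objective, n_grid = 2001) {
  stopifnot(n_grid >= 2)
  cs <- chemostat_steady_state(model)
  Xs <- seq(model$spec$Xmin, model$spec$Xmax, length.out = n_grid)
  best <- NULL; X_best <- NA_real_
  objs <- rep(NA_real_, n_grid); stat <- character(n_grid)
  for (i in seq_along(Xs)) {
    sol <- solve_fixed_biomass(cs, Xs[i], objective, "max")
    stat[i] <- sol$status
    if (sol$status == "optimal") {
      objs[i] <- sol$objective
      if (is.null(best) || sol$objective > best$objective + 1e-12) {
        best <- sol; X_best <- Xs[i]
      }
    }
  }
  if (is.null(best))
    best <- structure(list(status = "infeasible", objective = NA_real_,
                           variables = NULL, fluxes = NULL),
                      class = "fn_solution")
  best$X_best <- X_best
  best$grid <- data.frame(X = Xs, status = stat, objective = objs)
  best
}

#' Random small constraint-based model (for property tests)
#'
#' Generates a connected toy network: a chain of `n_mets` metabolites with a
#' source exchange into the first, a sink exchange out of the last, and
#' `n_rxns` random internal conversions with coefficients in {1, 2}; a
#' fraction of internal reactions is made reversible.  The RNG state is
#' taken from R's global seed, so callers seed before use.
#'
#' @param n_mets,n_rxns network size.
#' @param p_rev probability an internal reaction is reversible.
#' @return A [cbm_model()] with objective `"SINK"`.
#' @export
random_cbm <- function(n_mets = 6, n_rxns = 8, p_rev = 0.4) {
  mets <- paste0("M", seq_len(n_mets))
  rx <- list(
    list(id = "SRC", stoich = stats::setNames(1, mets[1]),
         lb = 0, ub = stats::runif(1, 5, 15)),
    list(id = "SINK", stoich = stats::setNames(-1, mets[n_mets]),
         lb = 0, ub = 1000))
  for (i in seq_len(n_rxns)) {
    from <- sample.int(n_mets - 1L, 1L)
    cand <- seq(from + 1L, n_mets)
    to <- cand[sample.int(length(cand), 1L)]
    st <- stats::setNames(c(-sample(1:2, 1), sample(1:2, 1)),
                          c(mets[from], mets[to]))
    rev <- stats::runif(1) < p_rev
    rx[[length(rx) + 1L]] <- list(
      id = sprintf("R%02d", i), stoich = st,
      lb = if (rev) -stats::runif(1, 1, 20) else 0,
      ub = stats::runif(1, 1, 20))
  }
  cbm_model(rx, objective = "SINK")
}
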