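## Productivity objectives and study drivers.
##
## Volumetric productivity VP (g product / L / h) is the product outflow of
## the tank; productivity on substrate PS = mu * Y_P/S = VP / c_s (1/h)
## weighs the product against the substrate fed.  At steady state mu = D,
## so for fixed feed concentration both are maximized by the same linear
## objective: the flux of the product effluent transition t_cout.

#' Product-per-substrate yield
#'
#' `Y_P/S = flux_P / (D * c_s)`: grams of product made per gram of
#' substrate fed (dimensionless).
#'
#' @param flux_P product formation flux (g/L/h).
#' @param D dilution rate (1/h), positive.
#' @param c_s feed substrate concentration (g/L), positive.
#' @export
substrate_yield <- function(flux_P, D, c_s) {
  if (!is.numeric(D) || D <= 0) stop("D must be positive")
  if (!is.numeric(c_s) || c_s <= 0) stop("c_s must be positive")
  flux_P / (D * c_s)
}

#' Productivity on substrate from volumetric productivity
#'
#' `PS = VP / c_s` (1/h); equivalently `PS = mu * Y_P/S` with `mu = D` at
#' steady state.
#'
#' @param VP volumetric productivity (g/L/h).
#' @param c_s feed substrate concentration (g/L), positive.
#' @export
productivity_on_substrate <- function(VP, c_s) {
  if (!is.numeric(c_s) || c_s <= 0) stop("c_s must be positive")
  VP / c_s
}

#' Relative error of an observation against a prediction
#'
#' `100 * (observed - predicted) / predicted`, in percent — the orientation
#' that matches published model-validation tables (observed in vivo value
#' against the in silico prediction).
#'
#' @param observed,predicted numeric values; `predicted` must be nonzero.
#' @export
relative_error <- function(observed, predicted) {
  if (any(predicted == 0)) stop("relative error undefined for predicted = 0")
  100 * (observed - predicted) / predicted
}

# assemble a productivity_result from an fn_solution of the integrated model
.productivity_result <- function(sol, model, n_regions, mode) {
  spec <- model$spec
  out <- list(status = sol$status, mode = mode, spec = spec,
              n_regions = n_regions,
              VP = NA_real_, PS = NA_real_, Y_PS = NA_real_,
              X_opt = NA_real_, s_c = NA_real_, s_g = NA_real_,
              fluxes = NULL, region = sol$region %||% NA_integer_,
              per_region = sol$per_region)
  if (sol$status == "optimal") {
    v <- sol$variables
    VP_mM <- sol$objective                       # flux of t_cout, mM/h
    out$VP <- convert_units(VP_mM, "mM_per_h", "g_per_L_per_h", spec$mw_product)
    out$PS <- productivity_on_substrate(out$VP, spec$c_g)
    out$Y_PS <- substrate_yield(out$VP, spec$D, spec$c_g)
    out$X_opt <- unname(v["conc.X"])
    out$s_c <- convert_units(unname(v["conc.C"]), "mM", "g_per_L", spec$mw_product)
    out$s_g <- convert_units(unname(v["conc.G"]), "mM", "g_per_L", spec$mw_substrate)
    out$fluxes <- sol$fluxes
  }
  structure(out, class = "productivity_result")
}

#' @export
print.productivity_result <- function(x, ...) {
  cat("Chemostat productivity (", x$mode, " mode)\n", sep = "")
  cat("  feed ", x$spec$c_g, " g/L, D = ", x$spec$D, " /h",
      if (!is.na(x$n_regions)) paste0(", ", x$n_regions, " biomass regions"),
      "\n", sep = "")
  cat("  status: ", x$status, "\n", sep = "")
  if (x$status == "optimal") {
    cat(sprintf("  VP   = %.4f g/L/h\n", x$VP))
    cat(sprintf("  PS   = %.5f 1/h\n", x$PS))
    cat(sprintf("  Y_PS = %.4f g/g\n", x$Y_PS))
    cat(sprintf("  biomass X = %.4f gDW/L\n", x$X_opt))
    cat(sprintf("  tank product  s_c = %.4f g/L\n", x$s_c))
    cat(sprintf("  residual substrate s_g = %.4f g/L\n", x$s_g))
  }
  invisible(x)
}

#' @export
summary.productivity_result <- function(object, ...) {
  print(object)
  if (object$status == "optimal" && !is.null(object$fluxes)) {
    cat("  cell exchange fluxes (mmol/gDW/h):\n")
    ids <- c(object$spec$substrate_exchange, object$spec$growth_reaction,
             object$spec$product_exchange)
    for (id in ids)
      cat(sprintf("    %-16s %10.5f\n", id, object$fluxes[[id]]))
  }
  invisible(object)
}

# accept a cbm_model or a flexible_net for the cell side
.as_cell_net <- function(cell) {
  if (inherits(cell, "cbm_model")) cbm_to_fn(cell)
  else if (inherits(cell, "flexible_net")) cell
  else stop("cell model must be a cbm_model or flexible_net")
}

#' Maximize steady-state product productivity
#'
#' Builds the integrated cell+tank net, imposes the chemostat steady state
#' (mu = D, tank balances), relaxes the three bilinear interface relations
#' over a biomass partition and maximizes the product outflow flux
#' (`t_cout`, mM/h) region by region.  For a fixed feed concentration this
#' simultaneously maximizes VP and PS.
#'
#' @param cell a [cbm_model()] or cell [flexible_net()].
#' @param spec a [chemostat_spec()].
#' @param n_regions number of biomass regions (default 100).
#' @param partition optional explicit [partition_biomass()] overriding
#'   `n_regions`.
#' @return A `productivity_result` (status `"infeasible"` under washout).
#' @export
maximize_productivity <- function(cell, spec, n_regions = 100,
                                  partition = NULL) {
  model <- build_integrated_fn(.as_cell_net(cell), spec)
  if (is.null(partition))
    partition <- partition_biomass(spec$Xmin, spec$Xmax, n_regions)
  sol <- solve_piecewise(model, partition, c(t_cout = 1), "max")
  .productivity_result(sol, model, partition$n, "optimization")
}

#' Predict tank concentrations at a measured biomass
#'
#' Fixes the cell density X to a measured value, which restores the exact
#' bilinear coupling (each `w = v * X` becomes linear), and maximizes the
#' product outflow under mu = D.  Returns the predicted tank product
#' concentration and residual substrate — the in-silico counterparts of
#' chemostat measurements.
#'
#' @param cell a [cbm_model()] or cell [flexible_net()].
#' @param spec a [chemostat_spec()].
#' @param X_measured measured biomass (gDW/L) within `[Xmin, Xmax]`.
#' @return A `productivity_result` with `mode = "prediction"`.
#' @export
predict_concentrations <- function(cell, spec, X_measured) {
  if (X_measured < spec$Xmin || X_measured > spec$Xmax)
    stop("X_measured outside [Xmin, Xmax]")
  model <- build_integrated_fn(.as_cell_net(cell), spec)
  sol <- solve_fixed_biomass(model, X_measured, c(t_cout = 1), "max")
  res <- .productivity_result(sol, model, NA_integer_, "prediction")
  if (res$status == "optimal") res$X_opt <- X_measured
  res
}

#' Sweep feed concentration and dilution rate
#'
#' One [maximize_productivity()] call per grid point; rows are ordered feed
#' concentration major, dilution rate minor.  Infeasible points (washout)
#' are kept with NA numeric fields and status `"infeasible"`.
#'
#' @param cell a [cbm_model()] or cell [flexible_net()].
#' @param c_g_values,D_values numeric grids (non-empty).
#' @param n_regions biomass regions per point.
#' @param spec_fn function `(c_g, D) -> chemostat_spec`; defaults to
#'   [toy_producer_spec()]-style wiring via `...` passed to
#'   [chemostat_spec()].
#' @param ... extra arguments for [chemostat_spec()] (exchange ids etc.)
#'   when `spec_fn` is not supplied.
#' @return A data frame of class `sweep_table` with columns `c_g`, `D`,
#'   `VP`, `PS`, `X_opt`, `status`.
#' @export
sweep_grid <- function(cell, c_g_values, D_values, n_regions = 100,
                       spec_fn = NULL, ...) {
  stopifnot(length(c_g_values) >= 1, length(D_values) >= 1)
  if (is.null(spec_fn))
    spec_fn <- function(c_g, D) chemostat_spec(c_g = c_g, D = D, ...)
  grid <- expand.grid(D = D_values, c_g = c_g_values)[, c("c_g", "D")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- maximize_productivity(cell, spec_fn(grid$c_g[i], grid$D[i]),
                               n_regions = n_regions)
    data.frame(c_g = grid$c_g[i], D = grid$D[i],
               VP = r$VP, PS = r$PS, X_opt = r$X_opt, status = r$status)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Productivity versus number of biomass regions
#'
#' Recomputes the maximal PS for each region count.  With nested uniform
#' partitions (e.g. n, 2n, 4n, ...) the sequence is non-increasing: refining
#' a partition can only tighten the relaxation.
#'
#' @param cell a [cbm_model()] or cell [flexible_net()].
#' @param spec a [chemostat_spec()].
#' @param n_values positive integer vector of region counts.
#' @return A data frame with columns `n`, `PS`, `VP`, `status`.
#' @export
region_convergence <- function(cell, spec, n_values) {
  stopifnot(all(n_values >= 1))
  rows <- lapply(n_values, function(n) {
    r <- maximize_productivity(cell, spec, n_regions = n)
    data.frame(n = n, PS = r$PS, VP = r$VP, status = r$status)
  })
  do.call(rbind, rows)
}
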