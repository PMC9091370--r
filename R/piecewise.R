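## Region-wise linear relaxation of the bilinear interface relations.
##
## Each interface relation w = v * X (tank flux = specific rate x biomass)
## is replaced, inside a biomass region [X_{i-1}, X_i], by the bracketing
## inequalities X_{i-1} * v <= w <= X_i * v together with X in
## [X_{i-1}, X_i].  Every exact solution of the bilinear system is feasible
## in the region holding its X, so the maximum over regions is an upper
## bound on the true optimum that tightens as the partition refines.  The
## regions are solved as independent LPs and the best objective wins.

#' Partition the biomass range
#'
#' @param Xmin,Xmax biomass bounds (gDW/L), `Xmin < Xmax`.
#' @param n number of regions (ignored when `breakpoints` is given).
#' @param breakpoints optional explicit strictly increasing breakpoint
#'   vector; its range must be `[Xmin, Xmax]`.  Regions need not be evenly
#'   spaced.
#' @return An object of class `biomass_partition` with fields `breakpoints`
#'   (length `n + 1`) and `n`.
#' @export
partition_biomass <- function(Xmin, Xmax, n = 100, breakpoints = NULL) {
  stopifnot(is.numeric(Xmin), is.numeric(Xmax), Xmin < Xmax)
  if (is.null(breakpoints)) {
    stopifnot(n >= 1)
    breakpoints <- seq(Xmin, Xmax, length.out = n + 1)
  } else {
    breakpoints <- as.numeric(breakpoints)
    if (any(diff(breakpoints) <= 0))
      stop("breakpoints must be strictly increasing")
    if (abs(breakpoints[1] - Xmin) > 1e-12 ||
        abs(breakpoints[length(breakpoints)] - Xmax) > 1e-12)
      stop("breakpoints must start at Xmin and end at Xmax")
  }
  structure(list(breakpoints = breakpoints, n = length(breakpoints) - 1L),
            class = "biomass_partition")
}

#' @export
print.biomass_partition <- function(x, ...) {
  cat("Biomass partition: ", x$n, " regions over [",
      x$breakpoints[1], ", ", x$breakpoints[length(x$breakpoints)],
      "] gDW/L\n", sep = "")
  invisible(x)
}

# region-wise extra rows for every registered bilinear term
.region_rows <- function(cs, Xlo, Xhi) {
  nv <- length(cs$vars)
  vi <- stats::setNames(seq_len(nv), cs$vars)
  A <- NULL; b <- numeric(0)
  for (bl in cs$bilinear) {
    r1 <- numeric(nv); r1[vi[bl$w]] <- -1; r1[vi[bl$v]] <- Xlo  # Xlo*v <= w
    r2 <- numeric(nv); r2[vi[bl$w]] <- 1;  r2[vi[bl$v]] <- -Xhi # w <= Xhi*v
    A <- rbind(A, r1, r2); b <- c(b, 0, 0)
  }
  list(A = A, b = b)
}

#' Build the LP of one biomass region
#'
#' The chemostat steady-state system with the biomass concentration clamped
#' to region `i` and every bilinear term `w = v * X` bracketed by
#' `[X_{i-1} * v, X_i * v]` (the same partition serves all interface
#' handlers, since all involve X).
#'
#' @param model an [build_integrated_fn()] result (or an `fn_constraints`
#'   system already containing the steady-state rows).
#' @param partition a [biomass_partition()].
#' @param i region index, `1 <= i <= n`.
#' @param objective named numeric over transition ids.
#' @return A list of class `region_problem` with the assembled constraint
#'   pieces, ready for the LP solver.
#' @export
region_problem <- function(model, partition, i, objective) {
  stopifnot(inherits(partition, "biomass_partition"),
            i >= 1, i <= partition$n)
  cs <- if (inherits(model, "fn_constraints")) model
        else chemostat_steady_state(model)
  Xlo <- partition$breakpoints[i]
  Xhi <- partition$breakpoints[i + 1]
  rows <- .region_rows(cs, Xlo, Xhi)
  lb <- cs$lb; ub <- cs$ub
  xv <- grep("^conc\\.", cs$vars, value = TRUE)
  Xvars <- unique(vapply(cs$bilinear, `[[`, character(1), "X"))
  for (v in Xvars) {            # clamp X to the region (closed interval)
    lb[v] <- max(lb[v], Xlo)
    ub[v] <- min(ub[v], Xhi)
  }
  structure(list(cs = cs, i = i, Xlo = Xlo, Xhi = Xhi,
                 extra_le = rows$A, extra_ble = rows$b,
                 lb = lb, ub = ub, objective = objective),
            class = "region_problem")
}

#' Solve the region-wise relaxation and take the best region
#'
#' Each region's LP is solved independently; infeasible regions are skipped
#' and the returned solution is the best objective over the feasible ones
#' (ties go to the lowest region index, for determinism).  If every region
#' is infeasible the result has status `"infeasible"` (e.g. washout:
#' dilution rate above the maximal growth rate with a positive biomass
#' floor).
#'
#' @param model an [build_integrated_fn()] result or prepared
#'   `fn_constraints`.
#' @param partition a [biomass_partition()].
#' @param objective named numeric over transition ids.
#' @param sense `"max"` or `"min"`.
#' @return An `fn_solution` with extra fields `region` (winning index) and
#'   `per_region` (data frame of region index, status, objective).
#' @export
solve_piecewise <- function(model, partition, objective,
                            sense = c("max", "min")) {
  sense <- match.arg(sense)
  cs <- if (inherits(model, "fn_constraints")) model
        else chemostat_steady_state(model)
  if (!length(cs$bilinear))
    warning("no bilinear terms registered; a single LP would be exact")
  best <- NULL
  tab <- data.frame(region = seq_len(partition$n),
                    status = NA_character_, objective = NA_real_)
  for (i in seq_len(partition$n)) {
    rp <- region_problem(cs, partition, i, objective)
    sol <- .solve_constraints(cs, objective, sense,
                              extra_le = rp$extra_le, extra_ble = rp$extra_ble,
                              lb = rp$lb, ub = rp$ub)
    tab$status[i] <- sol$status
    if (sol$status == "optimal") {
      tab$objective[i] <- sol$objective
      better <- is.null(best) ||
        (sense == "max" && sol$objective > best$objective + 1e-12) ||
        (sense == "min" && sol$objective < best$objective - 1e-12)
      if (better) { best <- sol; best$region <- i }
    }
  }
  if (is.null(best))
    best <- structure(list(status = "infeasible", objective = NA_real_,
                           variables = NULL, fluxes = NULL, region = NA_integer_),
                      class = "fn_solution")
  best$per_region <- tab
  best
}

#' Solve the integrated model at a fixed biomass
#'
#' With the cell density X fixed, every bilinear relation `w = v * X`
#' becomes linear and the steady-state problem is a single exact LP.  Used
#' by the fixed-biomass prediction mode and by the brute-force grid oracle.
#'
#' @param model an [build_integrated_fn()] result or prepared
#'   `fn_constraints`.
#' @param X biomass value (gDW/L), inside the spec's `[Xmin, Xmax]`.
#' @param objective named numeric over transition ids.
#' @param sense `"max"` or `"min"`.
#' @return An `fn_solution`.
#' @export
solve_fixed_biomass <- function(model, X, objective, sense = c("max", "min")) {
  sense <- match.arg(sense)
  cs <- if (inherits(model, "fn_constraints")) model
        else chemostat_steady_state(model)
  nv <- length(cs$vars)
  vi <- stats::setNames(seq_len(nv), cs$vars)
  A <- NULL; b <- numeric(0)
  lb <- cs$lb; ub <- cs$ub
  for (bl in cs$bilinear) {
    r <- numeric(nv); r[vi[bl$w]] <- 1; r[vi[bl$v]] <- -X  # w = X * v
    A <- rbind(A, r); b <- c(b, 0)
    if (X < lb[bl$X] - 1e-9 || X > ub[bl$X] + 1e-9)
      stop("fixed biomass ", X, " outside the admissible range [",
           lb[bl$X], ", ", ub[bl$X], "]")
    lb[bl$X] <- X; ub[bl$X] <- X
  }
  .solve_constraints(cs, objective, sense,
                     extra_eq = A, extra_beq = b, lb = lb, ub = ub)
}
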