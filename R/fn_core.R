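## Flexible Nets: data model and steady-state constraint semantics.
##
## A Flexible Net is a tripartite structure.  Places hold state (metabolite or
## tank-species concentrations), transitions carry processes (reactions,
## in/out flows) and handlers connect the two:
##   * event handlers encode stoichiometry -- how much of each place one unit
##     of a transition's occurrence consumes or produces;
##   * intensity handlers encode kinetics -- how concentrations set transition
##     speeds, possibly guarded (different linear relations in different
##     concentration regions) or bilinear (rate = flux x concentration, the
##     cell/tank interface case).
## At steady state every place's net flow is zero; the resulting linear
## system, plus the default-intensity bounds lambda0, is the LP that
## optimize_fn() solves.

#' Create a place
#'
#' @param id place identifier (unique within a net).
#' @param role `"metabolite"` or `"species"` (macroscopic tank species).
#' @param units concentration unit tag (`"mM"`, `"gDW_per_L"` or `""`).
#' @param conc_lo,conc_hi admissible concentration range; used for the
#'   biomass place whose range the piecewise relaxation partitions.
#' @return An object of class `fn_place`.
#' @export
fn_place <- function(id, role = "metabolite", units = "mM",
                     conc_lo = 0, conc_hi = Inf) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            conc_lo >= 0, conc_lo <= conc_hi)
  structure(list(id = id, role = role, units = units,
                 conc_lo = conc_lo, conc_hi = conc_hi),
            class = "fn_place")
}

#' Create a transition
#'
#' `l0_lo`/`l0_hi` are the default-intensity (lambda0) bounds: the intrinsic
#' flux range of the transition before any intensity handler contributes.
#' A transition with no handler has flux exactly in `[l0_lo, l0_hi]`; when
#' unset both default to 0, so a handler-driven transition's flux equals the
#' intensity its handlers produce.
#'
#' @param id transition identifier.
#' @param l0_lo,l0_hi lambda0 bounds; `0 <= l0_lo <= l0_hi` (fluxes are
#'   non-negative in a Flexible Net -- reversible reactions must be unfolded).
#' @return An object of class `fn_transition`.
#' @export
fn_transition <- function(id, l0_lo = 0, l0_hi = 0) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.na(l0_lo) || is.na(l0_hi) || l0_lo < 0 || l0_lo > l0_hi)
    stop("transition '", id, "': need 0 <= l0_lo <= l0_hi")
  structure(list(id = id, l0_lo = as.numeric(l0_lo), l0_hi = as.numeric(l0_hi)),
            class = "fn_transition")
}

#' Create an event handler
#'
#' The signed coefficients give the change of each incident place per unit
#' occurrence of the handled transition: negative = consumed, positive =
#' produced.  One handler per reaction, as in the net encoding of a
#' constraint-based model.
#'
#' @param id handler identifier.
#' @param transition id of the transition whose occurrence drives the handler.
#' @param stoich named numeric vector, place id -> signed coefficient.
#' @return An object of class `fn_event_handler`.
#' @export
fn_event_handler <- function(id, transition, stoich) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(transition), length(transition) == 1L,
            is.numeric(stoich), all(is.finite(stoich)))
  if (length(stoich) && (is.null(names(stoich)) || !all(nzchar(names(stoich)))))
    stop("event-handler stoichiometry must be named by place id")
  structure(list(id = id, transition = transition, stoich = stoich),
            class = "fn_event_handler")
}

#' Create a guard for an intensity handler
#'
#' A guard is active when the observed concentration lies in `[lo, hi)`
#' (the last guard of a handler is closed at its upper end).  While active it
#' produces the intensity `sum(coef * conc) + const`; when `coef_hi` is given
#' the produced intensity may be anything in the interval between the two
#' linear forms (uncertain kinetics).
#'
#' @param lo,hi activation interval on the observed concentration.
#' @param coef named numeric vector over place ids (may be empty for a
#'   constant rate).
#' @param const additive constant.
#' @param coef_hi optional named numeric giving the upper linear form.
#' @return An object of class `fn_guard`.
#' @export
fn_guard <- function(lo = -Inf, hi = Inf, coef = numeric(0), const = 0,
                     coef_hi = NULL) {
  stopifnot(lo < hi, is.numeric(coef), is.numeric(const))
  if (length(coef) && is.null(names(coef)))
    stop("guard coefficients must be named by place id")
  structure(list(lo = lo, hi = hi, coef = coef, const = const,
                 coef_hi = coef_hi),
            class = "fn_guard")
}

#' Create an intensity handler
#'
#' Two kinds are supported.  Linear handlers (`type = "linear"`) carry one or
#' more guards on one observed place; with a single all-covering guard the
#' handler is unguarded.  Bilinear handlers (`type = "bilinear"`) produce
#' `rate = flux[source] * conc[scale]` -- the cell/tank interface relations
#' (tank flux = specific exchange rate x cell density).  Bilinear relations
#' are not linear constraints; they are collected into a registry and handled
#' by the piecewise relaxation or by fixing the scaling concentration.
#'
#' @param id handler identifier.
#' @param transition id of the transition that receives the intensity.
#' @param guards list of [fn_guard()] objects (linear handlers).
#' @param on id of the observed place the guards test (required when any
#'   guard has a finite interval).
#' @param type `"linear"` or `"bilinear"`.
#' @param source for bilinear handlers, the transition whose flux is scaled.
#' @param scale for bilinear handlers, the place whose concentration scales.
#' @return An object of class `fn_intensity_handler`.
#' @export
fn_intensity_handler <- function(id, transition, guards = NULL, on = NA_character_,
                                 type = c("linear", "bilinear"),
                                 source = NULL, scale = NULL) {
  type <- match.arg(type)
  if (type == "bilinear") {
    stopifnot(is.character(source), is.character(scale))
    return(structure(list(id = id, transition = transition, type = "bilinear",
                          source = source, scale = scale),
                     class = "fn_intensity_handler"))
  }
  stopifnot(is.list(guards), length(guards) >= 1L,
            all(vapply(guards, inherits, logical(1), "fn_guard")))
  lo <- vapply(guards, `[[`, numeric(1), "lo")
  hi <- vapply(guards, `[[`, numeric(1), "hi")
  ord <- order(lo)
  guards <- guards[ord]; lo <- lo[ord]; hi <- hi[ord]
  if (length(guards) > 1L) {
    if (is.na(on))
      stop("guarded handler '", id, "' needs an observed place ('on')")
    if (any(abs(hi[-length(hi)] - lo[-1L]) > 1e-12))
      stop("guard intervals of handler '", id,
           "' must be disjoint and contiguous (cover the admissible range)")
  }
  structure(list(id = id, transition = transition, type = "linear",
                 on = on, guards = guards),
            class = "fn_intensity_handler")
}

#' Assemble a Flexible Net
#'
#' Validates the tripartite structure: handlers reference only declared
#' places and transitions, and ids are unique within each vertex class.
#'
#' @param places list of [fn_place()] objects.
#' @param transitions list of [fn_transition()] objects.
#' @param event_handlers list of [fn_event_handler()] objects.
#' @param intensity_handlers list of [fn_intensity_handler()] objects.
#' @return An object of class `flexible_net`.
#' @export
flexible_net <- function(places, transitions, event_handlers = list(),
                         intensity_handlers = list()) {
  stopifnot(all(vapply(places, inherits, logical(1), "fn_place")),
            all(vapply(transitions, inherits, logical(1), "fn_transition")),
            all(vapply(event_handlers, inherits, logical(1), "fn_event_handler")),
            all(vapply(intensity_handlers, inherits, logical(1),
                       "fn_intensity_handler")))
  pid <- vapply(places, `[[`, character(1), "id")
  tid <- vapply(transitions, `[[`, character(1), "id")
  if (anyDuplicated(pid)) stop("duplicate place ids")
  if (anyDuplicated(tid)) stop("duplicate transition ids")
  hid <- c(vapply(event_handlers, `[[`, character(1), "id"),
           vapply(intensity_handlers, `[[`, character(1), "id"))
  if (anyDuplicated(hid)) stop("duplicate handler ids")
  for (eh in event_handlers) {
    if (!eh$transition %in% tid)
      stop("event handler '", eh$id, "': unknown transition '", eh$transition, "'")
    bad <- setdiff(names(eh$stoich), pid)
    if (length(bad))
      stop("event handler '", eh$id, "': unknown place(s) ",
           paste(bad, collapse = ", "))
  }
  for (ih in intensity_handlers) {
    if (!ih$transition %in% tid)
      stop("intensity handler '", ih$id, "': unknown transition '",
           ih$transition, "'")
    if (ih$type == "bilinear") {
      if (!ih$source %in% tid)
        stop("intensity handler '", ih$id, "': unknown source transition")
      if (!ih$scale %in% pid)
        stop("intensity handler '", ih$id, "': unknown scale place")
    } else {
      if (!is.na(ih$on) && !ih$on %in% pid)
        stop("intensity handler '", ih$id, "': unknown observed place")
      refs <- unique(unlist(lapply(ih$guards, function(g)
        c(names(g$coef), names(g$coef_hi)))))
      bad <- setdiff(refs, pid)
      if (length(bad))
        stop("intensity handler '", ih$id, "': unknown place(s) ",
             paste(bad, collapse = ", "))
    }
  }
  names(places) <- pid
  names(transitions) <- tid
  names(event_handlers) <-
    vapply(event_handlers, `[[`, character(1), "id")
  names(intensity_handlers) <-
    vapply(intensity_handlers, `[[`, character(1), "id")
  structure(list(places = places, transitions = transitions,
                 event_handlers = event_handlers,
                 intensity_handlers = intensity_handlers),
            class = "flexible_net")
}

#' @export
print.flexible_net <- function(x, ...) {
  nb <- sum(vapply(x$intensity_handlers, function(h) h$type == "bilinear",
                   logical(1)))
  cat("Flexible net: ", length(x$places), " places, ",
      length(x$transitions), " transitions, ",
      length(x$event_handlers), " event handlers, ",
      length(x$intensity_handlers), " intensity handlers",
      if (nb) paste0(" (", nb, " bilinear)"), "\n", sep = "")
  invisible(x)
}

#' Apply an event handler to an occurrence amount
#'
#' Returns the signed change of every incident place when the handled
#' transition occurs `x` times (at steady state, `x` is a rate).
#'
#' @param handler an [fn_event_handler()].
#' @param x occurrence amount, `x >= 0`.
#' @return Named numeric vector of place deltas.
#' @export
apply_event_handler <- function(handler, x) {
  stopifnot(inherits(handler, "fn_event_handler"))
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop("occurrence amount x must be a non-negative number")
  handler$stoich * x
}

#' Find the active guard of an intensity handler
#'
#' Exactly one guard is active at any admissible state: the one whose
#' half-open interval `[lo, hi)` (closed at the top for the last guard)
#' contains the observed concentration.
#'
#' @param handler an [fn_intensity_handler()] of type `"linear"`.
#' @param state named numeric vector of place concentrations; must contain
#'   the observed place and every place the active guard's relation uses.
#' @return A list with `index` (guard position), `rate` (produced intensity;
#'   for interval relations a length-2 vector `c(lo, hi)`).
#' @export
active_region <- function(handler, state) {
  stopifnot(inherits(handler, "fn_intensity_handler"))
  if (handler$type != "linear")
    stop("active_region applies to linear (possibly guarded) handlers")
  gs <- handler$guards
  if (length(gs) == 1L) {
    idx <- 1L
  } else {
    obs <- state[[handler$on]]
    if (is.null(obs) || is.na(obs))
      stop("state lacks observed place '", handler$on, "'")
    lo <- vapply(gs, `[[`, numeric(1), "lo")
    hi <- vapply(gs, `[[`, numeric(1), "hi")
    idx <- which(obs >= lo & (obs < hi | (obs <= hi & seq_along(gs) == length(gs))))
    if (length(idx) != 1L)
      stop("state ", obs, " outside the guards of handler '", handler$id,
           "' (coverage violation)")
  }
  g <- gs[[idx]]
  eval_form <- function(coef, const) {
    if (!length(coef)) return(const)
    miss <- setdiff(names(coef), names(state))
    if (length(miss))
      stop("state lacks place(s) ", paste(miss, collapse = ", "))
    sum(coef * state[names(coef)]) + const
  }
  rate <- eval_form(g$coef, g$const)
  if (!is.null(g$coef_hi))
    rate <- c(rate, eval_form(g$coef_hi, g$const))
  list(index = idx, rate = rate)
}

## ---- steady-state constraint system ---------------------------------------

# Variables of the LP, in order:
#   flux.<t>   one per transition (steady-state speed, >= 0)
#   lam0.<t>   only for transitions that have intensity handlers AND a
#              non-degenerate lambda0 interval
#   rate.<h>   one per intensity handler (its produced intensity)
#   conc.<p>   one per place referenced by any intensity relation
# Rows:
#   per place with event arcs:     sum_eh stoich[p] * flux[t(eh)]  = 0
#   per handler-driven transition: flux[t] - lam0 - sum rate[h]    = 0
#   per linear unguarded handler:  rate[h] - coef . conc           = const
#     (interval relations give two <= rows instead)
#   bilinear handlers contribute no rows; they are recorded in the registry
#   as (rate variable, source flux variable, scale concentration variable).

#' Build the steady-state constraint system of a Flexible Net
#'
#' Encodes zero net flow through every place, the lambda0 flux bounds, and
#' the relations of unguarded linear intensity handlers.  Bilinear interface
#' relations are left symbolic in the `bilinear` registry for the piecewise
#' relaxation (or for fixed-biomass solving).  Handlers with more than one
#' guard cannot be expressed in a single LP; nets containing them must be
#' solved region by region.
#'
#' @param net a [flexible_net()].
#' @return An object of class `fn_constraints`: a list with `vars`, `lb`,
#'   `ub`, `A_eq`, `b_eq`, `A_le`, `b_le`, `bilinear` and the source `net`.
#' @export
steady_state_constraints <- function(net) {
  stopifnot(inherits(net, "flexible_net"))
  tid <- names(net$transitions)
  ihs <- net$intensity_handlers

  for (ih in ihs)
    if (ih$type == "linear" && length(ih$guards) > 1L)
      stop("handler '", ih$id, "' is guarded; a single steady-state LP ",
           "cannot express guards -- solve region-wise instead")

  # which places need concentration variables
  conc_places <- character(0)
  for (ih in ihs) {
    if (ih$type == "bilinear") conc_places <- c(conc_places, ih$scale)
    else conc_places <- c(conc_places,
                          unlist(lapply(ih$guards, function(g)
                            c(names(g$coef), names(g$coef_hi)))))
  }
  conc_places <- unique(conc_places)

  handlers_of <- split(ihs, vapply(ihs, `[[`, character(1), "transition"))
  driven <- names(handlers_of)   # transitions with intensity handlers
  lam0_var <- vapply(net$transitions[driven], function(tr)
    tr$l0_hi > tr$l0_lo, logical(1))

  vars <- c(paste0("flux.", tid),
            if (any(lam0_var)) paste0("lam0.", driven[lam0_var]),
            if (length(ihs)) paste0("rate.", names(ihs)),
            if (length(conc_places)) paste0("conc.", conc_places))
  nv <- length(vars)
  vi <- stats::setNames(seq_len(nv), vars)

  lb <- stats::setNames(rep(0, nv), vars)
  ub <- stats::setNames(rep(Inf, nv), vars)
  for (t in tid) {
    tr <- net$transitions[[t]]
    if (!t %in% driven) {               # pure lambda0 transition
      lb[paste0("flux.", t)] <- tr$l0_lo
      ub[paste0("flux.", t)] <- tr$l0_hi
    }
  }
  for (t in driven[lam0_var]) {
    tr <- net$transitions[[t]]
    lb[paste0("lam0.", t)] <- tr$l0_lo
    ub[paste0("lam0.", t)] <- tr$l0_hi
  }
  for (p in conc_places) {
    pl <- net$places[[p]]
    lb[paste0("conc.", p)] <- pl$conc_lo
    ub[paste0("conc.", p)] <- pl$conc_hi
  }

  A_eq <- NULL; b_eq <- numeric(0)
  A_le <- NULL; b_le <- numeric(0)
  row <- function() numeric(nv)
  add_eq <- function(r, b) { A_eq <<- rbind(A_eq, r); b_eq <<- c(b_eq, b) }
  add_le <- function(r, b) { A_le <<- rbind(A_le, r); b_le <<- c(b_le, b) }

  # place balances
  arcs <- list()
  for (eh in net$event_handlers)
    for (p in names(eh$stoich))
      arcs[[p]] <- c(arcs[[p]],
                     stats::setNames(eh$stoich[[p]], eh$transition))
  for (p in names(arcs)) {
    r <- row()
    for (k in seq_along(arcs[[p]])) {
      t <- names(arcs[[p]])[k]
      r[vi[paste0("flux.", t)]] <- r[vi[paste0("flux.", t)]] + arcs[[p]][k]
    }
    add_eq(r, 0)
  }

  # flux composition for handler-driven transitions
  for (t in driven) {
    tr <- net$transitions[[t]]
    r <- row()
    r[vi[paste0("flux.", t)]] <- 1
    rhs <- 0
    if (tr$l0_hi > tr$l0_lo) r[vi[paste0("lam0.", t)]] <- -1 else rhs <- tr$l0_lo
    for (ih in handlers_of[[t]]) r[vi[paste0("rate.", ih$id)]] <- -1
    add_eq(r, rhs)
  }

  # handler relations + bilinear registry
  bilinear <- list()
  for (ih in ihs) {
    rv <- paste0("rate.", ih$id)
    if (ih$type == "bilinear") {
      bilinear[[ih$id]] <- list(w = rv,
                                v = paste0("flux.", ih$source),
                                X = paste0("conc.", ih$scale))
      next
    }
    g <- ih$guards[[1L]]
    r <- row(); r[vi[rv]] <- 1
    for (p in names(g$coef)) r[vi[paste0("conc.", p)]] <- -g$coef[[p]]
    if (is.null(g$coef_hi)) {
      add_eq(r, g$const)
    } else {
      add_le(-r, -g$const)              # rate >= lower form
      r2 <- row(); r2[vi[rv]] <- 1
      for (p in names(g$coef_hi)) r2[vi[paste0("conc.", p)]] <- -g$coef_hi[[p]]
      add_le(r2, g$const)               # rate <= upper form
    }
  }

  if (is.null(A_eq)) A_eq <- matrix(0, 0, nv)
  if (is.null(A_le)) A_le <- matrix(0, 0, nv)
  colnames(A_eq) <- vars; colnames(A_le) <- vars
  structure(list(vars = vars, lb = lb, ub = ub,
                 A_eq = A_eq, b_eq = b_eq, A_le = A_le, b_le = b_le,
                 bilinear = bilinear, net = net),
            class = "fn_constraints")
}

# objective over transition fluxes -> coefficient vector over cs$vars
.objective_vector <- function(cs, objective) {
  stopifnot(is.numeric(objective), !is.null(names(objective)))
  obj <- stats::setNames(rep(0, length(cs$vars)), cs$vars)
  for (t in names(objective)) {
    v <- paste0("flux.", t)
    if (!v %in% cs$vars)
      stop("objective references unknown transition '", t, "'")
    obj[v] <- obj[v] + objective[[t]]
  }
  obj
}

# Solve an fn_constraints system (must have no unresolved bilinear terms
# unless `extra_*` rows linearize them).
.solve_constraints <- function(cs, objective, sense = c("max", "min"),
                               extra_eq = NULL, extra_beq = NULL,
                               extra_le = NULL, extra_ble = NULL,
                               lb = NULL, ub = NULL) {
  sense <- match.arg(sense)
  obj <- .objective_vector(cs, objective)
  res <- solve_lp(obj,
                  A_eq = rbind(cs$A_eq, extra_eq),
                  b_eq = c(cs$b_eq, extra_beq),
                  A_le = rbind(cs$A_le, extra_le),
                  b_le = c(cs$b_le, extra_ble),
                  lb = if (is.null(lb)) cs$lb else lb,
                  ub = if (is.null(ub)) cs$ub else ub,
                  maximize = sense == "max")
  sol <- list(status = res$status, objective = res$objective,
              variables = NULL, fluxes = NULL)
  if (res$status == "optimal") {
    x <- stats::setNames(res$x, cs$vars)
    sol$variables <- x
    fl <- x[startsWith(cs$vars, "flux.")]
    names(fl) <- sub("^flux\\.", "", names(fl))
    sol$fluxes <- fl
  }
  structure(sol, class = "fn_solution")
}

#' Optimize a Flexible Net at steady state
#'
#' Maximizes or minimizes a linear objective over transition fluxes subject
#' to the steady-state constraint system.  The net must not contain guarded
#' or bilinear handlers (those are handled by [solve_piecewise()] and
#' [solve_fixed_biomass()]).  With a net obtained from a constraint-based
#' model via [cbm_to_fn()] this is exactly flux balance analysis.
#'
#' @param net a [flexible_net()] (or an `fn_constraints` system).
#' @param objective named numeric vector: transition id -> coefficient.
#' @param sense `"max"` or `"min"`.
#' @return An `fn_solution`: list with `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`), `objective`, `variables`, and `fluxes` (named by
#'   transition).
#' @examples
#' net <- cbm_to_fn(table1_model())
#' optimize_fn(net, c(R4 = 1))$objective   # 10
#' @export
optimize_fn <- function(net, objective, sense = c("max", "min")) {
  cs <- if (inherits(net, "fn_constraints")) net else steady_state_constraints(net)
  if (length(cs$bilinear))
    stop("net has bilinear interface handlers; use solve_piecewise() or ",
         "solve_fixed_biomass()")
  .solve_constraints(cs, objective, sense)
}

#' @export
print.fn_solution <- function(x, ...) {
  cat("Flexible-net steady-state solution\n")
  cat("  status:    ", x$status, "\n")
  if (x$status == "optimal") {
    cat("  objective: ", format(x$objective, digits = 8), "\n")
    if (!is.null(x$region)) cat("  region:    ", x$region, "\n")
    nf <- length(x$fluxes)
    show <- utils::head(x$fluxes[order(-abs(x$fluxes))], 8L)
    cat("  largest fluxes of", nf, "transitions:\n")
    for (i in seq_along(show))
      cat(sprintf("    %-18s %12.6g\n", names(show)[i], show[i]))
  }
  invisible(x)
}

#' Flux variability over a Flexible Net
#'
#' Minimum and maximum achievable steady-state flux of each requested
#' transition (the net analogue of flux-variability analysis).
#'
#' @param net a [flexible_net()] without bilinear/guarded handlers.
#' @param transitions transition ids (default: all).
#' @return A data frame with columns `transition`, `min`, `max`.
#' @export
flux_variability <- function(net, transitions = NULL) {
  cs <- steady_state_constraints(net)
  if (is.null(transitions)) transitions <- names(cs$net$transitions)
  out <- data.frame(transition = transitions,
                    min = NA_real_, max = NA_real_)
  for (i in seq_along(transitions)) {
    o <- stats::setNames(1, transitions[i])
    lo <- .solve_constraints(cs, o, "min")
    hi <- .solve_constraints(cs, o, "max")
    out$min[i] <- if (lo$status == "optimal") lo$objective else NA_real_
    out$max[i] <- if (hi$status == "optimal") hi$objective else
      if (hi$status == "unbounded") Inf else NA_real_
  }
  out
}
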