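# Independent oracles used across tests.
#
# fba_direct() formulates flux balance analysis from the model tuple itself
# (stoichiometric matrix, native signed bounds -- no unfolding, no net
# construction) and solves it with pracma::linprog, a separate simplex
# implementation from the package's boot-based solver.  It shares no code
# path with optimize_fn().

fba_direct <- function(model, objective, sense = "max") {
  rid <- names(model$reactions)
  mets <- model$metabolites
  S <- matrix(0, length(mets), length(rid), dimnames = list(mets, rid))
  for (r in model$reactions)
    S[names(r$stoich), r$id] <- r$stoich
  lb <- vapply(model$reactions, `[[`, numeric(1), "lb")
  ub <- vapply(model$reactions, `[[`, numeric(1), "ub")
  cc <- stats::setNames(rep(0, length(rid)), rid)
  cc[names(objective)] <- objective
  # shift to y = v - lb >= 0 (pracma's native lb/ub handling is unreliable);
  # upper bounds become explicit rows y <= ub - lb
  res <- pracma::linprog(cc = cc,
                         A = diag(length(rid)), b = ub - lb,
                         Aeq = S, beq = as.numeric(-S %*% lb),
                         maxiter = 500, maximize = (sense == "max"))
  list(objective = res$fval + sum(cc * lb),
       x = stats::setNames(res$x + lb, rid),
       ok = res$errno == 1)
}

# per-reaction flux variability by the direct route
fva_direct <- function(model, ids) {
  out <- data.frame(id = ids, min = NA_real_, max = NA_real_)
  for (i in seq_along(ids)) {
    o <- stats::setNames(1, ids[i])
    out$min[i] <- fba_direct(model, o, "min")$objective
    out$max[i] <- fba_direct(model, o, "max")$objective
  }
  out
}

# map an (unfolded) FN flux vector back to net reaction fluxes
net_fluxes <- function(fluxes, model) {
  sapply(names(model$reactions), function(id) {
    if (id %in% names(fluxes)) return(unname(fluxes[id]))
    unname(fluxes[paste0(id, "_f")] - fluxes[paste0(id, "_b")])
  })
}
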