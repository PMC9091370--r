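## Constraint-based models: the {reactions, metabolites, S, L, U} tuple,
## readers/writers, reversible unfolding and conversion to a Flexible Net.

#' Create a constraint-based metabolic model
#'
#' @param reactions a list of reaction entries, each a list with `id`,
#'   `stoich` (named numeric, metabolite -> signed coefficient; boundary
#'   reactions may produce/consume from nothing), `lb`, `ub`
#'   (mmol gDW^-1 h^-1).
#' @param metabolites character vector of metabolite ids; defaults to the
#'   union of stoichiometry keys.
#' @param objective optional id of the objective reaction.
#' @return An object of class `cbm_model`.
#' @export
cbm_model <- function(reactions, metabolites = NULL, objective = NULL) {
  stopifnot(is.list(reactions))
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate reaction ids")
  used <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
  if (is.null(metabolites)) metabolites <- used
  bad <- setdiff(used, metabolites)
  if (length(bad))
    stop("stoichiometry references undeclared metabolite(s): ",
         paste(bad, collapse = ", "))
  for (r in reactions) {
    if (is.null(r$lb) || is.null(r$ub) || is.na(r$lb) || is.na(r$ub))
      stop("reaction '", r$id, "' lacks flux bounds")
    if (r$lb > r$ub)
      stop("reaction '", r$id, "': lower bound exceeds upper bound")
  }
  names(reactions) <- ids
  if (!is.null(objective) && !objective %in% ids)
    stop("objective reaction '", objective, "' not in model")
  structure(list(reactions = reactions,
                 metabolites = as.character(metabolites),
                 objective = objective),
            class = "cbm_model")
}

#' @export
print.cbm_model <- function(x, ...) {
  cat("Constraint-based model: ", length(x$reactions), " reactions, ",
      length(x$metabolites), " metabolites\n", sep = "")
  if (!is.null(x$objective)) cat("  objective: ", x$objective, "\n")
  invisible(x)
}

#' Parse a reaction formula string
#'
#' The dialect used by the TSV/JSON model format: `"2 A + B -> D"` for an
#' irreversible reaction, `"A <-> 2 B"` for a reversible one; either side may
#' be empty for boundary/exchange reactions (`"-> A"`, `"B + C ->"`).
#'
#' @param formula formula string.
#' @return A list with `stoich` (named numeric) and `reversible` (logical).
#' @export
parse_reaction_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  reversible <- grepl("<->", formula, fixed = TRUE)
  sides <- strsplit(formula, if (reversible) "<->" else "->", fixed = TRUE)[[1]]
  if (!grepl("->", formula, fixed = TRUE) || length(sides) > 2L)
    stop("cannot parse reaction formula: '", formula, "'")
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric(0))
    out <- numeric(0)
    for (term in trimws(strsplit(s, "+", fixed = TRUE)[[1]])) {
      if (!nzchar(term)) stop("empty term in formula: '", formula, "'")
      m <- regmatches(term,
                      regexec("^(?:([0-9]*\\.?[0-9]+)\\s+)?(\\S+)$", term))[[1]]
      if (length(m) != 3L || !nzchar(m[3]))
        stop("cannot parse term '", term, "' in formula: '", formula, "'")
      coef <- if (nzchar(m[2])) as.numeric(m[2]) else 1
      out[m[3]] <- (if (is.na(out[m[3]])) 0 else out[m[3]]) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (m in names(rhs)) st[m] <- (if (is.na(st[m])) 0 else st[m]) + rhs[m]
  st <- st[st != 0]
  list(stoich = st, reversible = reversible)
}

# inverse of parse_reaction_formula, for writers
.format_formula <- function(stoich, reversible = FALSE) {
  side <- function(v) paste(ifelse(v == 1, names(v),
                                   paste(format(v, trim = TRUE), names(v))),
                            collapse = " + ")
  lhs <- -stoich[stoich < 0]; rhs <- stoich[stoich > 0]
  paste(side(lhs), if (reversible) "<->" else "->", side(rhs))
}

#' Read a constraint-based model
#'
#' Supported formats: `"tsv"` (columns `id`, `formula`, `lb`, `ub`; formula
#' dialect of [parse_reaction_formula()]), `"json"` (the same fields as
#' arrays of records, see [write_cbm_json()]), and `"sbml"` (SBML Level 3
#' with the fbc package, see [read_sbml_model()]).  Reactions without bounds
#' are an error: no silent defaults are applied.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"tsv"`, `"json"`, `"sbml"`; `"auto"`
#'   picks by file extension.
#' @param quiet suppress the log line with model dimensions.
#' @return A [cbm_model()].
#' @export
load_model <- function(path, format = c("auto", "tsv", "json", "sbml"),
                       quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", json = "json",
                     xml = "sbml", sbml = "sbml",
                     stop("cannot infer model format from extension: ", path))
  model <- switch(format,
                  tsv = .read_cbm_tsv(path),
                  json = .read_cbm_json(path),
                  sbml = read_sbml_model(path))
  if (!quiet)
    message("loaded ", format, " model: ", length(model$reactions),
            " reactions, ", length(model$metabolites), " metabolites")
  model
}

.read_cbm_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#", strip.white = TRUE)
  need <- c("id", "formula", "lb", "ub")
  if (!all(need %in% names(df)))
    stop("TSV model needs columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("empty model file: ", path)
  reactions <- lapply(seq_len(nrow(df)), function(i) {
    pf <- parse_reaction_formula(df$formula[i])
    list(id = df$id[i], stoich = pf$stoich,
         lb = as.numeric(df$lb[i]), ub = as.numeric(df$ub[i]))
  })
  cbm_model(reactions)
}

.read_cbm_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$reactions) || !length(j$reactions))
    stop("empty or invalid JSON model: ", path)
  reactions <- lapply(j$reactions, function(r) {
    st <- if (!is.null(r$stoich)) unlist(r$stoich) else
      parse_reaction_formula(r$formula)$stoich
    list(id = r$id, stoich = st,
         lb = if (is.null(r$lb)) NA_real_ else as.numeric(r$lb),
         ub = if (is.null(r$ub)) NA_real_ else as.numeric(r$ub))
  })
  cbm_model(reactions,
            metabolites = if (!is.null(j$metabolites))
              unlist(j$metabolites) else NULL,
            objective = j$objective)
}

#' Write a model to the JSON dialect
#'
#' @param model a [cbm_model()].
#' @param path output file.
#' @export
write_cbm_json <- function(model, path) {
  stopifnot(inherits(model, "cbm_model"))
  j <- list(metabolites = model$metabolites,
            reactions = lapply(unname(model$reactions), function(r)
              list(id = r$id, stoich = as.list(r$stoich),
                   lb = r$lb, ub = r$ub)),
            objective = model$objective)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Add a reaction to a model
#'
#' New metabolites appearing in the stoichiometry are declared alongside.
#'
#' @param model a [cbm_model()].
#' @param id new reaction id (must not already exist).
#' @param stoich named numeric stoichiometry, or `NULL` if `formula` given.
#' @param formula formula string alternative to `stoich`.
#' @param lb,ub flux bounds.
#' @return The extended model.
#' @export
add_reaction <- function(model, id, stoich = NULL, formula = NULL,
                         lb = 0, ub = 1000) {
  stopifnot(inherits(model, "cbm_model"))
  if (id %in% names(model$reactions))
    stop("reaction '", id, "' already in model")
  if (is.null(stoich)) {
    if (is.null(formula)) stop("need stoich or formula")
    pf <- parse_reaction_formula(formula)
    stoich <- pf$stoich
    if (pf$reversible && lb == 0) lb <- -ub
  }
  reactions <- c(model$reactions,
                 list(list(id = id, stoich = stoich, lb = lb, ub = ub)))
  names(reactions)[length(reactions)] <- id
  cbm_model(reactions,
            metabolites = union(model$metabolites, names(stoich)),
            objective = model$objective)
}

#' Add the citramalate production pathway
#'
#' Inserts citramalate synthase (acetyl-CoA + pyruvate + H2O -> citramalate
#' + CoA + H+) plus a citramalate exchange reaction, turning a wild-type
#' model into one for a cimA-transgenic strain.  Metabolite ids default to
#' the BiGG cytosolic ids used by iJO1366.
#'
#' @param model a [cbm_model()].
#' @param synthase_id,exchange_id reaction ids to create.
#' @param accoa,pyr,h2o,coa,h,citramalate metabolite ids.
#' @param bounds flux bounds applied to both added reactions.
#' @return The extended model.
#' @export
add_citramalate_pathway <- function(model,
                                    synthase_id = "CIMA",
                                    exchange_id = "EX_citramalate",
                                    accoa = "accoa_c", pyr = "pyr_c",
                                    h2o = "h2o_c", coa = "coa_c", h = "h_c",
                                    citramalate = "citramalate_c",
                                    bounds = c(0, 1000)) {
  st <- stats::setNames(c(-1, -1, -1, 1, 1, 1),
                        c(accoa, pyr, h2o, citramalate, coa, h))
  model <- add_reaction(model, synthase_id, stoich = st,
                        lb = bounds[1], ub = bounds[2])
  add_reaction(model, exchange_id,
               stoich = stats::setNames(-1, citramalate),
               lb = bounds[1], ub = bounds[2])
}

#' Unfold reversible reactions
#'
#' Every reaction whose flux range extends below zero is split into a
#' forward copy `<id>_f` and a backward copy `<id>_b` with negated
#' stoichiometry, so that all fluxes are non-negative (a Flexible Net
#' requirement).  The net flux `v_f - v_b` spans exactly the original range.
#'
#' @param model a [cbm_model()].
#' @return A model with non-negative bounds only.
#' @export
unfold_reversible <- function(model) {
  stopifnot(inherits(model, "cbm_model"))
  out <- list()
  for (r in model$reactions) {
    if (r$lb >= 0) {
      out[[length(out) + 1L]] <- r
    } else {
      out[[length(out) + 1L]] <- list(id = paste0(r$id, "_f"),
                                      stoich = r$stoich,
                                      lb = max(0, r$lb), ub = max(0, r$ub))
      out[[length(out) + 1L]] <- list(id = paste0(r$id, "_b"),
                                      stoich = -r$stoich,
                                      lb = max(0, -r$ub), ub = -r$lb)
    }
  }
  obj <- model$objective
  if (!is.null(obj) && !obj %in% vapply(out, `[[`, character(1), "id"))
    obj <- paste0(obj, "_f")
  cbm_model(out, metabolites = model$metabolites, objective = obj)
}

#' Convert a constraint-based model to a Flexible Net
#'
#' One place per metabolite, one transition per (unfolded) reaction with its
#' flux bounds as the transition's lambda0, and one event handler per
#' reaction carrying the stoichiometry.  No intensity handlers: a
#' constraint-based model has no concentration-dependent kinetics, so the
#' steady-state LP of the resulting net is exactly flux balance analysis.
#'
#' @param model a [cbm_model()]; reversible reactions are unfolded first.
#' @return A [flexible_net()].
#' @export
cbm_to_fn <- function(model) {
  stopifnot(inherits(model, "cbm_model"))
  if (any(vapply(model$reactions, `[[`, numeric(1), "lb") < 0))
    model <- unfold_reversible(model)
  places <- lapply(model$metabolites, fn_place)
  transitions <- lapply(model$reactions, function(r)
    fn_transition(r$id, r$lb, r$ub))
  handlers <- lapply(model$reactions, function(r)
    fn_event_handler(paste0("v_", r$id), r$id, r$stoich))
  flexible_net(places, unname(transitions), unname(handlers))
}
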