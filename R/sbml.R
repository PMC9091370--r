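## SBML Level 3 + fbc reader (the format genome-scale reconstructions such
## as iJO1366 are distributed in).  Only what constraint-based analysis
## needs is read: species, reactions with stoichiometry, fbc flux bounds and
## the active fbc objective.  Gene associations are ignored.

#' Read an SBML Level 3 (fbc) model
#'
#' Flux bounds must be present for every reaction, either as fbc
#' `lowerFluxBound`/`upperFluxBound` parameter references or (Level 2
#' fallback) as `listOfParameters` entries `LOWER_BOUND`/`UPPER_BOUND` in
#' the reaction's kinetic law; a reaction without bounds is an error.
#' Species flagged `boundaryCondition="true"` are treated as external and
#' dropped from stoichiometries.  Exchange reactions can later be recognised
#' by their `EX_` id prefix.
#'
#' @param path path to an `.xml`/`.sbml` file.
#' @return A [cbm_model()].
#' @export
read_sbml_model <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = xml2::xml_ns(doc)[["d1"]],
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  # tolerate fbc version 1
  all_ns <- xml2::xml_ns(doc)
  fbc_real <- grep("fbc", unlist(all_ns), value = TRUE)
  if (length(fbc_real)) ns[["fbc"]] <- fbc_real[[1]]

  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp_nodes)) stop("no species found in SBML file: ", path)
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"
  internal <- sp_id[!sp_boundary]

  par_nodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx_nodes)) stop("no reactions found in SBML file: ", path)

  reactions <- lapply(rx_nodes, function(rx) {
    id <- xml2::xml_attr(rx, "id")
    sides <- function(xp, sign) {
      refs <- xml2::xml_find_all(rx, xp, ns)
      if (!length(refs)) return(numeric(0))
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(sign * st, xml2::xml_attr(refs, "species"))
    }
    st <- c(sides("./s:listOfReactants/s:speciesReference", -1),
            sides("./s:listOfProducts/s:speciesReference", +1))
    st <- st[names(st) %in% internal]
    if (length(st)) {
      st <- tapply(st, names(st), sum)          # merge duplicated species
      st <- stats::setNames(as.numeric(st), names(st))
    }

    lb_ref <- xml2::xml_attr(rx, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rx, "upperFluxBound")
    if (!is.na(lb_ref) && !is.na(ub_ref)) {
      if (!all(c(lb_ref, ub_ref) %in% names(par_val)))
        stop("reaction '", id, "': flux-bound parameter not found")
      lb <- par_val[[lb_ref]]; ub <- par_val[[ub_ref]]
    } else {
      kl <- xml2::xml_find_all(
        rx, "./s:kineticLaw//s:parameter | ./s:kineticLaw//s:localParameter", ns)
      kv <- stats::setNames(as.numeric(xml2::xml_attr(kl, "value")),
                            xml2::xml_attr(kl, "id"))
      lb <- unname(kv["LOWER_BOUND"])
      ub <- unname(kv["UPPER_BOUND"])
    }
    if (is.na(lb) || is.na(ub))
      stop("reaction '", id, "' has no flux bounds in SBML file")
    list(id = id, stoich = st, lb = lb, ub = ub)
  })

  obj <- NULL
  obj_node <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (!inherits(obj_node, "xml_missing"))
    obj <- xml2::xml_attr(obj_node, "reaction")

  cbm_model(reactions, metabolites = internal, objective = obj)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
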