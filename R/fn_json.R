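## JSON serialization of Flexible Nets.
##
## Schema (arrays of records):
##   places:  {id, role, units, conc_lo?, conc_hi?}
##   transitions: {id, l0: [lo, hi]}        (hi may be the string "Inf")
##   event_handlers: {id, transition, stoich: {place: coef, ...}}
##   intensity_handlers:
##     linear:   {id, transition, type: "linear", on?, guards: [
##                  {cond: [lo, hi], coef: {...}, const, coef_hi?: {...}}]}
##     bilinear: {id, transition, type: "bilinear", source, scale}

.num_out <- function(x) if (is.infinite(x)) as.character(x) else x
.num_in <- function(x) if (is.character(x)) as.numeric(x) else as.numeric(x)

#' Write a Flexible Net to JSON
#'
#' @param net a [flexible_net()].
#' @param path output file.
#' @export
write_fn_json <- function(net, path) {
  stopifnot(inherits(net, "flexible_net"))
  j <- list(
    places = lapply(unname(net$places), function(p)
      list(id = p$id, role = p$role, units = p$units,
           conc_lo = .num_out(p$conc_lo), conc_hi = .num_out(p$conc_hi))),
    transitions = lapply(unname(net$transitions), function(tr)
      list(id = tr$id, l0 = list(.num_out(tr$l0_lo), .num_out(tr$l0_hi)))),
    event_handlers = lapply(unname(net$event_handlers), function(h)
      list(id = h$id, transition = h$transition, stoich = as.list(h$stoich))),
    intensity_handlers = lapply(unname(net$intensity_handlers), function(h) {
      if (h$type == "bilinear")
        return(list(id = h$id, transition = h$transition, type = "bilinear",
                    source = h$source, scale = h$scale))
      list(id = h$id, transition = h$transition, type = "linear",
           on = if (is.na(h$on)) NULL else h$on,
           guards = lapply(h$guards, function(g) {
             out <- list(cond = list(.num_out(g$lo), .num_out(g$hi)),
                         coef = as.list(g$coef), const = g$const)
             if (!is.null(g$coef_hi)) out$coef_hi <- as.list(g$coef_hi)
             out
           }))
    }))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a Flexible Net from JSON
#'
#' @param path file written by [write_fn_json()].
#' @return A [flexible_net()].
#' @export
read_fn_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  places <- lapply(j$places, function(p)
    fn_place(p$id, p$role %||% "metabolite", p$units %||% "mM",
             .num_in(p$conc_lo %||% 0), .num_in(p$conc_hi %||% Inf)))
  transitions <- lapply(j$transitions, function(tr)
    fn_transition(tr$id, .num_in(tr$l0[[1]]), .num_in(tr$l0[[2]])))
  eh <- lapply(j$event_handlers, function(h)
    fn_event_handler(h$id, h$transition, unlist(h$stoich)))
  ih <- lapply(j$intensity_handlers, function(h) {
    if (identical(h$type, "bilinear"))
      return(fn_intensity_handler(h$id, h$transition, type = "bilinear",
                                  source = h$source, scale = h$scale))
    guards <- lapply(h$guards, function(g)
      fn_guard(.num_in(g$cond[[1]]), .num_in(g$cond[[2]]),
               coef = if (length(g$coef)) unlist(g$coef) else numeric(0),
               const = g$const %||% 0,
               coef_hi = if (!is.null(g$coef_hi)) unlist(g$coef_hi)))
    fn_intensity_handler(h$id, h$transition, guards = guards,
                         on = h$on %||% NA_character_)
  })
  flexible_net(places, transitions, eh, ih)
}
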