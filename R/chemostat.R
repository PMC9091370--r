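## Chemostat (continuous-culture) layer: the macroscopic tank mass balances
## and their merger with a cell-scale Flexible Net.
##
## At steady state the tank obeys
##   biomass:    mu * X            = D * X        (so mu = D when X > 0)
##   substrate:  D * c_g           = u_g * X + D * s_g
##   product:    |u_c| * X         = D * s_c
## where D is the dilution rate (1/h), c_g the feed substrate concentration,
## s_g/s_c tank concentrations (mM), X the cell density (gDW/L), and u_g,
## |u_c|, mu specific exchange/growth rates taken from the cell model.  The
## products u_g*X, |u_c|*X and mu*X are the bilinear interface relations.

.MW_GLUCOSE <- 180.16     # g/mol
.MW_CITRAMALATE <- 148.12 # g/mol

#' Specify a chemostat
#'
#' User-facing concentrations are in g/L; internally tank metabolites are
#' tracked in mM using the molar masses given here.
#'
#' @param c_g feed substrate concentration (g/L).
#' @param D dilution rate (1/h).
#' @param substrate_exchange id of the cell-net transition whose flux is the
#'   specific substrate uptake rate (mmol gDW^-1 h^-1, non-negative).
#' @param product_exchange id of the transition whose flux is the specific
#'   product secretion rate (non-negative; the net's arc orientation absorbs
#'   the sign of secretion).
#' @param growth_reaction id of the biomass/growth transition (flux in 1/h).
#' @param mw_substrate,mw_product molar masses (g/mol); defaults are glucose
#'   and citramalate.
#' @param Xmin,Xmax biomass bounds (gDW/L).  These need not be tight; the
#'   default cap is `c_g * 0.5 * 1.5` (a generous yield-based bound of
#'   0.5 gDW per gram of substrate with 50% headroom).
#' @return An object of class `chemostat_spec`.
#' @export
chemostat_spec <- function(c_g, D,
                           substrate_exchange, product_exchange,
                           growth_reaction,
                           mw_substrate = .MW_GLUCOSE,
                           mw_product = .MW_CITRAMALATE,
                           Xmin = 0, Xmax = NULL) {
  if (is.null(Xmax)) Xmax <- c_g * 0.5 * 1.5
  stopifnot(is.numeric(c_g), c_g >= 0, is.numeric(D), D > 0,
            mw_substrate > 0, mw_product > 0,
            Xmin >= 0, Xmin < Xmax)
  structure(list(c_g = c_g, D = D,
                 substrate_exchange = substrate_exchange,
                 product_exchange = product_exchange,
                 growth_reaction = growth_reaction,
                 mw_substrate = mw_substrate, mw_product = mw_product,
                 Xmin = Xmin, Xmax = Xmax),
            class = "chemostat_spec")
}

#' @export
print.chemostat_spec <- function(x, ...) {
  cat("Chemostat: feed ", x$c_g, " g/L (",
      format(convert_units(x$c_g, "g_per_L", "mM", x$mw_substrate),
             digits = 6), " mM), D = ", x$D, " /h, X in [",
      x$Xmin, ", ", x$Xmax, "] gDW/L\n", sep = "")
  cat("  uptake: ", x$substrate_exchange, "  secretion: ",
      x$product_exchange, "  growth: ", x$growth_reaction, "\n", sep = "")
  invisible(x)
}

#' Read a chemostat specification from a YAML or JSON config file
#'
#' The file holds the [chemostat_spec()] arguments as a flat mapping, e.g.
#' ```yaml
#' c_g: 10
#' D: 0.23
#' substrate_exchange: GLC_upt
#' product_exchange: EX_prod
#' growth_reaction: GROWTH
#' ```
#' Unknown keys are an error (no silent typos).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [chemostat_spec()].
#' @export
read_chemostat_spec <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (tolower(tools::file_ext(path)) == "json")
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  bad <- setdiff(names(cfg), names(formals(chemostat_spec)))
  if (length(bad))
    stop("unknown chemostat config key(s): ", paste(bad, collapse = ", "))
  do.call(chemostat_spec, cfg)
}

#' Convert between the units the model mixes
#'
#' Supported pairs: `g_per_L` <-> `mM` and `g_per_L_per_h` <-> `mM_per_h`
#' (via the molar mass), and the identity pair.
#'
#' @param value numeric value(s).
#' @param from,to unit tags.
#' @param molar_mass molar mass in g/mol (needed for mass <-> molar pairs).
#' @return Converted value.
#' @export
convert_units <- function(value, from, to, molar_mass = NULL) {
  if (from == to) return(value)
  key <- paste(from, to, sep = "->")
  need_mw <- function() {
    if (is.null(molar_mass) || molar_mass <= 0)
      stop("conversion ", key, " needs a positive molar mass")
    molar_mass
  }
  switch(key,
         "g_per_L->mM" = value / need_mw() * 1000,
         "mM->g_per_L" = value * need_mw() / 1000,
         "g_per_L_per_h->mM_per_h" = value / need_mw() * 1000,
         "mM_per_h->g_per_L_per_h" = value * need_mw() / 1000,
         stop("unsupported unit conversion: ", key))
}

#' Merge a cell Flexible Net with the chemostat tank
#'
#' Adds the macroscopic side of the production system to a cell-scale net:
#' tank places `G` (substrate, mM), `C` (product, mM) and `X` (biomass,
#' gDW/L, bounded by the spec); reservoir/effluent/interface transitions
#' `t_gin` (feed, lambda0 fixed at `D*c_g` in mM/h), `t_ut`, `t_gout`,
#' `t_ct`, `t_cout`, `t_xt`, `t_xout`; effluent intensity handlers
#' `s_gout`, `s_cout`, `s_xout` (rate = D x tank concentration) and the
#' three bilinear interface handlers `h_u`, `h_r`, `h_c` (tank flux = cell
#' exchange flux x biomass X).
#'
#' @param cell_net a [flexible_net()] for the cell (e.g. from [cbm_to_fn()]).
#' @param spec a [chemostat_spec()]; its three named transitions must exist
#'   in `cell_net`.
#' @return An object of class `integrated_fn`: list with `net`, `spec` and
#'   the names of the bilinear handlers.
#' @export
build_integrated_fn <- function(cell_net, spec) {
  stopifnot(inherits(cell_net, "flexible_net"),
            inherits(spec, "chemostat_spec"))
  tid <- names(cell_net$transitions)
  for (f in c("substrate_exchange", "product_exchange", "growth_reaction"))
    if (!spec[[f]] %in% tid)
      stop("cell net has no transition '", spec[[f]], "' (", f, ")")
  for (p in c("G", "C", "X"))
    if (p %in% names(cell_net$places))
      stop("cell net already has a place named '", p, "'")

  c_g_mM <- convert_units(spec$c_g, "g_per_L", "mM", spec$mw_substrate)
  feed <- spec$D * c_g_mM   # mM/h

  places <- c(unname(cell_net$places), list(
    fn_place("G", role = "species", units = "mM"),
    fn_place("C", role = "species", units = "mM"),
    fn_place("X", role = "species", units = "gDW_per_L",
             conc_lo = spec$Xmin, conc_hi = spec$Xmax)))

  transitions <- c(unname(cell_net$transitions), list(
    fn_transition("t_gin", feed, feed),   # reservoir feed, fixed at D*c_g
    fn_transition("t_ut"),                # handler-driven: no default intensity
    fn_transition("t_gout"),
    fn_transition("t_ct"),
    fn_transition("t_cout"),
    fn_transition("t_xt"),
    fn_transition("t_xout")))

  eh <- c(unname(cell_net$event_handlers), list(
    fn_event_handler("v_gin", "t_gin", c(G = 1)),
    fn_event_handler("v_ut", "t_ut", c(G = -1)),
    fn_event_handler("v_gout", "t_gout", c(G = -1)),
    fn_event_handler("v_ct", "t_ct", c(C = 1)),
    fn_event_handler("v_cout", "t_cout", c(C = -1)),
    fn_event_handler("v_xt", "t_xt", c(X = 1)),
    fn_event_handler("v_xout", "t_xout", c(X = -1))))

  D <- spec$D
  ih <- c(unname(cell_net$intensity_handlers), list(
    fn_intensity_handler("h_u", "t_ut", type = "bilinear",
                         source = spec$substrate_exchange, scale = "X"),
    fn_intensity_handler("h_r", "t_xt", type = "bilinear",
                         source = spec$growth_reaction, scale = "X"),
    fn_intensity_handler("h_c", "t_ct", type = "bilinear",
                         source = spec$product_exchange, scale = "X"),
    fn_intensity_handler("s_gout", "t_gout",
                         guards = list(fn_guard(coef = c(G = D)))),
    fn_intensity_handler("s_cout", "t_cout",
                         guards = list(fn_guard(coef = c(C = D)))),
    fn_intensity_handler("s_xout", "t_xout",
                         guards = list(fn_guard(coef = c(X = D))))))

  net <- flexible_net(places, transitions, eh, ih)
  structure(list(net = net, spec = spec,
                 bilinear_handlers = c("h_u", "h_r", "h_c")),
            class = "integrated_fn")
}

#' @export
print.integrated_fn <- function(x, ...) {
  cat("Integrated cell+chemostat Flexible Net\n")
  print(x$spec)
  print(x$net)
  invisible(x)
}

#' Steady-state constraints of an integrated model
#'
#' The constraints of the merged net (zero net flow through every place,
#' including the tank balances) plus the continuous-culture identity
#' `mu = D`: constant cell density with positive biomass forces the growth
#' rate to equal the dilution rate.  The three bilinear interface relations
#' stay symbolic in the registry; [solve_piecewise()] brackets them
#' region-wise and [solve_fixed_biomass()] makes them exact at a fixed X.
#'
#' @param model an [build_integrated_fn()] result.
#' @return An `fn_constraints` system.
#' @export
chemostat_steady_state <- function(model) {
  stopifnot(inherits(model, "integrated_fn"))
  cs <- steady_state_constraints(model$net)
  r <- stats::setNames(rep(0, length(cs$vars)), cs$vars)
  r[paste0("flux.", model$spec$growth_reaction)] <- 1
  cs$A_eq <- rbind(cs$A_eq, r)
  cs$b_eq <- c(cs$b_eq, model$spec$D)
  cs
}
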