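#' Construct a reaction network
#'
#' A `reaction_network` is the in-memory form of a single-cell reaction model:
#' species with initial amounts, reactions with stoichiometry and kinetic-law
#' expressions, and a table of global parameters. It is the common currency of
#' the whole package: the SBML loader produces one, the simulator consumes one,
#' and knockouts/per-cell multipliers are edits of one.
#'
#' @param species data.frame with columns `id`, `name`, `initial`,
#'   `compartment`, `boundary` (logical; a boundary species has zero
#'   derivative, used e.g. for an extracellular ligand held constant).
#' @param reactions list of reactions; each a list with elements `id`, `name`,
#'   `reactants` (named integer vector of stoichiometries), `products`
#'   (named integer vector), `rate` (an unevaluated R expression for the
#'   kinetic law, in terms of species ids and parameter ids) and
#'   `local_params` (named numeric, possibly empty).
#' @param parameters named numeric vector of global parameter values.
#' @param compartments data.frame with columns `id`, `size`.
#' @param id,name identifiers for the model.
#' @param hours_per_time_unit conversion from the model's internal time unit to
#'   hours (1 for models written in hours, 1/3600 for SBML seconds). All
#'   reported times of death are in hours post stimulus.
#' @param tnf_species id of the free-ligand (TNF) species, or `NA` if the model
#'   has no stimulus input (e.g. the toy timer).
#' @param tnf_units_per_ng_ml linear conversion factor from ng/ml to the
#'   model's TNF amount units, or `NA` if unknown.
#' @param death_rule how a cell's death event is detected; either
#'   `list(type = "parp_fraction", parp = <id>, cleaved = <id>, fraction = 0.5)`
#'   (death when cleaved PARP reaches `fraction` of total PARP, the total being
#'   evaluated at t = 0) or `list(type = "threshold", species = <id>,
#'   theta = <amount>)` (death when a species first reaches `theta` from
#'   below). `NULL` for models without a death readout.
#' @param active_caspases character vector of species ids that must be
#'   (numerically) absent in the pre-stimulus steady state.
#' @param requires_equilibration logical; if `FALSE` the declared initial
#'   amounts are used directly as the t = 0 state (toy fixtures).
#'
#' @return An object of class `reaction_network`.
#' @export
reaction_network <- function(species, reactions, parameters = numeric(),
                             compartments = data.frame(id = "cell", size = 1),
                             id = "model", name = id,
                             hours_per_time_unit = 1,
                             tnf_species = NA_character_,
                             tnf_units_per_ng_ml = NA_real_,
                             death_rule = NULL,
                             active_caspases = character(),
                             requires_equilibration = TRUE) {
  stopifnot(is.data.frame(species),
            all(c("id", "initial", "compartment") %in% names(species)))
  if (is.null(species$name)) species$name <- species$id
  if (is.null(species$boundary)) species$boundary <- FALSE
  species <- species[, c("id", "name", "initial", "compartment", "boundary")]
  if (anyDuplicated(species$id)) stop("duplicate species ids")
  if (any(!is.finite(species$initial)) || any(species$initial < 0))
    stop("initial amounts must be finite and >= 0")
  if (length(parameters) && (any(!is.finite(parameters)) || any(parameters < 0)))
    stop("parameter values must be finite and >= 0")

  reactions <- lapply(reactions, function(r) {
    r$reactants <- .as_stoich(r$reactants)
    r$products  <- .as_stoich(r$products)
    if (is.null(r$local_params)) r$local_params <- numeric()
    if (is.null(r$name)) r$name <- r$id
    refs <- setdiff(all.vars(r$rate),
                    c(names(parameters), names(r$local_params), "t",
                      compartments$id))
    unknown <- setdiff(refs, species$id)
    if (length(unknown))
      stop("rate law of reaction '", r$id, "' references unknown symbol(s): ",
           paste(unknown, collapse = ", "))
    miss <- setdiff(c(names(r$reactants), names(r$products)), species$id)
    if (length(miss))
      stop("reaction '", r$id, "' references unknown species: ",
           paste(miss, collapse = ", "))
    r
  })
  rids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rids)) stop("duplicate reaction ids")
  names(reactions) <- rids

  net <- structure(
    list(id = id, name = name, species = species, reactions = reactions,
         parameters = parameters, compartments = compartments,
         hours_per_time_unit = hours_per_time_unit,
         tnf_species = tnf_species,
         tnf_units_per_ng_ml = tnf_units_per_ng_ml,
         death_rule = death_rule,
         active_caspases = active_caspases,
         requires_equilibration = requires_equilibration),
    class = "reaction_network")
  net$production_rate_ids <- identify_production_rates(net)
  net
}

.as_stoich <- function(x) {
  if (is.null(x) || !length(x)) return(integer())
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("stoichiometry vectors must be named by species id")
  if (any(x != round(x)) || any(x <= 0))
    stop("stoichiometric coefficients must be positive integers")
  storage.mode(x) <- "integer"
  x
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Reaction network:", x$name, sprintf("(id '%s')\n", x$id))
  cat(sprintf("  %d species, %d reactions, %d global parameters\n",
              nrow(x$species), length(x$reactions), length(x$parameters)))
  cat(sprintf("  %d distributed production rate(s): %s\n",
              length(x$production_rate_ids),
              paste(utils::head(x$production_rate_ids, 8), collapse = ", ")))
  if (!is.na(x$tnf_species))
    cat("  stimulus species:", x$tnf_species, "\n")
  if (!is.null(x$death_rule))
    cat("  death rule:", x$death_rule$type, "\n")
  invisible(x)
}

#' Identify distributed production-rate parameters
#'
#' Production (protein expression) reactions are identified structurally as
#' zeroth-order synthesis reactions: reactions with no reactant species. The
#' returned parameter ids are the kinetic constants of those reactions, in
#' model document order; these are the rates that are lognormally distributed
#' across the cell population.
#'
#' @param network a `reaction_network`.
#' @return character vector of parameter ids (possibly empty).
#' @export
identify_production_rates <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  ids <- character()
  for (r in network$reactions) {
    if (length(r$reactants)) next
    vars <- all.vars(r$rate)
    # zeroth order: the rate law may not depend on any species amount
    if (length(intersect(vars, network$species$id))) next
    pars <- intersect(vars, c(names(network$parameters), names(r$local_params)))
    # a zeroth-order synthesis law must expose exactly one rate constant
    pars <- setdiff(pars, network$compartments$id)
    if (length(pars) == 1L) ids <- c(ids, pars)
  }
  unique(ids)
}

#' Knock out a reaction in silico
#'
#' Returns a copy of the network in which the named reaction's rate is
#' identically zero for all states; every other reaction is untouched and the
#' input network is not modified. This is how the NF-kB knockout population is
#' built: the IKK-mediated release and degradation of bound IkBa is zeroed, so
#' no TNF-induced NF-kB activation can occur.
#'
#' @param network a `reaction_network`.
#' @param reaction_id id of the reaction to silence.
#' @return the modified `reaction_network`.
#' @export
apply_knockout <- function(network, reaction_id) {
  stopifnot(inherits(network, "reaction_network"))
  if (!reaction_id %in% names(network$reactions))
    stop("unknown reaction id '", reaction_id, "'; available: ",
         paste(names(network$reactions), collapse = ", "))
  network$reactions[[reaction_id]]$rate <- quote(0)
  network$production_rate_ids <- identify_production_rates(network)
  network
}

#' Set the TNF dose conversion for a network
#'
#' @param network a `reaction_network`.
#' @param tnf_species id of the free-ligand species.
#' @param units_per_ng_ml model amount units corresponding to 1 ng/ml.
#' @return the network with dose metadata attached.
#' @export
set_tnf_input <- function(network, tnf_species, units_per_ng_ml) {
  stopifnot(inherits(network, "reaction_network"),
            tnf_species %in% network$species$id,
            is.finite(units_per_ng_ml), units_per_ng_ml > 0)
  network$tnf_species <- tnf_species
  network$tnf_units_per_ng_ml <- units_per_ng_ml
  network
}

#' Set the death readout of a network
#'
#' @param network a `reaction_network`.
#' @param rule a death rule list; see [reaction_network()].
#' @return the network with the rule attached.
#' @export
set_death_rule <- function(network, rule) {
  stopifnot(inherits(network, "reaction_network"))
  sp <- switch(rule$type,
               parp_fraction = c(rule$parp, rule$cleaved),
               threshold = rule$species,
               stop("unknown death rule type '", rule$type, "'"))
  miss <- setdiff(sp, network$species$id)
  if (length(miss)) stop("death rule references unknown species: ",
                         paste(miss, collapse = ", "))
  network$death_rule <- rule
  network
}

#' Export a normalized model summary as JSON
#'
#' Writes species, reactions (with deparsed rate laws) and parameters to a
#' JSON file for provenance logging of a run.
#'
#' @param network a `reaction_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(network, path) {
  out <- list(
    id = network$id, name = network$name,
    species = network$species,
    parameters = as.list(network$parameters),
    production_rate_ids = network$production_rate_ids,
    reactions = lapply(unname(network$reactions), function(r)
      list(id = r$id, name = r$name,
           reactants = as.list(r$reactants), products = as.list(r$products),
           rate = paste(deparse(r$rate), collapse = " "),
           local_params = as.list(r$local_params))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
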