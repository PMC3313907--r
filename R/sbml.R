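# SBML input/output for mass-action style models.
#
# Scope: SBML level 2 style documents with compartments, species, global and
# reaction-local parameters, and kinetic laws written in MathML arithmetic
# (times, plus, minus, divide, power, exp, ln, log). Constructs that would
# change the ODE semantics silently if ignored -- events, rules, function
# definitions, constraints, stoichiometryMath, delays -- raise an error
# instead: silent omission would corrupt every downstream number.

.SBML_NS <- "http://www.sbml.org/sbml/level2/version4"
.META_NS <- "http://example.org/cellensemble/annotation"

#' Load a reaction network from an SBML file
#'
#' Parses an SBML document into a [reaction_network()]. Species, reaction and
#' parameter ids are preserved verbatim, so a network loaded from a deposited
#' model keeps that model's identifiers. Unsupported SBML constructs (events,
#' rules, function definitions, constraints, non-integer or math-defined
#' stoichiometry) raise an explicit error naming the offending element.
#'
#' Dose metadata (stimulus species id, ng/ml conversion) and the death rule are
#' read from a package annotation block if present (as written by
#' [write_sbml()]); otherwise they are left unset and can be attached with
#' [set_tnf_input()] and [set_death_rule()].
#'
#' @param path path to an SBML file.
#' @return a `reaction_network`.
#' @export
load_sbml <- function(path) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML in '", path, "': ",
                                           conditionMessage(e)))
  doc <- xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) stop("malformed SBML: no <model> element")

  for (bad in c("listOfEvents", "listOfRules", "listOfFunctionDefinitions",
                "listOfConstraints", "listOfInitialAssignments")) {
    if (!inherits(xml2::xml_find_first(model, paste0("./", bad)),
                  "xml_missing"))
      stop("unsupported SBML construct: <", bad, ">")
  }

  comp_nodes <- xml2::xml_find_all(model, "./listOfCompartments/compartment")
  compartments <- data.frame(
    id = xml2::xml_attr(comp_nodes, "id"),
    size = .attr_num(comp_nodes, "size", default = 1),
    stringsAsFactors = FALSE)
  if (!nrow(compartments))
    compartments <- data.frame(id = "cell", size = 1)

  sp_nodes <- xml2::xml_find_all(model, "./listOfSpecies/species")
  if (!length(sp_nodes)) stop("malformed SBML: model has no species")
  init_amt <- .attr_num(sp_nodes, "initialAmount", default = NA_real_)
  init_conc <- .attr_num(sp_nodes, "initialConcentration", default = NA_real_)
  initial <- ifelse(is.na(init_amt), init_conc, init_amt)
  initial[is.na(initial)] <- 0
  species <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = .attr_chr(sp_nodes, "name"),
    initial = initial,
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    boundary = .attr_num(sp_nodes, "boundaryCondition", default = 0,
                         logical = TRUE) |
      .attr_num(sp_nodes, "constant", default = 0, logical = TRUE),
    stringsAsFactors = FALSE)
  species$name[is.na(species$name)] <- species$id[is.na(species$name)]

  par_nodes <- xml2::xml_find_all(model, "./listOfParameters/parameter")
  parameters <- stats::setNames(.attr_num(par_nodes, "value", default = 0),
                                xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(model, "./listOfReactions/reaction")
  reactions <- lapply(rx_nodes, .parse_reaction)

  hours_per_unit <- .sbml_time_hours(model)
  meta <- .read_meta(model)

  reaction_network(
    species = species, reactions = reactions, parameters = parameters,
    compartments = compartments,
    id = xml2::xml_attr(model, "id"),
    name = if (!is.na(xml2::xml_attr(model, "name")))
      xml2::xml_attr(model, "name") else xml2::xml_attr(model, "id"),
    hours_per_time_unit = hours_per_unit,
    tnf_species = meta$tnf_species,
    tnf_units_per_ng_ml = meta$tnf_units_per_ng_ml,
    death_rule = meta$death_rule,
    active_caspases = meta$active_caspases,
    requires_equilibration = meta$requires_equilibration)
}

.attr_num <- function(nodes, attr, default = NA_real_, logical = FALSE) {
  v <- xml2::xml_attr(nodes, attr)
  if (logical) return(!is.na(v) & v %in% c("true", "1"))
  out <- suppressWarnings(as.numeric(v))
  out[is.na(v)] <- default
  out
}

.attr_chr <- function(nodes, attr) xml2::xml_attr(nodes, attr)

.parse_reaction <- function(node) {
  rid <- xml2::xml_attr(node, "id")
  stoich <- function(list_name) {
    refs <- xml2::xml_find_all(node, paste0("./", list_name, "/speciesReference"))
    if (!length(refs)) return(integer())
    if (length(xml2::xml_find_all(refs, "./stoichiometryMath")))
      stop("unsupported SBML construct in reaction '", rid,
           "': <stoichiometryMath>")
    s <- .attr_num(refs, "stoichiometry", default = 1)
    if (any(s != round(s)) || any(s <= 0))
      stop("non positive-integer stoichiometry in reaction '", rid, "'")
    stats::setNames(as.integer(s), xml2::xml_attr(refs, "species"))
  }
  kl <- xml2::xml_find_first(node, "./kineticLaw")
  if (inherits(kl, "xml_missing"))
    stop("reaction '", rid, "' has no <kineticLaw>")
  math <- xml2::xml_find_first(kl, "./math")
  if (inherits(math, "xml_missing"))
    stop("kineticLaw of reaction '", rid, "' has no <math>")
  kids <- xml2::xml_children(math)
  if (length(kids) != 1L)
    stop("kineticLaw math of reaction '", rid, "' must have one root element")
  locals_nodes <- xml2::xml_find_all(kl, "./listOfParameters/parameter")
  locals <- stats::setNames(.attr_num(locals_nodes, "value", default = 0),
                            xml2::xml_attr(locals_nodes, "id"))
  list(id = rid,
       name = if (!is.na(xml2::xml_attr(node, "name")))
         xml2::xml_attr(node, "name") else rid,
       reactants = stoich("listOfReactants"),
       products = stoich("listOfProducts"),
       rate = mathml_to_expr(kids[[1]]),
       local_params = locals)
}

.sbml_time_hours <- function(model) {
  ud <- xml2::xml_find_first(
    model, "./listOfUnitDefinitions/unitDefinition[@id='time']/listOfUnits/unit")
  if (inherits(ud, "xml_missing")) return(1 / 3600)  # SBML default: seconds
  kind <- xml2::xml_attr(ud, "kind")
  mult <- .attr_num(ud, "multiplier", default = 1)
  scale <- .attr_num(ud, "scale", default = 0)
  secs <- switch(kind, second = mult * 10^scale,
                 hour = 3600 * mult * 10^scale,
                 stop("unsupported time unit kind '", kind, "'"))
  secs / 3600
}

.read_meta <- function(model) {
  out <- list(tnf_species = NA_character_, tnf_units_per_ng_ml = NA_real_,
              death_rule = NULL, active_caspases = character(),
              requires_equilibration = TRUE)
  node <- xml2::xml_find_first(model, "./annotation/meta")
  if (inherits(node, "xml_missing")) return(out)
  g <- function(a) xml2::xml_attr(node, a)
  if (!is.na(g("tnfSpecies"))) out$tnf_species <- g("tnfSpecies")
  if (!is.na(g("tnfUnitsPerNgMl")))
    out$tnf_units_per_ng_ml <- as.numeric(g("tnfUnitsPerNgMl"))
  if (!is.na(g("activeCaspases")) && nzchar(g("activeCaspases"))) {
    entries <- strsplit(g("activeCaspases"), ",")[[1]]
    parts <- strsplit(entries, ":")
    vals <- vapply(parts, function(p) p[length(p)], "")
    nms <- vapply(parts, function(p) if (length(p) == 2) p[1] else "", "")
    out$active_caspases <- stats::setNames(vals, nms)
    if (all(!nzchar(nms))) out$active_caspases <- unname(vals)
  }
  if (!is.na(g("requiresEquilibration")))
    out$requires_equilibration <- g("requiresEquilibration") == "true"
  if (!is.na(g("deathRuleType"))) {
    out$death_rule <- switch(
      g("deathRuleType"),
      parp_fraction = list(type = "parp_fraction", parp = g("deathParp"),
                           cleaved = g("deathCleaved"),
                           fraction = as.numeric(g("deathFraction"))),
      threshold = list(type = "threshold", species = g("deathSpecies"),
                       theta = as.numeric(g("deathTheta"))))
  }
  out
}

## ---- MathML <-> R expressions -------------------------------------------

.MATHML_OPS <- c(times = "*", plus = "+", minus = "-", divide = "/",
                 power = "^")

#' @keywords internal
mathml_to_expr <- function(node) {
  name <- xml2::xml_name(node)
  if (name == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (name == "cn") {
    type <- xml2::xml_attr(node, "type")
    if (!is.na(type) && type == "e-notation") {
      parts <- xml2::xml_contents(node)
      nums <- trimws(vapply(parts, xml2::xml_text, ""))
      nums <- nums[nzchar(nums)]
      return(as.numeric(nums[1]) * 10^as.numeric(nums[2]))
    }
    return(as.numeric(trimws(xml2::xml_text(node))))
  }
  if (name == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- lapply(kids[-1], mathml_to_expr)
    if (op %in% names(.MATHML_OPS)) {
      sym <- .MATHML_OPS[[op]]
      if (op == "minus" && length(args) == 1L)
        return(call("-", args[[1]]))
      if (length(args) < 2L)
        stop("MathML <", op, "> needs at least two operands")
      return(Reduce(function(a, b) call(sym, a, b), args))
    }
    if (op == "exp") return(call("exp", args[[1]]))
    if (op == "ln") return(call("log", args[[1]]))
    if (op == "log") return(call("log", args[[1]], 10))
    stop("unsupported MathML operator <", op, ">")
  }
  stop("unsupported MathML element <", name, ">")
}

#' @keywords internal
expr_to_mathml <- function(e) {
  if (is.numeric(e)) {
    return(sprintf("<cn> %s </cn>", format(e, digits = 17)))
  }
  if (is.name(e)) return(sprintf("<ci> %s </ci>", as.character(e)))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    tag <- names(.MATHML_OPS)[match(op, .MATHML_OPS)]
    args <- lapply(as.list(e)[-1], expr_to_mathml)
    if (op == "-" && length(args) == 1L)
      return(paste0("<apply><minus/>", args[[1]], "</apply>"))
    if (!is.na(tag))
      return(paste0("<apply><", tag, "/>",
                    paste(unlist(args), collapse = ""), "</apply>"))
    if (op == "exp")
      return(paste0("<apply><exp/>", args[[1]], "</apply>"))
    if (op == "log" && length(args) == 1L)
      return(paste0("<apply><ln/>", args[[1]], "</apply>"))
    if (op == "(") return(args[[1]])
    stop("cannot serialize operator '", op, "' to MathML")
  }
  stop("cannot serialize expression of class ", class(e)[1])
}

#' Write a reaction network as SBML
#'
#' Emits an SBML level 2 version 4 document that [load_sbml()] reads back into
#' an identical network (same ids, stoichiometry, parameter values and kinetic
#' laws). Package-specific metadata (stimulus species, dose conversion, death
#' rule) is stored in a model annotation so it round-trips too.
#'
#' @param network a `reaction_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(network, path) {
  stopifnot(inherits(network, "reaction_network"))
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" level="2" version="4">', .SBML_NS),
    sprintf('<model id="%s" name="%s">', network$id, esc(network$name)),
    .meta_xml(network),
    '<listOfUnitDefinitions><unitDefinition id="time"><listOfUnits>',
    sprintf('<unit kind="second" multiplier="%s"/>',
            format(network$hours_per_time_unit * 3600, digits = 17)),
    '</listOfUnits></unitDefinition></listOfUnitDefinitions>',
    "<listOfCompartments>",
    sprintf('<compartment id="%s" size="%s"/>',
            network$compartments$id,
            format(network$compartments$size, digits = 17)),
    "</listOfCompartments>",
    "<listOfSpecies>",
    sprintf('<species id="%s" name="%s" compartment="%s" initialAmount="%s" boundaryCondition="%s"/>',
            network$species$id, esc(network$species$name),
            network$species$compartment,
            format(network$species$initial, digits = 17),
            ifelse(network$species$boundary, "true", "false")),
    "</listOfSpecies>")
  if (length(network$parameters))
    lines <- c(lines, "<listOfParameters>",
               sprintf('<parameter id="%s" value="%s"/>',
                       names(network$parameters),
                       format(network$parameters, digits = 17)),
               "</listOfParameters>")
  lines <- c(lines, "<listOfReactions>")
  for (r in network$reactions) {
    lines <- c(lines, sprintf('<reaction id="%s" name="%s" reversible="false">',
                              r$id, esc(r$name)))
    refl <- function(tag, st) {
      if (!length(st)) return(character())
      c(sprintf("<%s>", tag),
        sprintf('<speciesReference species="%s" stoichiometry="%d"/>',
                names(st), st),
        sprintf("</%s>", tag))
    }
    lines <- c(lines, refl("listOfReactants", r$reactants),
               refl("listOfProducts", r$products),
               "<kineticLaw>",
               '<math xmlns="http://www.w3.org/1998/Math/MathML">',
               expr_to_mathml(r$rate), "</math>")
    if (length(r$local_params))
      lines <- c(lines, "<listOfParameters>",
                 sprintf('<parameter id="%s" value="%s"/>',
                         names(r$local_params),
                         format(r$local_params, digits = 17)),
                 "</listOfParameters>")
    lines <- c(lines, "</kineticLaw>", "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

.meta_xml <- function(network) {
  attrs <- c(
    if (!is.na(network$tnf_species))
      sprintf('tnfSpecies="%s"', network$tnf_species),
    if (!is.na(network$tnf_units_per_ng_ml))
      sprintf('tnfUnitsPerNgMl="%s"',
              format(network$tnf_units_per_ng_ml, digits = 17)),
    if (length(network$active_caspases))
      sprintf('activeCaspases="%s"', {
        ac <- network$active_caspases
        nms <- if (is.null(names(ac))) rep("", length(ac)) else names(ac)
        paste(ifelse(nzchar(nms), paste0(nms, ":", ac), ac), collapse = ",")
      }),
    sprintf('requiresEquilibration="%s"',
            if (network$requires_equilibration) "true" else "false"))
  dr <- network$death_rule
  if (!is.null(dr)) {
    attrs <- c(attrs, sprintf('deathRuleType="%s"', dr$type))
    if (dr$type == "parp_fraction")
      attrs <- c(attrs,
                 sprintf('deathParp="%s"', dr$parp),
                 sprintf('deathCleaved="%s"', dr$cleaved),
                 sprintf('deathFraction="%s"', format(dr$fraction, digits = 17)))
    if (dr$type == "threshold")
      attrs <- c(attrs,
                 sprintf('deathSpecies="%s"', dr$species),
                 sprintf('deathTheta="%s"', format(dr$theta, digits = 17)))
  }
  sprintf('<annotation><meta xmlns="%s" %s/></annotation>',
          .META_NS, paste(attrs, collapse = " "))
}
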