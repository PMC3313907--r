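# Shared fixtures: tiny networks with closed-form behavior.

# production-degradation pair: dX/dt = k - g*X, steady state k/g
make_prod_deg <- function(k = 2, g = 0.5) {
  reaction_network(
    species = data.frame(id = "X", initial = 0, compartment = "cell"),
    reactions = list(
      list(id = "prod", reactants = integer(), products = c(X = 1L),
           rate = quote(k_syn)),
      list(id = "deg", reactants = c(X = 1L), products = integer(),
           rate = quote(g_deg * X))),
    parameters = c(k_syn = k, g_deg = g),
    id = "prod_deg", hours_per_time_unit = 1,
    requires_equilibration = TRUE)
}

# minimal SBML document: one species, one zeroth-order production reaction
minimal_sbml <- function(path, k = 3) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="mini" name="minimal production model">',
    '<listOfCompartments><compartment id="cell" size="1"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="X" compartment="cell" initialAmount="0"/>',
    '</listOfSpecies>',
    sprintf('<listOfParameters><parameter id="k" value="%g"/></listOfParameters>', k),
    '<listOfReactions><reaction id="prod_X">',
    '<listOfProducts><speciesReference species="X" stoichiometry="1"/></listOfProducts>',
    '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<ci> k </ci>',
    '</math></kineticLaw>',
    '</reaction></listOfReactions>',
    '</model></sbml>'), path)
  path
}

# short-horizon protocol used to create censored survivors on the demo model
demo_protocol <- function(dose = 10, mode = "continuous", horizon = 100)
  stimulus_protocol(dose, mode, horizon = horizon)
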