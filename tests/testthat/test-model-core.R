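test_that("network construction validates species, stoichiometry and values", {
  sp <- data.frame(id = "X", initial = 0, compartment = "cell")
  expect_error(reaction_network(
    sp, list(list(id = "r", reactants = integer(), products = c(Y = 1L),
                  rate = quote(1)))), "unknown species")
  expect_error(reaction_network(
    sp, list(list(id = "r", reactants = integer(), products = c(X = 1L),
                  rate = quote(k * Z))),
    parameters = c(k = 1)), "unknown symbol")
  expect_error(reaction_network(
    sp, list(list(id = "r", reactants = c(X = 0.5), products = integer(),
                  rate = quote(1)))), "positive integers")
  expect_error(reaction_network(
    data.frame(id = "X", initial = -1, compartment = "cell"), list()),
    "finite and >= 0")
  expect_error(reaction_network(sp, list(), parameters = c(k = NaN)),
               "finite and >= 0")
})

test_that("minimal SBML file loads with ids preserved", {
  path <- withr::local_tempfile(fileext = ".xml")
  minimal_sbml(path, k = 3)
  net <- load_sbml(path)
  expect_s3_class(net, "reaction_network")
  expect_equal(net$species$id, "X")
  expect_equal(names(net$reactions), "prod_X")
  expect_equal(unname(net$parameters["k"]), 3)
  expect_equal(net$production_rate_ids, "k")
})

test_that("SBML round trip preserves parameters, stoichiometry and kinetics", {
  net <- example_tnf_network()
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(net, path)
  net2 <- load_sbml(path)
  expect_equal(net2$parameters, net$parameters)
  expect_equal(net2$species, net$species)
  expect_equal(lapply(net2$reactions, function(r) r$reactants),
               lapply(net$reactions, function(r) r$reactants))
  expect_equal(lapply(net2$reactions, function(r) r$products),
               lapply(net$reactions, function(r) r$products))
  expect_equal(lapply(net2$reactions, function(r) deparse(r$rate)),
               lapply(net$reactions, function(r) deparse(r$rate)))
  expect_equal(net2$death_rule, net$death_rule)
  expect_equal(net2$active_caspases, net$active_caspases)
  expect_equal(net2$tnf_units_per_ng_ml, net$tnf_units_per_ng_ml)
  # second round trip is byte-stable modulo the file, so dynamics agree
  rhs1 <- build_rhs(net)
  rhs2 <- build_rhs(net2)
  st <- stats::setNames(c(5, 80, 3, 90, 1, 40, 70, 30), net$species$id)
  expect_equal(rhs2(0, st), rhs1(0, st))
})

test_that("malformed and unsupported SBML fail loudly", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model>", bad)
  expect_error(load_sbml(bad), "malformed")
  expect_error(load_sbml(file.path(tempdir(), "no_such_file.xml")),
               "not found")
  ev <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="m"><listOfSpecies>',
    '<species id="X" compartment="c" initialAmount="0"/></listOfSpecies>',
    '<listOfEvents><event id="e"/></listOfEvents>',
    '</model></sbml>'), ev)
  expect_error(load_sbml(ev), "listOfEvents")
})

test_that("production rates are the zeroth-order synthesis constants", {
  net <- example_tnf_network()
  expect_equal(identify_production_rates(net),
               c("k_prod_R", "k_prod_C8", "k_prod_I"))
  # stimulus-induced synthesis (rate depends on a species) is NOT distributed
  expect_false("k_ind" %in% net$production_rate_ids)
  toy <- make_toy_timer()
  expect_equal(identify_production_rates(toy), "k_prod")
  nodeg <- make_prod_deg()
  ko <- apply_knockout(nodeg, "prod")
  expect_equal(identify_production_rates(ko), character())
})

test_that("knockout zeroes one reaction, is idempotent, copies the network", {
  net <- example_tnf_network()
  ko <- apply_knockout(net, "induce_I")
  expect_identical(ko$reactions[["induce_I"]]$rate, quote(0))
  # original untouched
  expect_false(identical(net$reactions[["induce_I"]]$rate, quote(0)))
  expect_identical(apply_knockout(ko, "induce_I")$reactions,
                   ko$reactions)
  expect_error(apply_knockout(net, "no_such_rx"), "available")
})

test_that("knocked-out toy production freezes the species forever", {
  toy <- make_toy_timer(k = 1, theta = 5)
  ko <- apply_knockout(toy, "prod_X")
  res <- simulate_cell(ko, protocol = stimulus_protocol(0, horizon = 50))
  expect_equal(res$fate$status, "survived")
  expect_true(all(abs(res$trajectory$state[, "X"]) < 1e-10))
})

test_that("RHS applies multipliers linearly and matches an Euler oracle", {
  toy <- make_toy_timer(k = 2, theta = 5)
  f <- build_rhs(toy, cell_parameters(c(k_prod = 3)))
  expect_equal(unname(f(0, c(X = 0))), 6)   # dX/dt = m * k everywhere
  expect_equal(unname(f(10, c(X = 99))), 6)

  net <- example_tnf_network()
  f1 <- build_rhs(net)
  f2 <- build_rhs(net, cell_parameters(c(k_prod_C8 = 2)))
  st <- stats::setNames(c(10, 50, 5, 80, 2, 40, 90, 10), net$species$id)
  d1 <- f1(0, st); d2 <- f2(0, st)
  # doubling a production multiplier adds exactly its nominal flux
  expect_equal(d2[["C8"]] - d1[["C8"]], net$parameters[["k_prod_C8"]])
  expect_equal(d2[["R"]], d1[["R"]])

  expect_error(build_rhs(net, cell_parameters(c(nope = 1))), "unknown")

  # independent numerical oracle: the secant of a short integrated step
  # must match the reported derivative to first order
  set.seed(42)
  h <- 1e-4
  for (i in 1:3) {
    st <- stats::setNames(stats::runif(8, 0, 100), net$species$id)
    st["TNF"] <- stats::runif(1, 0, 10)
    d0 <- f1(0, st)
    out <- deSolve::lsoda(st, c(0, h), function(t, y, p) list(f1(t, y)),
                          parms = NULL, rtol = 1e-10, atol = 1e-12)
    secant <- (out[2, -1] - st) / h
    expect_equal(unname(secant), unname(d0), tolerance = 1e-2)
  }
})

test_that("zero state with zero production gives zero derivative", {
  net <- example_tnf_network()
  zero_prod <- net
  zero_prod$parameters[c("k_prod_R", "k_prod_C8", "k_prod_I")] <- 0
  f <- build_rhs(zero_prod)
  st <- stats::setNames(rep(0, 8), net$species$id)
  expect_equal(unname(f(0, st)), rep(0, 8))
})

test_that("conserved PARP moiety stays constant along trajectories", {
  net <- example_tnf_network()
  res <- simulate_cell(net, protocol = stimulus_protocol(10, "continuous",
                                                         horizon = 20))
  total <- res$trajectory$state[, "PARP"] + res$trajectory$state[, "cPARP"]
  expect_equal(total, rep(total[1], length(total)), tolerance = 1e-7)
})

test_that("network JSON summary is written and machine-readable", {
  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(example_tnf_network(), path)
  j <- jsonlite::read_json(path)
  expect_equal(length(j$reactions), 13)
  expect_equal(unlist(j$production_rate_ids),
               c("k_prod_R", "k_prod_C8", "k_prod_I"))
})
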