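test_that("pure production has no steady state and equilibrate says so", {
  toy <- make_toy_timer()
  expect_error(equilibrate(toy, budget_hours = 50), "no steady state")
})

test_that("equilibrated steady state persists without stimulus", {
  net <- example_tnf_network()
  ss <- equilibrate(net)
  res <- simulate_cell(net, protocol = stimulus_protocol(0, horizon = 100),
                       init = ss)
  expect_equal(res$fate$status, "survived")
  final <- res$trajectory$state[nrow(res$trajectory$state), ]
  expect_equal(final, ss, tolerance = 1e-6)
})

test_that("equilibration is covariant with production multipliers", {
  # closed form: dX/dt = m k - g X  =>  X* = m k / g
  net <- make_prod_deg(k = 2, g = 0.5)
  for (m in c(0.7, 1, 1.6)) {
    ss <- equilibrate(net, cell_parameters(c(k_syn = m)))
    expect_equal(unname(ss["X"]), m * 2 / 0.5, tolerance = 1e-6)
  }
})

test_that("a caspase-contaminated steady state is rejected", {
  net <- example_tnf_network()
  # force a residual stimulus through a nonzero TNF production so the
  # equilibrated state carries active caspase
  poisoned <- net
  poisoned$species$boundary[poisoned$species$id == "TNF"] <- FALSE
  poisoned$reactions <- c(poisoned$reactions, list(
    leak = list(id = "leak", name = "ligand leak", reactants = integer(),
                products = c(TNF = 1L), rate = quote(0.5),
                local_params = numeric())))
  expect_error(equilibrate(poisoned, budget_hours = 4000),
               "caspase|steady state")
})

test_that("an unstimulated cell survives with a flat trajectory", {
  net <- example_tnf_network()
  res <- simulate_cell(net, protocol = stimulus_protocol(0, horizon = 50))
  expect_equal(res$fate$status, "survived")
  expect_true(is.na(res$fate$tod_h))
  rng <- apply(res$trajectory$state, 2, function(x) diff(range(x)))
  expect_true(all(rng < 1e-4 * pmax(res$trajectory$state[1, ], 1)))
})

test_that("death event is bracketed: below criterion before, at it after", {
  net <- example_tnf_network()
  res <- simulate_cell(net, protocol = stimulus_protocol(10, "continuous"))
  expect_equal(res$fate$status, "died")
  tod <- res$fate$tod_h
  total0 <- res$trajectory$state[1, "PARP"] + res$trajectory$state[1, "cPARP"]
  before <- res$trajectory$time < tod - 0.02
  expect_true(all(res$trajectory$state[before, "cPARP"] < 0.5 * total0))
  # integration stops at the root: the last stored state is at 50% cleavage
  last <- nrow(res$trajectory$state)
  expect_equal(unname(res$trajectory$state[last, "cPARP"] / total0), 0.5,
               tolerance = 1e-5)
  expect_equal(res$trajectory$time[last], tod, tolerance = 1e-4)
})

test_that("tightening solver tolerances barely moves the death time", {
  net <- example_tnf_network()
  spec <- ensemble_spec(n_cells = 10, sigma = 0.148, seed = 21)
  pop <- sample_population(spec, net)
  p <- stimulus_protocol(10, "continuous")
  for (i in seq_along(pop)) {
    t1 <- simulate_cell(net, pop[[i]], p)$fate$tod_h
    t2 <- simulate_cell(net, pop[[i]], p, rtol = 1e-9, atol = 1e-13)$fate$tod_h
    expect_lt(abs(t1 - t2), 0.05)
  }
})

test_that("extending the horizon only converts survivors to late deaths", {
  net <- example_tnf_network()
  spec <- ensemble_spec(n_cells = 30, sigma = 0.3, seed = 8)
  pop <- sample_population(spec, net)
  short <- simulate_population(net, pop, stimulus_protocol(10, "continuous",
                                                           horizon = 7))
  long <- simulate_population(net, pop, stimulus_protocol(10, "continuous",
                                                          horizon = 40))
  expect_true(any(short$status == "survived"))  # censoring is active
  died_short <- short$status == "died"
  expect_equal(long$tod_h[died_short], short$tod_h[died_short],
               tolerance = 1e-6)
  converted <- short$status == "survived" & long$status == "died"
  expect_true(all(long$tod_h[converted] >= 7 - 1e-6))
})

test_that("population simulation of one nominal cell matches simulate_cell", {
  net <- example_tnf_network()
  spec <- ensemble_spec(n_cells = 1, sigma = 0, seed = 1)
  pop <- sample_population(spec, net)
  p <- stimulus_protocol(10, "continuous")
  fates <- simulate_population(net, pop, p)
  single <- simulate_cell(net, protocol = p)$fate
  expect_equal(fates$tod_h[1], single$tod_h, tolerance = 1e-9)
})

test_that("zero dose leaves the whole population alive", {
  net <- example_tnf_network()
  spec <- ensemble_spec(n_cells = 5, sigma = 0.148, seed = 2)
  pop <- sample_population(spec, net)
  fates <- simulate_population(net, pop, stimulus_protocol(0, horizon = 30))
  expect_true(all(fates$status == "survived"))
  expect_equal(summarize_fates(fates)$death_rate, 0)
})

test_that("viability curve counts censored and dying cells correctly", {
  fates <- data.frame(cell = 1:4,
                      status = c("died", "died", "survived", "survived"),
                      tod_h = c(2, 4, NA, NA))
  expect_equal(viability_curve(fates, c(1, 3, 5)), c(1, 0.75, 0.5))
  all_surv <- data.frame(cell = 1:3, status = "survived", tod_h = NA_real_)
  expect_equal(viability_curve(all_surv, 0:10), rep(1, 11))
})

test_that("higher continuous dose kills earlier across the population", {
  net <- example_tnf_network()
  spec <- ensemble_spec(n_cells = 40, sigma = 0.148, seed = 11)
  pop <- sample_population(spec, net)
  lo <- simulate_population(net, pop, stimulus_protocol(1, "continuous",
                                                        horizon = 60))
  hi <- simulate_population(net, pop, stimulus_protocol(30, "continuous",
                                                        horizon = 60))
  grid <- seq(0, 60, by = 2)
  expect_true(all(viability_curve(hi, grid) <= viability_curve(lo, grid) + 1e-12))
  v <- viability_curve(hi, grid)
  expect_true(all(diff(v) <= 1e-12))  # non-increasing
  expect_equal(v[1], 1)
})

test_that("trajectory normalization maps courses to [0, 1] with max 1", {
  traj <- structure(list(time = 0:2,
                         state = cbind(A = c(0, 2, 4), B = c(3, 3, 3),
                                       Z = c(0, 0, 0))),
                    class = "cell_trajectory")
  expect_equal(normalize_trajectory(traj, "A"), c(0, 0.5, 1))
  expect_equal(normalize_trajectory(traj, "B"), c(1, 1, 1))
  expect_warning(z <- normalize_trajectory(traj, "Z"), "zero")
  expect_equal(z, c(0, 0, 0))
  expect_error(normalize_trajectory(traj, "Q"), "not in trajectory")
})

test_that("fates CSV export stores multipliers, status and times", {
  net <- example_tnf_network()
  spec <- ensemble_spec(n_cells = 3, sigma = 0.148, seed = 6)
  pop <- sample_population(spec, net)
  fates <- simulate_population(net, pop, stimulus_protocol(10, "continuous"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fates_csv(fates, path)
  d <- utils::read.csv(path)
  expect_equal(nrow(d), 3)
  expect_true(all(c("cell", "k_prod_R", "k_prod_C8", "k_prod_I",
                    "status", "tod_h") %in% names(d)))
  expect_equal(d$tod_h, fates$tod_h, tolerance = 1e-9)
})
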