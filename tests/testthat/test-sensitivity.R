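test_that("robust fit recovers exact lines and degenerate cases", {
  x <- seq(-1, 1, length.out = 20)
  f <- robust_fit(x, 2 * x + 1)
  expect_equal(f$slope, 2, tolerance = 1e-10)
  expect_equal(f$intercept, 1, tolerance = 1e-10)
  expect_equal(f$error_sd, 0)
  fc <- robust_fit(x, rep(3, 20))
  expect_equal(fc$slope, 0, tolerance = 1e-10)
  expect_error(robust_fit(rep(1, 5), 1:5), "degenerate")
  expect_error(robust_fit(1:2, 1:2), "at least 3")
})

test_that("bisquare fit resists a high-leverage outlier better than OLS", {
  set.seed(7)
  x <- c(stats::runif(50, -1, 1), 10)
  y <- x
  y[51] <- -10  # gross outlier at 10x leverage
  rob <- robust_fit(x, y)
  ols <- stats::lm.fit(cbind(1, x), y)$coefficients[2]
  expect_lt(abs(rob$slope - 1), 0.05)
  expect_gt(abs(ols - 1), abs(rob$slope - 1))
})

test_that("slopes are invariant to log base and to ToD rescaling", {
  d <- generate_tod_dataset(slope = -0.7, noise_sd = 0.05, n = 400, seed = 9)
  x <- log(d$multiplier); y <- log(d$tod_h)
  nat <- robust_fit(x, y)
  b10 <- robust_fit(x / log(10), y / log(10))
  expect_equal(b10$slope, nat$slope, tolerance = 1e-12)
  scaled <- robust_fit(x, log(24 * d$tod_h))  # hours -> days offset
  expect_equal(scaled$slope, nat$slope, tolerance = 1e-9)
  expect_equal(scaled$intercept - nat$intercept, log(24), tolerance = 1e-6)
})

test_that("toy-ensemble population slope is exactly -1", {
  toy <- make_toy_timer(k = 1, theta = 5)
  spec <- ensemble_spec(n_cells = 200, sigma = 0.148, seed = 13,
                        distributed_ids = "k_prod")
  pop <- sample_population(spec)
  fates <- simulate_population(toy, pop,
                               stimulus_protocol(0, horizon = 100),
                               n_out = 21)
  s <- population_sensitivity(fates)
  expect_equal(s$slope, -1, tolerance = 1e-7)
  expect_equal(s$n_dying, 200)
})

test_that("the estimator recovers a known slope and tightens with n", {
  errs <- vapply(c(100, 1000, 10000), function(n) {
    d <- generate_tod_dataset(slope = 0.5, noise_sd = 0.2, n = n, seed = 17)
    f <- robust_fit(log(d$multiplier), log(d$tod_h))
    abs(f$slope - 0.5)
  }, numeric(1))
  # Monte-Carlo scale: sd approx noise_sd / (sqrt(n) * 0.148); allow 4 sd
  expect_lt(errs[1], 4 * 0.2 / (sqrt(100) * 0.148))
  expect_lt(errs[3], 4 * 0.2 / (sqrt(10000) * 0.148))
  expect_lt(errs[3], errs[1])
})

test_that("survivors are excluded from the fit and tallied by decile", {
  d <- generate_tod_dataset(slope = -1, noise_sd = 0.1, n = 800,
                            censor_fraction = 0.25, seed = 31)
  fates <- data.frame(cell = seq_len(nrow(d)), status = d$status,
                      tod_h = d$tod_h)
  m <- matrix(d$multiplier, ncol = 1, dimnames = list(NULL, "k"))
  s <- population_sensitivity(fates, multipliers = m)
  expect_equal(s$n_dying[1], sum(d$status == "died"))
  expect_equal(attr(s, "n_survived"), sum(d$status == "survived"))
  expect_equal(sum(attr(s, "survivors_by_decile")$k),
               sum(d$status == "survived"))
  expect_equal(s$slope[1], -1, tolerance = 0.05)
})

test_that("too few dying cells is an explicit error", {
  fates <- data.frame(cell = 1:5, status = c("died", "died", rep("survived", 3)),
                      tod_h = c(2, 3, NA, NA, NA))
  m <- matrix(stats::runif(5, 0.5, 2), ncol = 1, dimnames = list(NULL, "k"))
  expect_error(population_sensitivity(fates, multipliers = m),
               "insufficient deaths")
})

test_that("nominal x1.1 slope of the toy timer is exactly -1", {
  toy <- make_toy_timer(k = 2, theta = 7)
  ns <- nominal_sensitivity(toy, stimulus_protocol(0, horizon = 100))
  expect_true(ns$defined)
  expect_equal(ns$slope, -1, tolerance = 1e-10)
  # the factor cancels in the closed form
  ns2 <- nominal_sensitivity(toy, stimulus_protocol(0, horizon = 100),
                             factor = 1.5)
  expect_equal(ns2$slope, -1, tolerance = 1e-10)
})

test_that("a parameter without influence on death has zero nominal slope", {
  # two-species network: timer X plus an inert reporter Y with its own
  # production; Y never feeds back on X
  net <- reaction_network(
    species = data.frame(id = c("X", "Y"), initial = 0, compartment = "cell"),
    reactions = list(
      list(id = "prod_X", reactants = integer(), products = c(X = 1L),
           rate = quote(k_x)),
      list(id = "prod_Y", reactants = integer(), products = c(Y = 1L),
           rate = quote(k_y))),
    parameters = c(k_x = 1, k_y = 1),
    id = "timer_plus_reporter", hours_per_time_unit = 1,
    death_rule = list(type = "threshold", species = "X", theta = 5),
    requires_equilibration = FALSE)
  ns <- nominal_sensitivity(net, stimulus_protocol(0, horizon = 100))
  expect_equal(ns$slope[ns$parameter == "k_y"], 0, tolerance = 1e-10)
  expect_equal(ns$slope[ns$parameter == "k_x"], -1, tolerance = 1e-10)
})

test_that("surviving perturbed cells flag the slope undefined, not zero", {
  net <- example_tnf_network()
  # at a weak dose and short horizon the nominal cell survives
  ns <- nominal_sensitivity(net, stimulus_protocol(0.3, horizon = 10),
                            parameters = "k_prod_C8")
  expect_false(ns$defined)
  expect_true(is.na(ns$slope))
})

test_that("sensitivity report classifies and merges protocols", {
  mk <- function(slopes, proto) {
    s <- data.frame(parameter = names(slopes), slope = unname(slopes),
                    error_sd = 0.1, intercept = 0, n_dying = 100)
    structure(s, class = c("tod_sensitivity", "data.frame"),
              n_total = 120, n_survived = 20, protocol = proto,
              survivors_by_decile = list())
  }
  cont <- mk(c(inh = 0.8, rec = -0.5, idle = 0.03), NULL)
  puls <- mk(c(inh = 0.5, rec = -0.2, idle = 0.01), NULL)
  rep <- sensitivity_report(cont, puls)
  expect_equal(nrow(rep), 6)
  expect_equal(rep$group[rep$parameter == "inh" & rep$protocol == "continuous"],
               "later_death")
  expect_equal(rep$group[rep$parameter == "rec" & rep$protocol == "continuous"],
               "earlier_death")
  expect_equal(rep$group[rep$parameter == "idle" & rep$protocol == "pulse"],
               "negligible")
  expect_true(all(classify_slopes(c(0, 0, 0)) == "negligible"))
  bad <- mk(c(other = 1), NULL)
  expect_error(sensitivity_report(cont, bad), "different parameter sets")
})
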