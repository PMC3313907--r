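#' Specification of a heterogeneous cell population
#'
#' The cell-ensemble model varies all protein production (expression) rates
#' independently across cells, lognormally distributed around the nominal
#' single-cell model. The default spread sigma = 0.148 on the natural-log
#' scale and the default population size of 2500 cells are the study
#' configuration this package reproduces.
#'
#' @param n_cells number of cells (>= 1); default 2500.
#' @param sigma standard deviation of the log-multipliers (>= 0); default
#'   0.148 (natural log).
#' @param seed integer RNG seed.
#' @param distributed_ids parameter ids to distribute; default `NULL` means
#'   all production rates of the network the population is applied to.
#' @param center `"mean"` (default) centers the lognormal so its MEAN equals
#'   the nominal value (mu_log = -sigma^2/2); `"median"` puts the median at
#'   the nominal value (mu_log = 0). At sigma = 0.148 the two differ by about
#'   1.1 percent.
#' @return an object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_cells = 2500, sigma = 0.148, seed = 1,
                          distributed_ids = NULL,
                          center = c("mean", "median")) {
  center <- match.arg(center)
  if (!is.numeric(sigma) || (!is.na(sigma) && sigma < 0))
    stop("sigma must be >= 0")
  stopifnot(n_cells >= 1)
  structure(list(n_cells = as.integer(n_cells), sigma = sigma,
                 seed = as.integer(seed), distributed_ids = distributed_ids,
                 center = center),
            class = "ensemble_spec")
}

#' Sample a heterogeneous cell population
#'
#' Draws `n_cells` parameter sets, each multiplier i.i.d. lognormal with
#' log-scale spread `sigma`. Draws are cell-major (all multipliers of cell 1,
#' then cell 2, ...) in the order of `distributed_ids`, from a single RNG
#' stream seeded with `spec$seed`, so populations are bitwise reproducible
#' and independent of execution parallelism.
#'
#' @param spec an [ensemble_spec()].
#' @param network optional `reaction_network`; when `spec$distributed_ids` is
#'   `NULL` the network's production rates are distributed.
#' @return an object of class `cell_population`: a list of
#'   [cell_parameters()] with attributes `spec` and `matrix` (cells x
#'   parameters).
#' @export
sample_population <- function(spec, network = NULL) {
  stopifnot(inherits(spec, "ensemble_spec"))
  ids <- spec$distributed_ids
  if (is.null(ids)) {
    if (is.null(network))
      stop("distributed_ids not given and no network supplied")
    ids <- network$production_rate_ids
  }
  if (!length(ids)) stop("no distributed parameter ids")
  mu <- if (spec$center == "mean") -spec$sigma^2 / 2 else 0
  n <- spec$n_cells
  withr_seed <- .with_seed(spec$seed, {
    m <- matrix(stats::rlnorm(n * length(ids), meanlog = mu,
                              sdlog = spec$sigma),
                nrow = n, ncol = length(ids), byrow = TRUE,
                dimnames = list(NULL, ids))
    m
  })
  m <- withr_seed
  if (spec$sigma == 0) m[] <- 1  # exact nominal cells, no rounding residue
  cells <- lapply(seq_len(n), function(i) cell_parameters(m[i, ]))
  structure(cells, class = "cell_population", spec = spec, matrix = m)
}

# evaluate expr under a local RNG seed, restoring the global RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' @export
print.cell_population <- function(x, ...) {
  spec <- attr(x, "spec")
  m <- attr(x, "matrix")
  cat(sprintf("Cell population: %d cells x %d distributed rates (sigma = %g, seed = %d)\n",
              length(x), ncol(m), spec$sigma, spec$seed))
  invisible(x)
}

#' Extract the multiplier matrix of a population
#'
#' @param population a `cell_population`.
#' @return numeric matrix, cells x distributed parameters.
#' @export
population_matrix <- function(population) {
  stopifnot(inherits(population, "cell_population"))
  attr(population, "matrix")
}

#' Write / read a population as CSV
#'
#' One row per cell, one column per distributed parameter id, so sampled
#' populations are replayable and shareable across runs.
#'
#' @param population a `cell_population`.
#' @param path CSV file path.
#' @return `path` (write) or a `cell_population` (read).
#' @export
write_population_csv <- function(population, path) {
  m <- population_matrix(population)
  utils::write.csv(data.frame(cell = seq_len(nrow(m)), m,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(d[, setdiff(names(d), "cell"), drop = FALSE])
  cells <- lapply(seq_len(nrow(m)), function(i) cell_parameters(m[i, ]))
  structure(cells, class = "cell_population", matrix = m,
            spec = ensemble_spec(n_cells = nrow(m), sigma = NA_real_,
                                 seed = NA_integer_,
                                 distributed_ids = colnames(m)))
}

#' Closed-form death-timer toy model
#'
#' The simplest network with a death event: one species produced at constant
#' rate k from X(0) = 0, dying when X reaches the threshold theta, so the
#' time of death is exactly theta / k and the log-log elasticity of the time
#' of death with respect to k is exactly -1. This closed form is the ground
#' truth against which the population and nominal sensitivity estimators are
#' validated.
#'
#' @param k production rate (> 0), units 1/h.
#' @param theta death threshold (> 0).
#' @return a `reaction_network` whose only production rate is `k_prod`.
#' @export
make_toy_timer <- function(k = 1, theta = 5) {
  stopifnot(k > 0, theta > 0)
  reaction_network(
    species = data.frame(id = "X", name = "death timer", initial = 0,
                         compartment = "cell", boundary = FALSE),
    reactions = list(list(id = "prod_X", name = "production of X",
                          reactants = integer(),
                          products = c(X = 1L),
                          rate = quote(k_prod))),
    parameters = c(k_prod = k),
    id = "toy_timer", name = "closed-form death timer (synthetic)",
    hours_per_time_unit = 1,
    death_rule = list(type = "threshold", species = "X", theta = theta),
    requires_equilibration = FALSE)
}

#' Synthetic TNF-receptor/caspase demo network
#'
#' A small synthetic single-cell model with the qualitative architecture of
#' TNF-R1 signaling: receptor production and turnover, ligand binding to a
#' signaling complex, complex-catalyzed caspase activation, a stimulus-induced
#' survival branch that boosts a caspase inhibitor, and irreversible PARP
#' cleavage whose 50 percent point defines the time of death. It is NOT the
#' deposited nominal cell model; it exists so the simulator, knockout and
#' sensitivity machinery can be exercised and property-tested end to end.
#' Time unit: hours. TNF model units equal ng/ml (conversion factor 1).
#'
#' Reactions `prod_R`, `prod_C8`, `prod_I` are the zeroth-order production
#' rates eligible for population distribution; `induce_I` (stimulus-induced
#' inhibitor synthesis) is the survival-signaling reaction whose knockout
#' mimics removing anti-apoptotic feedback.
#'
#' @return a `reaction_network` with a `parp_fraction` death rule.
#' @export
example_tnf_network <- function() {
  species <- data.frame(
    id = c("TNF", "R", "C", "C8", "A8", "I", "PARP", "cPARP"),
    name = c("free TNF (ligand)", "TNF receptor", "TNF:receptor complex",
             "procaspase (inactive)", "active caspase",
             "caspase inhibitor", "PARP", "cleaved PARP"),
    initial = c(0, 100, 0, 100, 0, 50, 100, 0),
    compartment = "cell",
    boundary = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  rx <- list(
    list(id = "prod_R", name = "receptor production",
         reactants = integer(), products = c(R = 1L), rate = quote(k_prod_R)),
    list(id = "deg_R", name = "receptor turnover",
         reactants = c(R = 1L), products = integer(), rate = quote(d_R * R)),
    list(id = "bind_TNF", name = "ligand binding",
         reactants = c(R = 1L), products = c(C = 1L),
         rate = quote(k_b * TNF * R)),
    list(id = "deg_C", name = "complex turnover",
         reactants = c(C = 1L), products = integer(), rate = quote(d_C * C)),
    list(id = "prod_C8", name = "procaspase production",
         reactants = integer(), products = c(C8 = 1L),
         rate = quote(k_prod_C8)),
    list(id = "deg_C8", name = "procaspase turnover",
         reactants = c(C8 = 1L), products = integer(),
         rate = quote(d_C8 * C8)),
    list(id = "act_C8", name = "complex-catalyzed caspase activation",
         reactants = c(C8 = 1L), products = c(A8 = 1L),
         rate = quote(k_act * C * C8)),
    list(id = "deg_A8", name = "active caspase turnover",
         reactants = c(A8 = 1L), products = integer(),
         rate = quote(d_A8 * A8)),
    list(id = "prod_I", name = "inhibitor production",
         reactants = integer(), products = c(I = 1L), rate = quote(k_prod_I)),
    list(id = "deg_I", name = "inhibitor turnover",
         reactants = c(I = 1L), products = integer(), rate = quote(d_I * I)),
    list(id = "induce_I", name = "stimulus-induced inhibitor synthesis",
         reactants = integer(), products = c(I = 1L),
         rate = quote(k_ind * C)),
    list(id = "inhibit", name = "inhibitor neutralizes active caspase",
         reactants = c(A8 = 1L, I = 1L), products = integer(),
         rate = quote(k_i * A8 * I)),
    list(id = "cleave_PARP", name = "PARP cleavage by active caspase",
         reactants = c(PARP = 1L), products = c(cPARP = 1L),
         rate = quote(k_cl * A8 * PARP)))
  pars <- c(k_prod_R = 10, d_R = 0.1, k_b = 0.08, d_C = 0.06,
            k_prod_C8 = 5, d_C8 = 0.05, k_act = 0.001, d_A8 = 0.1,
            k_prod_I = 5, d_I = 0.1, k_ind = 0.2, k_i = 0.04,
            k_cl = 0.05)
  reaction_network(
    species = species, reactions = rx, parameters = pars,
    id = "tnf_demo", name = "synthetic TNF receptor/caspase demo network",
    hours_per_time_unit = 1,
    tnf_species = "TNF", tnf_units_per_ng_ml = 1,
    death_rule = list(type = "parp_fraction", parp = "PARP",
                      cleaved = "cPARP", fraction = 0.5),
    active_caspases = c(A8 = "C8"),
    requires_equilibration = TRUE)
}

#' Synthetic time-of-death dataset with known regression structure
#'
#' Generates paired (multiplier, time-of-death) records following
#' log ToD = intercept + slope * log multiplier + Gaussian noise, with a
#' random fraction marked as censored survivors. This is the ground-truth
#' fixture for the regression stage: any sound estimator must recover `slope`
#' from the dying records.
#'
#' @param slope true log-log slope b.
#' @param intercept true intercept a (log-hours).
#' @param noise_sd Gaussian noise standard deviation on log ToD (>= 0).
#' @param n number of records (>= 3).
#' @param censor_fraction fraction marked censored, in [0, 1).
#' @param seed RNG seed.
#' @param sigma log-scale spread of the multipliers (default 0.148).
#' @return data.frame with columns `multiplier`, `status`
#'   (`"died"`/`"survived"`), `tod_h` (`NA` when censored).
#' @export
generate_tod_dataset <- function(slope, intercept = log(10), noise_sd = 0,
                                 n = 2500, censor_fraction = 0, seed = 1,
                                 sigma = 0.148) {
  stopifnot(n >= 3, noise_sd >= 0,
            censor_fraction >= 0, censor_fraction < 1)
  .with_seed(seed, {
    m <- stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
    log_tod <- intercept + slope * log(m) +
      stats::rnorm(n, sd = noise_sd)
    censored <- stats::runif(n) < censor_fraction
    data.frame(multiplier = m,
               status = ifelse(censored, "survived", "died"),
               tod_h = ifelse(censored, NA_real_, exp(log_tod)))
  })
}
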