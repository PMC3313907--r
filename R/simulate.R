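# Stiff simulation of single cells and populations, with event detection of
# the time of death (50 percent PARP cleavage, or a threshold crossing for
# toy fixtures) by root-finding rather than grid lookup: downstream slope
# estimates are sensitive to quantization of the death times.

.initial_state <- function(network) {
  stats::setNames(network$species$initial, network$species$id)
}

# deSolve-facing wrapper: integrates in HOURS regardless of the model's
# internal time unit (dx/dt_hours = f(x) / hours_per_time_unit^-1).
.desolve_func <- function(rhs, time_scale) {
  force(rhs); force(time_scale)
  function(t, y, parms) list(rhs(t, y) * time_scale)
}

.death_root <- function(network, state0) {
  dr <- network$death_rule
  if (is.null(dr)) return(NULL)
  if (dr$type == "threshold") {
    sp <- dr$species; theta <- dr$theta
    return(function(y) y[[sp]] - theta)
  }
  if (dr$type == "parp_fraction") {
    total0 <- state0[[dr$parp]] + state0[[dr$cleaved]]
    if (!(total0 > 0)) stop("total PARP at t = 0 is not positive")
    cl <- dr$cleaved; frac <- dr$fraction
    return(function(y) y[[cl]] - frac * total0)
  }
  stop("unknown death rule type '", dr$type, "'")
}

#' Pre-equilibrate a cell to its unstimulated steady state
#'
#' Integrates the unstimulated system (stimulus species held at 0) until the
#' maximum relative derivative falls below `tol`, and checks that the steady
#' state has no activated caspases: that state is the t = 0 initial condition
#' of every stimulation run. Cells with different production-rate multipliers
#' have different steady states, so equilibration is per cell.
#'
#' @param network a `reaction_network`.
#' @param cell_params a [cell_parameters()] object.
#' @param tol convergence tolerance on the maximum relative derivative
#'   (per hour), default 1e-9.
#' @param budget_hours total integration budget in hours (default 3000 h,
#'   i.e. about 1e7 seconds of model time for a seconds-based model).
#' @param rtol,atol solver tolerances.
#' @return named steady-state vector (model units).
#' @export
equilibrate <- function(network, cell_params = cell_parameters(),
                        tol = 1e-9, budget_hours = 3000,
                        rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(network, "reaction_network"))
  rhs <- build_rhs(network, cell_params)
  f <- .desolve_func(rhs, 1 / network$hours_per_time_unit)

  y <- .initial_state(network)
  if (!is.na(network$tnf_species)) y[network$tnf_species] <- 0

  rel_deriv <- function(y) {
    d <- rhs(0, y) / network$hours_per_time_unit
    max(abs(d) / pmax(abs(y), 1e-6))
  }
  spans <- c(10, 100, 1000)
  spans <- c(spans[spans < budget_hours], budget_hours)
  t_done <- 0
  for (t_end in spans) {
    out <- deSolve::lsoda(y, c(t_done, t_end), f, parms = NULL,
                          rtol = rtol, atol = atol)
    y <- out[nrow(out), -1]
    t_done <- t_end
    if (rel_deriv(y) < tol) break
  }
  if (rel_deriv(y) >= tol)
    stop("no steady state within the equilibration budget (",
         budget_hours, " h): max relative derivative ",
         format(rel_deriv(y), digits = 3), " /h")
  y <- pmax(y, 0)
  .check_caspase_free(network, y)
  y
}

.check_caspase_free <- function(network, state) {
  ac <- network$active_caspases
  if (!length(ac)) return(invisible(TRUE))
  for (i in seq_along(ac)) {
    # named entries map active form (name) -> its procaspase (value); the
    # negligibility threshold is then relative to the procaspase amount at
    # steady state, otherwise to the largest species amount
    named <- !is.null(names(ac)) && nzchar(names(ac)[i])
    sp <- if (named) names(ac)[i] else ac[[i]]
    ref <- if (named) state[[ac[[i]]]] else max(state)
    if (state[[sp]] > 1e-6 * max(ref, .Machine$double.eps))
      stop("equilibrated state has activated caspase '", sp,
           "' (amount ", format(state[[sp]], digits = 3),
           "); the pre-stimulus steady state must be caspase-free")
  }
  invisible(TRUE)
}

#' Simulate one cell under a stimulation protocol
#'
#' Integrates the cell's ODEs over the protocol schedule with a stiff solver
#' (lsodar) and locates the death event by root-finding on the death
#' criterion. The located root is then polished by bisection on re-integrated
#' short segments at tightened tolerances, giving death times accurate far
#' beyond the output grid.
#'
#' @param network a `reaction_network` with a death rule (or none, in which
#'   case the cell always survives).
#' @param cell_params a [cell_parameters()] object.
#' @param protocol a [stimulus_protocol()].
#' @param init optional named initial state (model units); default: the
#'   equilibrated steady state (or the declared initial amounts for networks
#'   with `requires_equilibration = FALSE`).
#' @param rtol,atol solver tolerances (defaults 1e-8 / 1e-12).
#' @param n_out output grid points per protocol segment.
#' @param refine_tol absolute tolerance (hours) for polishing the death time;
#'   set `NULL` to keep the solver's root as-is.
#' @return list with elements `trajectory` (class `cell_trajectory`: `time`
#'   in hours, `state` matrix) and `fate` (class `cell_fate`: `status`,
#'   `tod_h`, `censor_horizon`).
#' @export
simulate_cell <- function(network, cell_params = cell_parameters(),
                          protocol = stimulus_protocol(0, "continuous"),
                          init = NULL, rtol = 1e-8, atol = 1e-12,
                          n_out = 201, refine_tol = 1e-9) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(protocol, "stimulus_protocol"))
  rhs <- build_rhs(network, cell_params)
  f <- .desolve_func(rhs, 1 / network$hours_per_time_unit)

  if (is.null(init)) {
    init <- if (network$requires_equilibration)
      equilibrate(network, cell_params, rtol = rtol, atol = atol)
    else .initial_state(network)
  }
  segments <- apply_protocol(network, protocol)
  y <- init
  y[names(segments[[1]]$set)] <- segments[[1]]$set

  g <- .death_root(network, y)
  groot <- if (is.null(g)) NULL else function(t, y, parms) g(y)
  if (!is.null(g) && g(y) >= 0)
    stop("death criterion already met at t = 0")

  times_all <- NULL; states_all <- NULL
  tod <- NA_real_
  for (seg in segments) {
    y[names(seg$set)] <- seg$set
    times <- seq(seg$from, seg$to, length.out = n_out)
    out <- tryCatch(
      if (is.null(groot))
        deSolve::lsoda(y, times, f, parms = NULL, rtol = rtol, atol = atol)
      else
        deSolve::lsodar(y, times, f, parms = NULL, rtol = rtol, atol = atol,
                        rootfunc = groot),
      error = function(e)
        stop("integrator failure (", conditionMessage(e),
             ") for protocol [", protocol$dose, " ng/ml ", protocol$mode,
             "], multipliers: ",
             paste(sprintf("%s=%.6g", names(cell_params$multipliers),
                           cell_params$multipliers), collapse = ", ")))
    times_all <- c(times_all, out[, 1])
    states_all <- rbind(states_all, out[, -1, drop = FALSE])
    troot <- attr(out, "troot")
    if (!is.null(troot) && length(troot)) {
      tod <- troot[1]
      if (!is.null(refine_tol)) {
        anchor <- max(which(out[, 1] < tod))
        tod <- .refine_death_time(f, g, t0 = out[anchor, 1],
                                  y0 = out[anchor, -1],
                                  t_guess = tod, t_max = seg$to,
                                  tol = refine_tol)
      }
      break
    }
    y <- out[nrow(out), -1]
  }

  traj <- structure(list(time = times_all, state = states_all,
                         protocol = protocol,
                         multipliers = cell_params$multipliers),
                    class = "cell_trajectory")
  fate <- structure(list(status = if (is.na(tod)) "survived" else "died",
                         tod_h = tod, censor_horizon = protocol$horizon),
                    class = "cell_fate")
  list(trajectory = traj, fate = fate)
}

# Polish a death time: from the last grid state before the solver's root,
# re-integrate short spans at tight tolerances and bisect the criterion.
.refine_death_time <- function(f, g, t0, y0, t_guess, t_max, tol) {
  solve_to <- function(t) {
    if (t <= t0) return(g(y0))
    out <- deSolve::lsoda(y0, c(t0, t), f, parms = NULL,
                          rtol = 1e-12, atol = 1e-14)
    g(out[nrow(out), -1])
  }
  lo <- t0; g_lo <- g(y0)
  if (g_lo >= 0) return(t0)
  hi <- min(t_guess, t_max); g_hi <- solve_to(hi)
  step <- max(t_guess - t0, tol)
  while (g_hi < 0 && hi < t_max) {
    hi <- min(hi + step, t_max); step <- step * 2
    g_hi <- solve_to(hi)
  }
  if (g_hi < 0) return(t_guess)  # criterion not reached before segment end
  stats::uniroot(solve_to, lower = lo, upper = hi,
                 f.lower = g_lo, f.upper = g_hi,
                 tol = tol)$root
}

#' @export
print.cell_fate <- function(x, ...) {
  if (x$status == "died")
    cat(sprintf("died at %.3f h post stimulus\n", x$tod_h))
  else
    cat(sprintf("survived (censored at %g h)\n", x$censor_horizon))
  invisible(x)
}

#' Simulate a whole cell population
#'
#' Runs [simulate_cell()] for every cell of a sampled population; results are
#' order-aligned with the population and independent of execution order.
#' Individual cell failures are collected; the run aborts only if more than
#' `max_fail_fraction` of cells fail.
#'
#' @param network a `reaction_network`.
#' @param population a `cell_population` from [sample_population()].
#' @param protocol a [stimulus_protocol()].
#' @param store_trajectories keep every trajectory (memory-heavy)?
#' @param max_fail_fraction abort threshold for the fraction of failed cells.
#' @param ... further arguments to [simulate_cell()].
#' @return an object of class `cell_fates`: a data.frame with columns `cell`,
#'   `status`, `tod_h`, plus attributes `multipliers` (matrix), `protocol`,
#'   `failures` and optionally `trajectories`.
#' @export
simulate_population <- function(network, population, protocol,
                                store_trajectories = FALSE,
                                max_fail_fraction = 0.01, ...) {
  stopifnot(inherits(population, "cell_population"))
  n <- length(population)
  status <- character(n); tod <- rep(NA_real_, n)
  failures <- list()
  trajs <- if (store_trajectories) vector("list", n) else NULL
  for (i in seq_len(n)) {
    res <- tryCatch(simulate_cell(network, population[[i]], protocol, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        list(cell = i, message = conditionMessage(res))
      status[i] <- "failed"
      next
    }
    status[i] <- res$fate$status
    tod[i] <- if (res$fate$status == "died") res$fate$tod_h else NA_real_
    if (store_trajectories) trajs[[i]] <- res$trajectory
  }
  if (length(failures) > max_fail_fraction * n)
    stop(length(failures), " of ", n, " cells failed to simulate; first: ",
         failures[[1]]$message)
  out <- data.frame(cell = seq_len(n), status = status, tod_h = tod)
  class(out) <- c("cell_fates", "data.frame")
  attr(out, "multipliers") <- population_matrix(population)
  attr(out, "protocol") <- protocol
  attr(out, "failures") <- failures
  if (store_trajectories) attr(out, "trajectories") <- trajs
  out
}

#' @export
print.cell_fates <- function(x, ...) {
  n <- nrow(x); d <- sum(x$status == "died")
  p <- attr(x, "protocol")
  cat(sprintf("Fates of %d cells (%s ng/ml %s): %d died (%.1f%%), %d survived\n",
              n, format(p$dose), p$mode, d, 100 * d / n,
              sum(x$status == "survived")))
  if (d)
    cat(sprintf("  time of death: min %.2f h, median %.2f h, max %.2f h\n",
                min(x$tod_h, na.rm = TRUE),
                stats::median(x$tod_h, na.rm = TRUE),
                max(x$tod_h, na.rm = TRUE)))
  invisible(x)
}

#' Fraction of the population alive over time
#'
#' @param fates a `cell_fates` object (or data.frame with `status`, `tod_h`).
#' @param grid time points (hours) at which to evaluate viability.
#' @return numeric vector V(t) = fraction of cells with no death event at or
#'   before t; V is non-increasing and V(0) = 1.
#' @export
viability_curve <- function(fates, grid) {
  stopifnot(all(grid >= 0))
  died <- fates$status == "died"
  vapply(grid, function(t) mean(!(died & fates$tod_h <= t)), numeric(1))
}

#' Normalize a trajectory to relative activity
#'
#' Divides a species' time course by its maximum, the convention used to
#' report relative activities: values lie in [0, 1] with the maximum exactly
#' 1. An all-zero course is returned as all zeros with a warning.
#'
#' @param traj a `cell_trajectory` from [simulate_cell()].
#' @param species_id the species to normalize.
#' @return numeric vector of relative activities along `traj$time`.
#' @export
normalize_trajectory <- function(traj, species_id) {
  if (!species_id %in% colnames(traj$state))
    stop("species '", species_id, "' not in trajectory")
  x <- traj$state[, species_id]
  m <- max(x)
  if (m <= 0) {
    warning("time course of '", species_id, "' is identically zero")
    return(x * 0)
  }
  x / m
}

#' Write cell fates to CSV
#'
#' One row per cell: index, every production-rate multiplier, status and time
#' of death in hours.
#'
#' @param fates a `cell_fates` object.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_fates_csv <- function(fates, path) {
  m <- attr(fates, "multipliers")
  d <- cbind(data.frame(cell = fates$cell), as.data.frame(m),
             data.frame(status = fates$status, tod_h = fates$tod_h))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
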