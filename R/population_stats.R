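#' Summarize the fate distribution of a population
#'
#' Death rate over all cells; median, relative spread, quartiles, whiskers
#' (most extreme datum within 1.5 x IQR of the box) and outliers of the time
#' of death over dying cells only. The relative spread is the coefficient of
#' variation (sample sd / mean over dying cells) by default; a median
#' normalizer is available and the choice is stamped into the result.
#'
#' @param fates a `cell_fates` object or data.frame with `status`, `tod_h`.
#' @param rel_std_center `"mean"` (default) or `"median"` normalizer for the
#'   relative standard deviation.
#' @return object of class `population_summary`.
#' @export
summarize_fates <- function(fates, rel_std_center = c("mean", "median")) {
  rel_std_center <- match.arg(rel_std_center)
  stopifnot(nrow(fates) > 0)
  n <- nrow(fates)
  tod <- fates$tod_h[fates$status == "died" & is.finite(fates$tod_h)]
  death_rate <- length(tod) / n
  if (length(tod) == 0) {
    out <- list(n = n, n_dying = 0L, death_rate = 0,
                median_tod = NA_real_, relative_std = NA_real_,
                quartiles = c(NA_real_, NA_real_, NA_real_),
                whiskers = c(NA_real_, NA_real_), outliers = numeric(),
                rel_std_center = rel_std_center)
    return(structure(out, class = "population_summary"))
  }
  q <- stats::quantile(tod, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr; hi_fence <- q[3] + 1.5 * iqr
  inside <- tod[tod >= lo_fence & tod <= hi_fence]
  center <- if (rel_std_center == "mean") mean(tod) else stats::median(tod)
  rel_sd <- if (length(tod) >= 2) stats::sd(tod) / center else NA_real_
  structure(list(
    n = n, n_dying = length(tod), death_rate = death_rate,
    median_tod = q[2], relative_std = rel_sd,
    quartiles = q,
    whiskers = c(min(inside), max(inside)),
    outliers = sort(tod[tod < lo_fence | tod > hi_fence]),
    rel_std_center = rel_std_center),
    class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("Population of %d cells: death rate %.1f%% (%d dying)\n",
              x$n, 100 * x$death_rate, x$n_dying))
  if (x$n_dying > 0)
    cat(sprintf("  ToD median %.2f h [Q1 %.2f, Q3 %.2f], relative std %.3f (sd/%s)\n",
                x$median_tod, x$quartiles[1], x$quartiles[3],
                x$relative_std, x$rel_std_center))
  invisible(x)
}

#' Compare wild-type and knockout population summaries
#'
#' Computes the knockout-minus-wild-type differences of the three fate
#' metrics: death rate as a percentage-point difference, median time of death
#' and relative std as relative percent change (KO - WT) / WT x 100. Both the
#' percentage-point and relative conventions for the death rate are stored so
#' either can be inspected.
#'
#' @param wt,ko `population_summary` objects from aligned runs (same
#'   protocol, dose and sampled population).
#' @return object of class `population_comparison` with elements
#'   `delta_death_rate` (percentage points), `delta_death_rate_relative`
#'   (percent), `delta_median_tod` (percent), `delta_relative_std` (percent).
#' @export
compare_populations <- function(wt, ko) {
  stopifnot(inherits(wt, "population_summary"),
            inherits(ko, "population_summary"))
  rel <- function(a, b) {
    if (is.na(a) || is.na(b) || a == 0) return(NA_real_)
    (b - a) / a * 100
  }
  structure(list(
    delta_death_rate = (ko$death_rate - wt$death_rate) * 100,
    delta_death_rate_relative = rel(wt$death_rate, ko$death_rate),
    delta_median_tod = rel(wt$median_tod, ko$median_tod),
    delta_relative_std = rel(wt$relative_std, ko$relative_std),
    wt = wt, ko = ko),
    class = "population_comparison")
}

#' @export
print.population_comparison <- function(x, ...) {
  cat("Knockout vs wild type (KO - WT):\n")
  cat(sprintf("  death rate:    %+.2f percentage points\n",
              x$delta_death_rate))
  cat(sprintf("  median ToD:    %+.2f%%\n", x$delta_median_tod))
  cat(sprintf("  relative std:  %+.2f%%\n", x$delta_relative_std))
  invisible(x)
}

#' In-silico knockout experiment over a protocol grid
#'
#' For every dose x mode combination, simulates the SAME sampled population
#' (common random numbers) through the wild-type network and through the
#' network with the given reaction knocked out, summarizes both fate
#' distributions, compares them, and records viability curves. Pairing the
#' populations isolates the knockout's effect from sampling noise.
#'
#' @param network wild-type `reaction_network`.
#' @param ko_reaction id of the reaction to knock out (see
#'   [apply_knockout()]).
#' @param doses numeric vector of TNF doses (ng/ml).
#' @param modes character vector of stimulation modes.
#' @param spec an [ensemble_spec()] used once to sample the shared
#'   population.
#' @param horizon censor horizon in hours.
#' @param viability_grid time points (hours) for the viability curves.
#' @param ... further arguments to [simulate_population()].
#' @return data.frame of class `knockout_experiment` with one row per
#'   condition (`dose`, `mode`, WT/KO death rates, medians, relative stds and
#'   the three deltas), with attributes `viability` (list of per-condition
#'   WT/KO curves), `summaries`, and `population`.
#' @export
knockout_experiment <- function(network, ko_reaction, doses,
                                modes = "continuous", spec = ensemble_spec(),
                                horizon = 100,
                                viability_grid = seq(0, horizon, by = 1),
                                ...) {
  ko_net <- apply_knockout(network, ko_reaction)  # validates the id
  population <- sample_population(spec, network)
  rows <- list(); viab <- list(); sums <- list()
  for (mode in modes) for (dose in doses) {
    protocol <- stimulus_protocol(dose, mode, horizon = horizon)
    f_wt <- simulate_population(network, population, protocol, ...)
    f_ko <- simulate_population(ko_net, population, protocol, ...)
    s_wt <- summarize_fates(f_wt); s_ko <- summarize_fates(f_ko)
    cmp <- compare_populations(s_wt, s_ko)
    key <- sprintf("%s_%g", mode, dose)
    rows[[key]] <- data.frame(
      dose = dose, mode = mode,
      death_rate_wt = s_wt$death_rate, death_rate_ko = s_ko$death_rate,
      median_tod_wt = s_wt$median_tod, median_tod_ko = s_ko$median_tod,
      relative_std_wt = s_wt$relative_std,
      relative_std_ko = s_ko$relative_std,
      delta_death_rate = cmp$delta_death_rate,
      delta_median_tod = cmp$delta_median_tod,
      delta_relative_std = cmp$delta_relative_std)
    viab[[key]] <- list(time = viability_grid,
                        wt = viability_curve(f_wt, viability_grid),
                        ko = viability_curve(f_ko, viability_grid))
    sums[[key]] <- list(wt = s_wt, ko = s_ko)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("knockout_experiment", "data.frame"),
            viability = viab, summaries = sums, population = population,
            ko_reaction = ko_reaction)
}

#' @export
print.knockout_experiment <- function(x, digits = 3, ...) {
  cat("In-silico knockout experiment (reaction '",
      attr(x, "ko_reaction"), "'), KO - WT deltas:\n", sep = "")
  print.data.frame(
    data.frame(dose = x$dose, mode = x$mode,
               d_death_rate_pp = round(x$delta_death_rate, digits),
               d_median_tod_pct = round(x$delta_median_tod, digits),
               d_rel_std_pct = round(x$delta_relative_std, digits)),
    row.names = FALSE)
  invisible(x)
}
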