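#' Robust log-log line fit
#'
#' Iteratively reweighted robust regression with bisquare (Tukey) weights,
#' tuning constant 4.685 and median-absolute-deviation residual scale --
#' the standard robust-fit configuration. A perfectly collinear input (zero
#' residuals) is returned exactly with `error_sd = 0`.
#'
#' @param x,y numeric vectors (>= 3 finite points); for sensitivity use these
#'   are log multipliers and log times of death.
#' @param psi `"bisquare"` (default) or `"huber"`.
#' @return list with `slope`, `intercept`, `error_sd` (robust residual scale
#'   estimate), `n`.
#' @export
robust_fit <- function(x, y, psi = c("bisquare", "huber")) {
  psi <- match.arg(psi)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("robust_fit needs at least 3 finite points")
  if (max(x) - min(x) < .Machine$double.eps * max(1, abs(max(x))))
    stop("degenerate predictor: all x values equal")
  ols <- stats::lm.fit(cbind(1, x), y)
  scale0 <- max(abs(y), 1)
  if (max(abs(ols$residuals)) < 1e-10 * scale0) {
    return(list(slope = unname(ols$coefficients[2]),
                intercept = unname(ols$coefficients[1]),
                error_sd = 0, n = length(x)))
  }
  fit <- if (psi == "bisquare")
    MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685,
              scale.est = "MAD", maxit = 200)
  else
    MASS::rlm(y ~ x, psi = MASS::psi.huber, scale.est = "MAD", maxit = 200)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       error_sd = fit$s, n = length(x))
}

#' Population (global) sensitivity of the time of death
#'
#' The global sensitivity measure of the cell-ensemble analysis: for each
#' distributed production rate, the slope of a robust linear fit of
#' log(time of death) against log(multiplier) across the DYING cells of the
#' population. Survivors (censored at the horizon) are excluded from the fit
#' and reported separately; a negative slope means more protein advances
#' death, a positive slope delays it.
#'
#' This is the package's central fitting function; it returns a classed
#' object with `print`, `summary`, `coef` and `plot` methods.
#'
#' @param fates a `cell_fates` object from [simulate_population()], or any
#'   data.frame with `status` and `tod_h` columns.
#' @param multipliers cells x parameters multiplier matrix; defaults to the
#'   matrix attached to `fates`.
#' @param min_dying minimum number of dying cells required (default 3).
#' @param psi robust weight function, see [robust_fit()].
#' @return object of class `tod_sensitivity`: a data.frame with one row per
#'   distributed parameter (`parameter`, `slope`, `error_sd`, `intercept`,
#'   `n_dying`), with attributes `n_total`, `n_survived`, `protocol` and
#'   `survivors_by_decile`.
#' @export
population_sensitivity <- function(fates, multipliers = NULL,
                                   min_dying = 3, psi = "bisquare") {
  if (is.null(multipliers)) multipliers <- attr(fates, "multipliers")
  if (is.null(multipliers))
    stop("no multiplier matrix: supply `multipliers` or use fates from ",
         "simulate_population()")
  stopifnot(nrow(multipliers) == nrow(fates))
  dying <- fates$status == "died" & is.finite(fates$tod_h)
  if (sum(dying) < min_dying)
    stop("insufficient deaths for regression: ", sum(dying), " dying cells")
  log_tod <- log(fates$tod_h[dying])
  ids <- colnames(multipliers)
  rows <- lapply(ids, function(id) {
    f <- robust_fit(log(multipliers[dying, id]), log_tod, psi = psi)
    data.frame(parameter = id, slope = f$slope, error_sd = f$error_sd,
               intercept = f$intercept, n_dying = f$n)
  })
  out <- do.call(rbind, rows)
  # survivor counts per multiplier decile, per parameter: makes the
  # censoring bias of the excluded survivors visible
  surv <- fates$status == "survived"
  decile_counts <- lapply(ids, function(id) {
    br <- stats::quantile(multipliers[, id], probs = seq(0, 1, 0.1))
    br[1] <- -Inf; br[length(br)] <- Inf
    table(cut(multipliers[surv, id], breaks = br, labels = FALSE))
  })
  names(decile_counts) <- ids
  structure(out,
            class = c("tod_sensitivity", "data.frame"),
            n_total = nrow(fates), n_survived = sum(surv),
            protocol = attr(fates, "protocol"),
            survivors_by_decile = decile_counts)
}

#' @export
print.tod_sensitivity <- function(x, digits = 3, ...) {
  p <- attr(x, "protocol")
  cat("Population sensitivity of time of death (robust log-log slopes)\n")
  if (!is.null(p))
    cat(sprintf("  protocol: %s ng/ml %s; ", format(p$dose), p$mode))
  cat(sprintf("%d cells, %d survivors excluded from the fits\n",
              attr(x, "n_total"), attr(x, "n_survived")))
  print.data.frame(data.frame(parameter = x$parameter,
                              slope = round(x$slope, digits),
                              error_sd = round(x$error_sd, digits),
                              n_dying = x$n_dying),
                   row.names = FALSE)
  invisible(x)
}

#' @export
summary.tod_sensitivity <- function(object, negligible_threshold = 0.1, ...) {
  cls <- classify_slopes(object$slope, negligible_threshold)
  out <- data.frame(parameter = object$parameter,
                    slope = object$slope, error_sd = object$error_sd,
                    group = cls)
  cat("Sensitivity groups (|slope| <", negligible_threshold,
      "is negligible):\n")
  print(out, row.names = FALSE)
  invisible(out)
}

#' @export
coef.tod_sensitivity <- function(object, ...) {
  stats::setNames(object$slope, object$parameter)
}

#' @export
plot.tod_sensitivity <- function(x, ...) {
  graphics::dotchart(x$slope, labels = x$parameter,
                     xlab = "d log(time of death) / d log(multiplier)",
                     main = "Population sensitivity of time of death", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Local sensitivity of the nominal cell
#'
#' Perturbs one production rate at a time multiplicatively up and down by
#' `factor` (default 1.1) around the nominal cell and reports the central
#' log-log difference
#' `[log ToD(p x factor) - log ToD(p / factor)] / (2 log factor)`.
#' If the nominal or either perturbed cell survives the horizon the slope is
#' flagged undefined for that parameter rather than silently set to 0.
#'
#' @param network a `reaction_network`.
#' @param protocol a [stimulus_protocol()].
#' @param factor multiplicative perturbation (> 1), default 1.1.
#' @param parameters production-rate ids to perturb; default all.
#' @param refine_tol death-time polishing tolerance in hours (tight by
#'   default: local slopes amplify ToD error by 1 / (2 log factor)).
#' @param ... further arguments to [simulate_cell()].
#' @return data.frame (`parameter`, `slope`, `defined`, `tod_up_h`,
#'   `tod_down_h`), with the nominal time of death as attribute
#'   `tod_nominal_h`.
#' @export
nominal_sensitivity <- function(network, protocol, factor = 1.1,
                                parameters = NULL, refine_tol = 1e-12, ...) {
  stopifnot(factor > 1)
  if (is.null(parameters)) parameters <- network$production_rate_ids
  tod_of <- function(mult) {
    fate <- simulate_cell(network, cell_parameters(mult), protocol,
                          refine_tol = refine_tol, ...)$fate
    if (fate$status == "died") fate$tod_h else NA_real_
  }
  tod_nom <- tod_of(stats::setNames(numeric(0), character(0)))
  rows <- lapply(parameters, function(id) {
    up <- tod_of(stats::setNames(factor, id))
    dn <- tod_of(stats::setNames(1 / factor, id))
    defined <- !is.na(tod_nom) && !is.na(up) && !is.na(dn)
    data.frame(parameter = id,
               slope = if (defined)
                 (log(up) - log(dn)) / (2 * log(factor)) else NA_real_,
               defined = defined, tod_up_h = up, tod_down_h = dn)
  })
  out <- do.call(rbind, rows)
  attr(out, "tod_nominal_h") <- tod_nom
  attr(out, "factor") <- factor
  out
}

#' Classify slopes into the three sensitivity groups
#'
#' @param slope numeric vector of log-log slopes.
#' @param negligible_threshold |slope| below this is `"negligible"`;
#'   otherwise the sign decides `"later_death"` (positive: more protein
#'   delays death) or `"earlier_death"` (negative: more protein advances
#'   death).
#' @return character vector.
#' @export
classify_slopes <- function(slope, negligible_threshold = 0.1) {
  ifelse(!is.finite(slope), NA_character_,
         ifelse(abs(slope) < negligible_threshold, "negligible",
                ifelse(slope > 0, "later_death", "earlier_death")))
}

#' Combine sensitivity records into a comparison table
#'
#' Tidy table of population and nominal-cell slopes per parameter and
#' protocol, with the three-group classification (delaying / advancing /
#' negligible by slope sign and magnitude).
#'
#' @param continuous a `tod_sensitivity` for continuous stimulation.
#' @param pulse optionally, a `tod_sensitivity` for pulse stimulation.
#' @param nominal_continuous,nominal_pulse optional [nominal_sensitivity()]
#'   tables to merge in.
#' @param negligible_threshold classification cutoff on |slope|.
#' @return data.frame with columns `parameter`, `protocol`,
#'   `population_slope`, `error_sd`, `nominal_slope`, `group`.
#' @export
sensitivity_report <- function(continuous, pulse = NULL,
                               nominal_continuous = NULL,
                               nominal_pulse = NULL,
                               negligible_threshold = 0.1) {
  one <- function(pop, nom, label) {
    d <- data.frame(parameter = pop$parameter, protocol = label,
                    population_slope = pop$slope, error_sd = pop$error_sd,
                    nominal_slope = NA_real_)
    if (!is.null(nom))
      d$nominal_slope <- nom$slope[match(d$parameter, nom$parameter)]
    d$group <- classify_slopes(d$population_slope, negligible_threshold)
    d
  }
  out <- one(continuous, nominal_continuous, "continuous")
  if (!is.null(pulse)) {
    if (!setequal(pulse$parameter, continuous$parameter))
      stop("continuous and pulse records cover different parameter sets")
    out <- rbind(out, one(pulse, nominal_pulse, "pulse"))
  }
  out
}
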