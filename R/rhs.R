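#' Per-cell parameter multipliers
#'
#' A `cell_parameters` object holds one cell's multiplicative deviations of
#' the distributed production rates from the nominal model: multiplier 1 in
#' every slot is the nominal (median) cell.
#'
#' @param multipliers named numeric vector, names being production-rate
#'   parameter ids; all values must be > 0. An empty vector is the nominal
#'   cell.
#' @return an object of class `cell_parameters`.
#' @export
cell_parameters <- function(multipliers = numeric()) {
  if (length(multipliers)) {
    stopifnot(!is.null(names(multipliers)), all(nzchar(names(multipliers))))
    if (any(!is.finite(multipliers)) || any(multipliers <= 0))
      stop("all multipliers must be finite and > 0")
  }
  structure(list(multipliers = multipliers), class = "cell_parameters")
}

#' @export
print.cell_parameters <- function(x, ...) {
  if (!length(x$multipliers)) {
    cat("Nominal cell (all multipliers 1)\n")
  } else {
    cat("Cell parameter multipliers:\n")
    print(round(x$multipliers, 4))
  }
  invisible(x)
}

#' Build the ODE right-hand side of a network for one cell
#'
#' Assembles the derivative function dx/dt = S v(x) from the network's
#' stoichiometry and kinetic laws, with each distributed production rate
#' scaled by the cell's multiplier (effective rate = nominal x multiplier).
#' Boundary species (e.g. extracellular ligand held constant) get a zero
#' derivative. Evaluation has no side effects.
#'
#' @param network a `reaction_network`.
#' @param cell_params a [cell_parameters()] object; multiplier names must be a
#'   subset of the network's `production_rate_ids`.
#' @return a function `f(t, state)` returning the derivative vector, of class
#'   `derivative_function`, with attribute `species` giving the state
#'   ordering (the network's species ordering).
#' @export
build_rhs <- function(network, cell_params = cell_parameters()) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(cell_params, "cell_parameters"))
  mult <- cell_params$multipliers
  unknown <- setdiff(names(mult), network$production_rate_ids)
  if (length(unknown))
    stop("multiplier(s) for unknown production-rate parameter(s): ",
         paste(unknown, collapse = ", "))

  sp_ids <- network$species$id
  n_sp <- length(sp_ids)
  n_rx <- length(network$reactions)

  # stoichiometric matrix (species x reactions), boundary rows zeroed
  S <- matrix(0, n_sp, n_rx, dimnames = list(sp_ids, names(network$reactions)))
  for (j in seq_len(n_rx)) {
    r <- network$reactions[[j]]
    if (length(r$reactants))
      S[names(r$reactants), j] <- S[names(r$reactants), j] - r$reactants
    if (length(r$products))
      S[names(r$products), j] <- S[names(r$products), j] + r$products
  }
  S[network$species$boundary, ] <- 0

  pars <- network$parameters
  if (length(mult)) {
    glob <- intersect(names(mult), names(pars))
    pars[glob] <- pars[glob] * mult[glob]
  }
  base_env <- new.env(parent = baseenv())
  for (nm in names(pars)) assign(nm, pars[[nm]], envir = base_env)
  for (i in seq_len(nrow(network$compartments)))
    assign(network$compartments$id[i], network$compartments$size[i],
           envir = base_env)

  # base_env (parameters) <- state_env (species, t) <- per-reaction locals
  state_env <- new.env(parent = base_env)
  rate_exprs <- vector("list", n_rx)
  rate_envs <- vector("list", n_rx)
  for (j in seq_len(n_rx)) {
    r <- network$reactions[[j]]
    locals <- r$local_params
    if (length(locals)) {
      e <- new.env(parent = state_env)
      loc_mult <- intersect(names(mult), names(locals))
      locals[loc_mult] <- locals[loc_mult] * mult[loc_mult]
      for (nm in names(locals)) assign(nm, locals[[nm]], envir = e)
      rate_envs[[j]] <- e
    } else {
      rate_envs[[j]] <- state_env
    }
    rate_exprs[[j]] <- r$rate
  }

  f <- function(t, state) {
    for (i in seq_len(n_sp)) assign(sp_ids[i], state[[i]], envir = state_env)
    assign("t", t, envir = state_env)
    v <- numeric(n_rx)
    for (j in seq_len(n_rx))
      v[j] <- eval(rate_exprs[[j]], rate_envs[[j]])
    drop(S %*% v)
  }
  structure(f, class = c("derivative_function", "function"),
            species = sp_ids)
}
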