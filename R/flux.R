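#' Evaluate one Michaelis-Menten flux law
#'
#' Computes the flux of a single law at the given concentrations: the
#' product of saturation terms `[S] / (Km_S + [S])` over the law's
#' substrates, scaled by its vmax; reversible laws subtract the analogous
#' reverse product. `Km_S` signifies the substrate concentration at which
#' the term reaches one half.
#'
#' @param model a `metabolic_model`.
#' @param law_id id of the flux law (e.g. "PGI", "TPI").
#' @param concentrations named numeric vector of concentrations (mM); must
#'   cover every substrate of the law and be nonnegative.
#' @param params full parameter vector; defaults to the model's fitted set.
#' @return Single numeric flux value (mM/h).
#' @examples
#' m <- aav_model()
#' evaluate_flux(m, "PGI", c(G6P = 1.255))  # 2.283 * 1.255 / (2.165 + 1.255)
#' @export
evaluate_flux <- function(model, law_id, concentrations,
                          params = default_parameters(model)) {
  stopifnot(inherits(model, "metabolic_model"))
  i <- match(law_id, model$eval$law_ids)
  if (is.na(i)) stop("unknown flux law: ", law_id)
  law <- model$flux_laws[[i]]
  side_value <- function(side) {
    subs <- as.character(side$substrates)
    missing <- setdiff(subs, names(concentrations))
    if (length(missing)) {
      stop("flux law '", law_id, "': missing concentration for species '",
           paste(missing, collapse = ", "), "'")
    }
    conc <- concentrations[subs]
    if (any(conc < 0)) {
      stop("flux law '", law_id, "': negative concentration for species '",
           paste(subs[conc < 0], collapse = ", "), "'")
    }
    km <- params[paste0("Km_", subs)]
    if (anyNA(km)) {
      stop("flux law '", law_id, "': parameter set is missing '",
           paste(paste0("Km_", subs)[is.na(km)], collapse = ", "), "'")
    }
    vmax <- params[[paste0("vmax_", side$vmax)]]
    vmax * prod(conc / (km + conc))
  }
  v <- side_value(law$forward)
  if (!is.null(law$reverse)) v <- v - side_value(law$reverse)
  if (!is.finite(v)) stop("flux law '", law_id, "' evaluated to a non-finite value")
  unname(v)
}

#' Evaluate all fluxes of a model
#'
#' @inheritParams evaluate_flux
#' @return Named numeric vector of length `n_laws` (mM/h).
#' @export
evaluate_fluxes <- function(model, concentrations,
                            params = default_parameters(model)) {
  stats::setNames(
    vapply(model$eval$law_ids, evaluate_flux, numeric(1),
           model = model, concentrations = concentrations, params = params),
    model$eval$law_ids
  )
}

#' Assemble species rates from the stoichiometric matrix
#'
#' Net rate of change of every state: `dC/dt = S v(C)`, the stoichiometric
#' matrix times the flux vector. Species untouched by any reaction have
#' rate zero.
#'
#' @inheritParams evaluate_flux
#' @return Named numeric rate vector over species and auxiliary outputs
#'   (mM/h).
#' @export
assemble_rates <- function(model, concentrations,
                           params = default_parameters(model)) {
  v <- evaluate_fluxes(model, concentrations, params)
  drop(model$stoich %*% v)
}

# Resolve the compiled layout against a concrete parameter vector, returning
# numeric vectors ready for the vectorised RHS. Done once per simulation.
resolve_kinetics <- function(model, params) {
  ev <- model$eval
  pick <- function(nm) {
    v <- params[nm]
    if (anyNA(v)) {
      stop("parameter set is missing: ",
           paste(nm[is.na(v)], collapse = ", "))
    }
    unname(v)
  }
  rv_laws <- sort(unique(ev$rv$law))
  list(
    fw_sp = ev$fw$sp, fw_law = ev$fw$law, fw_km = pick(ev$fw$km),
    fw_vmax = pick(ev$fw$vmax),
    rv_sp = ev$rv$sp, rv_law = ev$rv$law, rv_km = pick(ev$rv$km),
    rv_vmax = ifelse(is.na(ev$rv$vmax), 0, params[ev$rv$vmax]),
    rv_laws = rv_laws,
    n_laws = ev$n_laws
  )
}

# Serialise the resolved model layout for the compiled ODE right-hand side
# (see src/rhs.c for the format).
pack_model <- function(model, kin) {
  n_laws <- kin$n_laws
  c(model$eval$n_state, n_laws, length(kin$fw_sp), length(kin$rv_sp),
    as.vector(model$stoich),
    kin$fw_vmax, unname(kin$rv_vmax),
    kin$fw_sp, kin$fw_law, kin$fw_km,
    kin$rv_sp, kin$rv_law, kin$rv_km)
}

# Vectorised flux evaluation: saturation terms for every (law, substrate)
# pair at once, per-law products via rowsum() of logs (exp(-Inf) = 0 handles
# depleted substrates exactly). Concentrations are floored at zero so
# integrator overshoot below zero cannot drive a negative saturation term.
fast_fluxes <- function(kin, state) {
  conc <- pmax(state, 0)
  sat_f <- conc[kin$fw_sp] / (kin$fw_km + conc[kin$fw_sp])
  v <- kin$fw_vmax * exp(rowsum(log(sat_f), kin$fw_law, reorder = TRUE)[, 1L])
  if (length(kin$rv_sp)) {
    sat_r <- conc[kin$rv_sp] / (kin$rv_km + conc[kin$rv_sp])
    prod_r <- exp(rowsum(log(sat_r), kin$rv_law, reorder = TRUE)[, 1L])
    v[kin$rv_laws] <- v[kin$rv_laws] -
      kin$rv_vmax[kin$rv_laws] * prod_r
  }
  v
}
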