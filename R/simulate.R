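#' Simulate the metabolic model
#'
#' Integrates the mass balances `dC/dt = S v(C)` from the initial
#' concentrations carried in the parameter set, using a stiff-capable
#' adaptive solver (lsoda), and returns the state sampled on the requested
#' time grid. Inside the right-hand side, concentrations are floored at
#' zero before the saturation terms are formed, so a depleted substrate
#' shuts its fluxes off instead of going negative.
#'
#' @param model a `metabolic_model`.
#' @param params full named parameter vector (`Km_*`, `vmax_*`, `C0_*`);
#'   defaults to the model's fitted values.
#' @param times output time grid in hours, starting at 0 and strictly
#'   increasing. Default 0 to 120 h every 24 h, the sampling cadence of the
#'   emulated bioreactor culture.
#' @param rtol,atol relative / absolute integration tolerances. Defaults
#'   1e-7 / 1e-9 mM; the cofactor pools span roughly 1e-5 to 20 mM.
#' @param flux_history if TRUE, also record the 32 fluxes at each output
#'   time.
#' @return A `trajectory` object: list with `times`, `states` (times x
#'   states matrix, mM; species then Biomass/Rep/Cap) and optionally
#'   `fluxes`.
#' @examples
#' tr <- simulate_model(aav_model())
#' tr$states[, "Glc"]   # monotone glucose depletion
#' @export
simulate_model <- function(model, params = default_parameters(model),
                           times = seq(0, 120, by = 24),
                           rtol = 1e-7, atol = 1e-9,
                           flux_history = FALSE) {
  stopifnot(inherits(model, "metabolic_model"))
  if (length(times) < 2 || times[1] != 0 || any(diff(times) <= 0)) {
    stop("'times' must start at 0 and be strictly increasing")
  }
  kin <- resolve_kinetics(model, params)
  S <- model$stoich
  y0 <- initial_state(model, params)

  # solver-failure warnings are promoted to errors below, so muffle them here
  sol <- suppressWarnings(
    if (is.loaded("aavmet_rhs", PACKAGE = "aavmet")) {
      .Call("aavmet_set_model", pack_model(model, kin), PACKAGE = "aavmet")
      deSolve::ode(y = y0, times = times, func = "aavmet_rhs",
                   dllname = "aavmet", initfunc = NULL, parms = NULL,
                   method = "lsoda", rtol = rtol, atol = atol,
                   maxsteps = 20000)
    } else {
      rhs <- function(t, y, p) list(drop(S %*% fast_fluxes(kin, y)))
      deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                   method = "lsoda", rtol = rtol, atol = atol,
                   maxsteps = 20000)
    }
  )
  attr_diag <- attributes(sol)
  if (attr_diag$istate[1L] < 0 || nrow(sol) < length(times)) {
    last_t <- if (nrow(sol)) sol[nrow(sol), 1L] else times[1]
    stop("integration failed at t = ", signif(last_t, 6),
         " h (solver status ", attr_diag$istate[1L], ")")
  }
  states <- unclass(sol)[, -1L, drop = FALSE]
  if (any(!is.finite(states))) {
    stop("integration produced non-finite concentrations")
  }
  # report physical (floored) concentrations, matching the flux evaluation
  states[] <- pmax(states, 0)
  traj <- structure(
    list(times = times, states = states),
    observed = model$observed,
    class = "trajectory"
  )
  if (flux_history) {
    traj$fluxes <- t(apply(states, 1L, function(y) fast_fluxes(kin, y)))
    colnames(traj$fluxes) <- model$eval$law_ids
  }
  traj
}

#' Extract the observed metabolite profiles from a trajectory
#'
#' Restricts a trajectory to the five measured species, in the fixed
#' observation order glutamine, glutamic acid, glucose, lactate, ammonium.
#'
#' @param traj a `trajectory`.
#' @param observed observation order; defaults to the order recorded on the
#'   trajectory.
#' @return An `observed_profiles` object: list with `times` (h) and
#'   `values` (times x species matrix, mM).
#' @export
observe <- function(traj, observed = attr(traj, "observed")) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(observed)) stop("no observation order available")
  missing <- setdiff(observed, colnames(traj$states))
  if (length(missing)) {
    stop("trajectory is missing observed species: ",
         paste(missing, collapse = ", "))
  }
  structure(
    list(times = traj$times,
         values = traj$states[, observed, drop = FALSE]),
    class = "observed_profiles"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d time points over %g-%g h, %d states\n",
              length(x$times), min(x$times), max(x$times), ncol(x$states)))
  invisible(x)
}

#' @export
print.observed_profiles <- function(x, ...) {
  cat(sprintf("Observed profiles (%s): %d time points over %g-%g h\n",
              paste(colnames(x$values), collapse = ", "),
              length(x$times), min(x$times), max(x$times)))
  print(cbind(time_h = x$times, x$values))
  invisible(x)
}

#' @export
plot.trajectory <- function(x, species = attr(x, "observed"), ...) {
  species <- species %||% colnames(x$states)
  graphics::matplot(x$times, x$states[, species, drop = FALSE],
                    type = "l", lty = 1, lwd = 2,
                    xlab = "time (h)", ylab = "concentration (mM)", ...)
  graphics::legend("topright", legend = species, lty = 1, lwd = 2,
                   col = seq_along(species), bty = "n")
  invisible(x)
}
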