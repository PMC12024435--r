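#' Read observed metabolite profiles from CSV
#'
#' Expects a `time_h` column and one column per observed species with a
#' unit tag in the header: `_mM` or `_gL` (grams per litre). Columns in
#' g/L are converted to mM at load time using molar masses 180.16 g/mol
#' for glucose and 90.08 g/mol for lactate; all downstream computation is
#' in mM.
#'
#' @param path CSV file path.
#' @param model a `metabolic_model` supplying the observation order.
#' @return An `observed_profiles` object.
#' @export
read_profiles <- function(path, model = aav_model()) {
  df <- utils::read.csv(path, check.names = FALSE)
  as_observed_profiles(df, model)
}

MOLAR_MASS <- c(Glc = 180.16, Lac = 90.08)  # g/mol

#' Coerce to observed profiles
#'
#' Accepts an `observed_profiles`, a `synthetic_dataset` (noisy profiles)
#' or a data frame in the CSV layout of [read_profiles()].
#'
#' @param x object to coerce.
#' @param model a `metabolic_model`.
#' @return An `observed_profiles` object.
#' @export
as_observed_profiles <- function(x, model) {
  if (inherits(x, "observed_profiles")) return(x)
  if (inherits(x, "synthetic_dataset")) return(x$noisy)
  if (!is.data.frame(x)) stop("cannot interpret 'x' as observed profiles")
  if (!"time_h" %in% names(x)) stop("profile data needs a 'time_h' column")
  times <- x$time_h
  vals <- matrix(NA_real_, length(times), length(model$observed),
                 dimnames = list(NULL, model$observed))
  for (sp in model$observed) {
    col_mM <- paste0(sp, "_mM")
    col_gL <- paste0(sp, "_gL")
    if (col_mM %in% names(x)) {
      vals[, sp] <- x[[col_mM]]
    } else if (col_gL %in% names(x)) {
      if (!sp %in% names(MOLAR_MASS)) {
        stop("no molar mass known to convert column '", col_gL, "' to mM")
      }
      vals[, sp] <- x[[col_gL]] * 1000 / MOLAR_MASS[[sp]]
    } else if (sp %in% names(x)) {
      vals[, sp] <- x[[sp]]
    } else {
      stop("profile data is missing a column for species '", sp, "'")
    }
  }
  structure(list(times = times, values = vals), class = "observed_profiles")
}

#' Write observed profiles to CSV
#'
#' @param profiles an `observed_profiles` or `synthetic_dataset`.
#' @param path output CSV path.
#' @param units named character vector mapping species to "mM" or "gL";
#'   species tagged "gL" are converted from mM on write (glucose and
#'   lactate only). Default writes everything in mM.
#' @return The path, invisibly.
#' @export
write_profiles <- function(profiles, path,
                           units = NULL) {
  if (inherits(profiles, "synthetic_dataset")) profiles <- profiles$noisy
  stopifnot(inherits(profiles, "observed_profiles"))
  sp <- colnames(profiles$values)
  if (is.null(units)) units <- stats::setNames(rep("mM", length(sp)), sp)
  df <- data.frame(time_h = profiles$times)
  for (s in sp) {
    u <- if (s %in% names(units)) units[[s]] else "mM"
    if (u == "gL") {
      if (!s %in% names(MOLAR_MASS)) {
        stop("no molar mass known to write species '", s, "' in g/L")
      }
      df[[paste0(s, "_gL")]] <- profiles$values[, s] * MOLAR_MASS[[s]] / 1000
    } else {
      df[[paste0(s, "_mM")]] <- profiles$values[, s]
    }
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a full trajectory to CSV
#'
#' First column `time_h`, then one column per state (species and the
#' auxiliary cumulative outputs), all in mM.
#'
#' @param traj a `trajectory`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  df <- data.frame(time_h = traj$times, traj$states, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV file path.
#' @param observed observation order to attach (optional).
#' @return A `trajectory` object.
#' @export
read_trajectory <- function(path, observed = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  states <- as.matrix(df[, -1L, drop = FALSE])
  structure(list(times = df$time_h, states = states),
            observed = observed, class = "trajectory")
}

#' Write a fitted-parameter report
#'
#' One row per parameter: name, kind, starting value, fitted value and
#' their ratio; free parameters flagged.
#'
#' @param fit a `kinetic_fit`.
#' @param path output CSV path.
#' @return The report data frame, invisibly.
#' @export
write_parameter_report <- function(fit, path) {
  stopifnot(inherits(fit, "kinetic_fit"))
  nm <- names(fit$parameters)
  df <- data.frame(
    name = nm,
    kind = parameter_kind(nm),
    initial = unname(fit$start[nm]),
    fitted = unname(fit$parameters[nm]),
    ratio = unname(fit$parameters[nm] / fit$start[nm]),
    free = nm %in% fit$free
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Export Sobol results to long-format CSV
#'
#' One row per (parameter, output, time) with the first-order index; the
#' aggregate rows carry `output = "aggregate"` and the bootstrap interval.
#'
#' @param result a `sobol_result`.
#' @param path output CSV path.
#' @return The long data frame, invisibly.
#' @export
write_sobol_results <- function(result, path) {
  stopifnot(inherits(result, "sobol_result"))
  agg <- data.frame(
    parameter = result$first_order$parameter,
    output = "aggregate", time_h = NA_real_,
    S = result$first_order$S,
    CI_low = result$first_order$CI_low,
    CI_high = result$first_order$CI_high
  )
  tr <- result$time_resolved
  long <- expand.grid(parameter = dimnames(tr)[[1]],
                      output = dimnames(tr)[[2]],
                      time_h = result$times,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$S <- as.vector(tr)
  long$CI_low <- NA_real_
  long$CI_high <- NA_real_
  out <- rbind(agg, long[, names(agg)])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
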