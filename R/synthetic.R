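#' Measurement-noise model for synthetic datasets
#'
#' Heteroscedastic Gaussian measurement error: the standard deviation at a
#' value y is `max(relative_sd * y, absolute_sd_floor)`, mimicking typical
#' bioanalyzer behaviour where error scales with signal but never drops
#' below the assay floor.
#'
#' @param relative_sd relative standard deviation (fraction, default 0.05).
#' @param absolute_sd_floor absolute floor in mM (default 0.02).
#' @return A `noise_model` list.
#' @export
noise_model <- function(relative_sd = 0.05, absolute_sd_floor = 0.02) {
  if (relative_sd < 0 || absolute_sd_floor < 0) {
    stop("noise magnitudes must be nonnegative")
  }
  structure(list(relative_sd = relative_sd,
                 absolute_sd_floor = absolute_sd_floor),
            class = "noise_model")
}

#' Generate a pseudo-experimental bioreactor dataset
#'
#' Emulates the study design the fitting stage expects: the five measured
#' metabolites (glutamine, glutamic acid, glucose, lactate, ammonium)
#' sampled every 24 h over a multi-day low-cell-density culture. Clean
#' profiles come from simulating the model under `truth`; noisy profiles
#' add seeded heteroscedastic Gaussian noise truncated at zero
#' (concentrations are nonnegative measurements).
#'
#' If, under the supplied truth parameters, glucose or glutamine is not
#' non-increasing, or lactate or ammonium not non-decreasing, a shape
#' warning is emitted — the expected depletion/accumulation pattern is an
#' empirical property of the parameter set, checked rather than assumed.
#'
#' @param model a `metabolic_model`.
#' @param truth full parameter vector used as ground truth.
#' @param times sampling grid (h), default 0 to 120 h every 24 h.
#' @param noise a [noise_model()].
#' @param seed integer seed; the dataset is reproducible.
#' @return A `synthetic_dataset`: list with `truth`, `clean`, `noisy`
#'   (both `observed_profiles`), `noise`, `seed`.
#' @examples
#' ds <- generate_dataset(aav_model(), seed = 42)
#' ds$noisy$values - ds$clean$values
#' @export
generate_dataset <- function(model, truth = default_parameters(model),
                             times = seq(0, 120, by = 24),
                             noise = noise_model(), seed = 1L) {
  stopifnot(inherits(model, "metabolic_model"))
  clean <- observe(simulate_model(model, truth, times = times))
  v <- clean$values
  mono_ok <- function(x, dir) all(dir * diff(x) >= -1e-9)
  checks <- c(Glc = mono_ok(v[, "Glc"], -1), Gln = mono_ok(v[, "Gln"], -1),
              Lac = mono_ok(v[, "Lac"], 1), NH4 = mono_ok(v[, "NH4"], 1))
  if (!all(checks)) {
    warning("generated profiles deviate from the expected depletion/",
            "accumulation shape for: ",
            paste(names(checks)[!checks], collapse = ", "))
  }
  noisy <- apply_noise(clean, noise, seed)
  structure(
    list(truth = truth, clean = clean, noisy = noisy,
         noise = noise, seed = seed, model_name = model$name),
    class = "synthetic_dataset"
  )
}

#' Add measurement noise to clean profiles
#'
#' Seeded heteroscedastic Gaussian noise per [noise_model()], truncated at
#' zero.
#'
#' @param clean an `observed_profiles` object.
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @return A noisy `observed_profiles` object.
#' @export
apply_noise <- function(clean, noise, seed = 1L) {
  stopifnot(inherits(clean, "observed_profiles"))
  v <- clean$values
  set.seed(seed)
  sd <- pmax(noise$relative_sd * v, noise$absolute_sd_floor)
  noisy_vals <- pmax(v + stats::rnorm(length(v), sd = sd), 0)
  structure(list(times = clean$times, values = noisy_vals),
            class = "observed_profiles")
}

#' Perturb a subset of parameters by random multipliers
#'
#' Multiplies each selected parameter by a seeded uniform factor drawn from
#' `range`; all other parameters are untouched. Used to set up
#' parameter-recovery experiments.
#'
#' @param params full named parameter vector.
#' @param subset names of the parameters to perturb (nonempty).
#' @param range `c(lower, upper)` multiplier range, positive; a degenerate
#'   range `c(m, m)` applies the fixed factor m.
#' @param seed integer seed.
#' @return The perturbed parameter vector.
#' @export
perturb_parameters <- function(params, subset, range = c(0.7, 1.3),
                               seed = 1L) {
  if (!length(subset)) stop("'subset' must be nonempty")
  missing <- setdiff(subset, names(params))
  if (length(missing)) {
    stop("unknown parameter: ", paste(missing, collapse = ", "))
  }
  if (any(range <= 0)) stop("multiplier range must be positive")
  set.seed(seed)
  fac <- stats::runif(length(subset), range[1], range[2])
  params[subset] <- params[subset] * fac
  params
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic bioreactor dataset (seed %d, rel sd %.3g, floor %.3g mM)\n",
    x$seed, x$noise$relative_sd, x$noise$absolute_sd_floor))
  print(x$noisy)
  invisible(x)
}
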