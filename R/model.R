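#' Load a kinetic-metabolic model definition
#'
#' Reads a YAML model definition (species, shared Km/vmax parameter registry,
#' Michaelis-Menten flux laws, reaction stoichiometries) and returns a
#' validated `metabolic_model` object. The definition shipped with the
#' package, `aav_hek293.yaml`, encodes the HEK293/rAAV production network:
#' 53 metabolite mass balances, 32 flux laws, 52 Km and 37 vmax parameters,
#' plus three cumulative auxiliary outputs (Biomass, Rep, Cap).
#'
#' Units throughout are mM for concentrations, hours for time and mM/h for
#' fluxes.
#'
#' @param path path to a YAML model definition file.
#' @return An object of class `metabolic_model`: a list with elements
#'   `species` (data frame: id, name, c0, observed, fixed_initial),
#'   `auxiliary` (character), `km`, `vmax` (named numeric registries),
#'   `flux_laws` (list), `reactions` (list), `observed` (observation order),
#'   `stoich` (state x flux stoichiometric matrix) and a precompiled
#'   evaluation layout used by the simulator.
#' @seealso [aav_model()] for the shipped model, [simulate_model()],
#'   [count_parameters()], [default_parameters()].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    stop("model definition file not found: ", path)
  }
  def <- yaml::read_yaml(path)
  build_model(def, source = path)
}

#' The shipped HEK293/rAAV production model
#'
#' Convenience loader for the packaged model definition (53 species, 32
#' Michaelis-Menten flux laws, 89 kinetic parameters).
#'
#' @return A `metabolic_model` object.
#' @examples
#' m <- aav_model()
#' count_parameters(m)
#' @export
aav_model <- function() {
  path <- system.file("extdata", "aav_hek293.yaml", package = "aavmet")
  load_model(path)
}

# Construct and validate a metabolic_model from a parsed definition list.
build_model <- function(def, source = "<in-memory>") {
  for (section in c("species", "parameters", "flux_laws", "reactions")) {
    if (is.null(def[[section]])) {
      stop("model definition is missing the '", section, "' section")
    }
  }

  sp <- do.call(rbind, lapply(def$species, function(s) {
    data.frame(
      id = as.character(s$id),
      name = if (is.null(s$name)) as.character(s$id) else as.character(s$name),
      c0 = as.numeric(s$c0),
      observed = isTRUE(s$observed),
      fixed_initial = isTRUE(s$fixed_initial),
      stringsAsFactors = FALSE
    )
  }))
  if (anyDuplicated(sp$id)) {
    stop("duplicate species id: ",
         paste(unique(sp$id[duplicated(sp$id)]), collapse = ", "))
  }
  if (any(!is.finite(sp$c0)) || any(sp$c0 < 0)) {
    stop("initial concentration of species '",
         paste(sp$id[!is.finite(sp$c0) | sp$c0 < 0], collapse = ", "),
         "' must be a nonnegative number")
  }

  aux <- as.character(def$auxiliary %||% character())
  if (any(aux %in% sp$id)) {
    stop("auxiliary output name clashes with a species id: ",
         paste(intersect(aux, sp$id), collapse = ", "))
  }

  km <- unlist(def$parameters$km)
  vmax <- unlist(def$parameters$vmax)
  check_registry <- function(x, what) {
    if (is.null(names(x)) || anyDuplicated(names(x))) {
      stop("duplicate or unnamed ", what, " parameter entries")
    }
    bad <- !is.finite(x) | x < 0
    if (any(bad)) {
      stop(what, " parameter '", paste(names(x)[bad], collapse = ", "),
           "' must be a nonnegative number")
    }
  }
  check_registry(km, "Km")
  check_registry(vmax, "vmax")
  unknown_km <- setdiff(names(km), sp$id)
  if (length(unknown_km)) {
    stop("Km registry references unknown species: ",
         paste(unknown_km, collapse = ", "))
  }

  laws <- def$flux_laws
  law_ids <- vapply(laws, function(l) as.character(l$id), character(1))
  if (anyDuplicated(law_ids)) {
    stop("duplicate flux law id: ",
         paste(unique(law_ids[duplicated(law_ids)]), collapse = ", "))
  }
  check_side <- function(side, law_id) {
    if (is.null(side$vmax) || !side$vmax %in% names(vmax)) {
      stop("flux law '", law_id, "' references unknown vmax parameter '",
           side$vmax %||% "<missing>", "'")
    }
    subs <- as.character(side$substrates)
    if (!length(subs)) stop("flux law '", law_id, "' has no substrate terms")
    bad <- setdiff(subs, sp$id)
    if (length(bad)) {
      stop("flux law '", law_id, "' references unknown species '",
           paste(bad, collapse = ", "), "'")
    }
    miss <- setdiff(subs, names(km))
    if (length(miss)) {
      stop("flux law '", law_id, "' has no Km registry entry for '",
           paste(miss, collapse = ", "), "'")
    }
    subs
  }
  for (l in laws) {
    check_side(l$forward, l$id)
    if (!is.null(l$reverse)) check_side(l$reverse, l$id)
  }

  state_names <- c(sp$id, aux)
  n_state <- length(state_names)
  rx <- def$reactions
  rx_flux <- vapply(rx, function(r) as.character(r$flux), character(1))
  if (anyDuplicated(rx_flux)) {
    stop("flux law referenced by more than one reaction: ",
         paste(unique(rx_flux[duplicated(rx_flux)]), collapse = ", "))
  }
  if (!setequal(rx_flux, law_ids)) {
    orphans <- setdiff(law_ids, rx_flux)
    dangling <- setdiff(rx_flux, law_ids)
    stop("reactions and flux laws do not match one-to-one",
         if (length(orphans)) paste0("; laws without a reaction: ",
                                     paste(orphans, collapse = ", ")),
         if (length(dangling)) paste0("; reactions with unknown flux law: ",
                                      paste(dangling, collapse = ", ")))
  }

  S <- matrix(0, nrow = n_state, ncol = length(laws),
              dimnames = list(state_names, law_ids))
  for (r in rx) {
    st <- unlist(r$stoichiometry)
    bad <- setdiff(names(st), state_names)
    if (length(bad)) {
      stop("reaction for flux '", r$flux,
           "' references unknown species '", paste(bad, collapse = ", "), "'")
    }
    if (any(!is.finite(st)) || any(st == 0)) {
      stop("reaction for flux '", r$flux,
           "' has a zero or non-finite stoichiometric coefficient")
    }
    S[names(st), r$flux] <- st
  }

  observed <- as.character(def$observed %||% sp$id[sp$observed])
  if (!setequal(observed, sp$id[sp$observed])) {
    stop("'observed' order must list exactly the species flagged observed")
  }

  model <- structure(
    list(
      name = def$model$name %||% "metabolic_model",
      species = sp,
      auxiliary = aux,
      km = km,
      vmax = vmax,
      flux_laws = laws,
      reactions = rx,
      observed = observed,
      state_names = state_names,
      stoich = S,
      source = source
    ),
    class = "metabolic_model"
  )
  model$eval <- compile_eval(model)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Flatten the flux laws into an index layout so the ODE right-hand side is a
# handful of vectorised operations: one saturation-term vector for the
# forward sides of all laws, one for the reverse sides, and per-term state /
# Km-name indices. rowsum() over the law index rebuilds the per-law products.
compile_eval <- function(model) {
  law_ids <- vapply(model$flux_laws, `[[`, character(1), "id")
  n_laws <- length(law_ids)
  side_layout <- function(get_side) {
    sp_idx <- integer(); law_idx <- integer(); km_name <- character()
    vmax_name <- rep(NA_character_, n_laws)
    for (i in seq_len(n_laws)) {
      side <- get_side(model$flux_laws[[i]])
      if (is.null(side)) next
      subs <- as.character(side$substrates)
      sp_idx <- c(sp_idx, match(subs, model$state_names))
      law_idx <- c(law_idx, rep.int(i, length(subs)))
      km_name <- c(km_name, paste0("Km_", subs))
      vmax_name[i] <- paste0("vmax_", side$vmax)
    }
    list(sp = sp_idx, law = law_idx, km = km_name, vmax = vmax_name)
  }
  fw <- side_layout(function(l) l$forward)
  rv <- side_layout(function(l) l$reverse)
  list(law_ids = law_ids, n_laws = n_laws, fw = fw, rv = rv,
       n_species = nrow(model$species),
       n_state = length(model$state_names))
}

#' Default (fitted) parameter set of a model
#'
#' Returns the full named parameter vector carried by the model definition:
#' `Km_<metabolite>` half-saturation constants (mM), `vmax_<flux>` maximum
#' fluxes (mM/h) and `C0_<species>` initial concentrations (mM). For the
#' shipped model these are the fitted values, 142 parameters in all.
#'
#' @param model a `metabolic_model`.
#' @return Named numeric vector of length `n_Km + n_vmax + n_species`.
#' @export
default_parameters <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  c(
    stats::setNames(model$km, paste0("Km_", names(model$km))),
    stats::setNames(model$vmax, paste0("vmax_", names(model$vmax))),
    stats::setNames(model$species$c0, paste0("C0_", model$species$id))
  )
}

#' Parameter kind lookup
#'
#' @param names parameter names (`Km_*`, `vmax_*`, `C0_*`).
#' @return Character vector of kinds: "Km", "vmax" or "initial_concentration".
#' @export
parameter_kind <- function(names) {
  kind <- rep(NA_character_, length(names))
  kind[startsWith(names, "Km_")] <- "Km"
  kind[startsWith(names, "vmax_")] <- "vmax"
  kind[startsWith(names, "C0_")] <- "initial_concentration"
  if (anyNA(kind)) {
    stop("unrecognised parameter name: ",
         paste(names[is.na(kind)], collapse = ", "))
  }
  kind
}

#' Count the parameters of a model
#'
#' @param model a `metabolic_model`.
#' @return List with `n_Km`, `n_vmax`, `n_kinetic` (= n_Km + n_vmax),
#'   `n_initial` (one per mass-balance species) and `n_total`.
#' @examples
#' count_parameters(aav_model())  # 52 / 37 / 89 / 53 / 142
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  n_km <- length(model$km)
  n_vmax <- length(model$vmax)
  n_init <- nrow(model$species)
  list(n_Km = n_km, n_vmax = n_vmax, n_kinetic = n_km + n_vmax,
       n_initial = n_init, n_total = n_km + n_vmax + n_init)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cnt <- count_parameters(x)
  n_rev <- sum(vapply(x$flux_laws, function(l) !is.null(l$reverse), logical(1)))
  cat("Kinetic-metabolic model:", x$name, "\n")
  cat(sprintf("  %d species (%d observed: %s) + %d auxiliary outputs\n",
              nrow(x$species), sum(x$species$observed),
              paste(x$observed, collapse = ", "), length(x$auxiliary)))
  cat(sprintf("  %d Michaelis-Menten flux laws (%d reversible)\n",
              length(x$flux_laws), n_rev))
  cat(sprintf("  %d kinetic parameters (Km = %d, vmax = %d); %d total with C0\n",
              cnt$n_kinetic, cnt$n_Km, cnt$n_vmax, cnt$n_total))
  invisible(x)
}

#' Initial state vector of a model under a parameter set
#'
#' Mass-balance species start at their `C0_*` parameter values; the
#' auxiliary cumulative outputs start at zero.
#'
#' @param model a `metabolic_model`.
#' @param params full named parameter vector (see [default_parameters()]).
#' @return Named numeric state vector (species then auxiliaries).
#' @export
initial_state <- function(model, params = default_parameters(model)) {
  c0 <- params[paste0("C0_", model$species$id)]
  if (anyNA(c0)) {
    stop("parameter set is missing initial concentrations for: ",
         paste(model$species$id[is.na(c0)], collapse = ", "))
  }
  stats::setNames(c(unname(c0), rep(0, length(model$auxiliary))),
                  model$state_names)
}
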