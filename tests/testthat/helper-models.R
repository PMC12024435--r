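# Fixture builders: all models are constructed in code from definition lists.

# single irreversible MM reaction A -> B
toy_ab_def <- function(vmax = 1, km = 0.5, a0 = 10, b0 = 0) {
  list(
    model = list(name = "toy_ab"),
    observed = list("A", "B"),
    species = list(
      list(id = "A", c0 = a0, observed = TRUE),
      list(id = "B", c0 = b0, observed = TRUE)
    ),
    auxiliary = list(),
    parameters = list(km = list(A = km), vmax = list(AB = vmax)),
    flux_laws = list(
      list(id = "AB", forward = list(vmax = "AB", substrates = list("A")))
    ),
    reactions = list(
      list(flux = "AB", stoichiometry = list(A = -1, B = 1))
    )
  )
}

toy_ab_model <- function(...) aavmet:::build_model(toy_ab_def(...))

# random sparse irreversible network for oracle-equivalence checks
random_model <- function(n_species = 5, n_laws = 4, seed = 1) {
  set.seed(seed)
  ids <- paste0("S", seq_len(n_species))
  species <- lapply(ids, function(s) list(id = s, c0 = runif(1, 0.1, 5)))
  km <- as.list(stats::setNames(runif(n_species, 0.05, 2), ids))
  vm <- as.list(stats::setNames(runif(n_laws, 0.1, 3), paste0("L", seq_len(n_laws))))
  laws <- list(); rxs <- list()
  for (l in seq_len(n_laws)) {
    subs <- sample(ids, sample(1:2, 1))
    prods <- sample(setdiff(ids, subs), 1)
    laws[[l]] <- list(id = paste0("L", l),
                      forward = list(vmax = paste0("L", l),
                                     substrates = as.list(subs)))
    st <- c(stats::setNames(as.list(rep(-1, length(subs))), subs),
            stats::setNames(list(round(runif(1, 0.5, 2), 2)), prods))
    rxs[[l]] <- list(flux = paste0("L", l), stoichiometry = st)
  }
  aavmet:::build_model(list(
    model = list(name = paste0("random", seed)),
    observed = list(),
    species = species, auxiliary = list(),
    parameters = list(km = km, vmax = vm),
    flux_laws = laws, reactions = rxs
  ))
}

# implicit closed-form solution of a single MM decay:
#   Km * ln(A0/A) + (A0 - A) = vmax * t
mm_time_of <- function(A, A0, vmax, km) (km * log(A0 / A) + (A0 - A)) / vmax

# the canonical parameter-recovery quartet: strong, mutually low-correlated
# effects on the observed metabolites (glucose uptake, glutaminolysis,
# pyruvate carboxylation, pyruvate oxidation)
recovery_quartet <- c("vmax_HK", "vmax_GLNS", "vmax_PC", "vmax_PDH")
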