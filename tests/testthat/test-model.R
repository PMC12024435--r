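test_that("shipped model reproduces the published network structure", {
  m <- aav_model()
  cnt <- count_parameters(m)
  expect_equal(length(m$flux_laws), 32L)
  expect_equal(cnt$n_Km, 52L)
  expect_equal(cnt$n_vmax, 37L)
  expect_equal(cnt$n_kinetic, 89L)
  expect_equal(nrow(m$species), 53L)
  expect_equal(cnt$n_initial, 53L)
  expect_equal(cnt$n_total, 142L)
  # exactly five measured species, in the fixed observation order
  expect_equal(m$observed, c("Gln", "GluAc", "Glc", "Lac", "NH4"))
  expect_equal(sum(m$species$observed), 5L)
  expect_equal(sum(m$species$fixed_initial), 5L)
  # five laws carry a subtracted reverse product
  rev_ids <- vapply(m$flux_laws, function(l) {
    if (is.null(l$reverse)) NA_character_ else l$id
  }, character(1))
  expect_setequal(rev_ids[!is.na(rev_ids)],
                  c("TPI", "PGK", "SD", "FH", "LDH"))
  # stoichiometric matrix spans species + auxiliary outputs x fluxes
  expect_equal(dim(m$stoich), c(53L + 3L, 32L))
  expect_true(all(c("Biomass", "Rep", "Cap") %in% rownames(m$stoich)))
})

test_that("model validation rejects malformed definitions", {
  def <- toy_ab_def()

  bad <- def
  bad$flux_laws[[1]]$forward$substrates <- list("FOO")
  expect_error(aavmet:::build_model(bad), "FOO")

  bad <- def
  bad$species[[2]]$id <- "A"
  expect_error(aavmet:::build_model(bad), "duplicate")

  bad <- def
  bad$species[[1]]$c0 <- -1
  expect_error(aavmet:::build_model(bad), "nonnegative")

  bad <- def
  bad$parameters$km$A <- -0.5
  expect_error(aavmet:::build_model(bad), "nonnegative")

  bad <- def
  bad$reactions[[1]]$flux <- "NOPE"
  expect_error(aavmet:::build_model(bad), "NOPE")

  bad <- def
  bad$reactions <- c(bad$reactions, bad$reactions)
  expect_error(aavmet:::build_model(bad), "more than one reaction")
})

test_that("single-fraction flux arithmetic matches direct computation", {
  m <- aav_model()
  # frozen oracle: vmax * G6P / (Km + G6P) with the shipped values
  expect_equal(evaluate_flux(m, "PGI", c(G6P = 1.255)),
               2.283 * 1.255 / (2.165 + 1.255), tolerance = 1e-12)
  # half-saturation identity: [S] = Km gives vmax / 2
  expect_equal(evaluate_flux(m, "PGI", c(G6P = 2.165)), 2.283 / 2,
               tolerance = 1e-12)
  # zero substrate shuts the flux off
  expect_equal(evaluate_flux(m, "HK", c(Glc = 0, ATP = 5)), 0)
  # balanced forward and reverse sides cancel
  p <- default_parameters(m)
  p["vmax_f_TPI"] <- 1
  p["vmax_r_TPI"] <- 1
  p["Km_DHAP"] <- 0.1
  p["Km_GAP"] <- 0.1
  expect_equal(evaluate_flux(m, "TPI", c(DHAP = 2, GAP = 2), p), 0)
})

test_that("flux evaluation validates its concentration input", {
  m <- aav_model()
  expect_error(evaluate_flux(m, "HK", c(Glc = 1)), "ATP")
  expect_error(evaluate_flux(m, "HK", c(Glc = -1, ATP = 1)), "negative")
  expect_error(evaluate_flux(m, "NOSUCH", c(Glc = 1)), "unknown flux law")
})

test_that("irreversible fluxes are bounded by vmax and monotone in substrates", {
  m <- aav_model()
  p <- default_parameters(m)
  irrev <- vapply(m$flux_laws, function(l) is.null(l$reverse), logical(1))
  set.seed(7)
  for (rep in 1:5) {
    conc <- setNames(runif(nrow(m$species), 0, 20), m$species$id)
    v <- evaluate_fluxes(m, conc, p)
    vmax_of <- vapply(m$flux_laws, function(l) p[[paste0("vmax_", l$forward$vmax)]],
                      numeric(1))
    expect_true(all(v[irrev] >= 0))
    expect_true(all(v[irrev] <= vmax_of[irrev] + 1e-12))
  }
  # monotone in each substrate, all else fixed
  conc <- setNames(rep(1, nrow(m$species)), m$species$id)
  for (law in c("HK", "PDH", "NS")) {
    i <- match(law, vapply(m$flux_laws, `[[`, character(1), "id"))
    for (s in as.character(m$flux_laws[[i]]$forward$substrates)) {
      lo <- conc; hi <- conc; hi[s] <- 2
      expect_lt(evaluate_flux(m, law, lo, p), evaluate_flux(m, law, hi, p))
    }
  }
})

test_that("stoichiometric assembly equals brute-force per-reaction accumulation", {
  for (seed in 1:4) {
    mod <- random_model(n_species = 6, n_laws = 5, seed = seed)
    p <- default_parameters(mod)
    conc <- setNames(runif(6, 0.1, 4), mod$species$id)
    fast <- assemble_rates(mod, conc, p)
    # oracle: accumulate each reaction's contribution one by one
    slow <- setNames(numeric(length(mod$state_names)), mod$state_names)
    for (r in mod$reactions) {
      v <- evaluate_flux(mod, r$flux, conc, p)
      st <- unlist(r$stoichiometry)
      slow[names(st)] <- slow[names(st)] + st * v
    }
    expect_equal(fast, slow, tolerance = 1e-12)
  }
})

test_that("species untouched by reactions and zeroed vmax give zero rates", {
  m <- aav_model()
  p <- default_parameters(m)
  p[startsWith(names(p), "vmax_")] <- 0
  conc <- setNames(rep(1, nrow(m$species)), m$species$id)
  expect_true(all(assemble_rates(m, conc, p) == 0))
  # glucose is only ever consumed
  p2 <- default_parameters(m)
  for (seed in 1:3) {
    set.seed(seed)
    conc <- setNames(runif(nrow(m$species), 0, 10), m$species$id)
    expect_lte(assemble_rates(m, conc, p2)[["Glc"]], 0)
  }
})

test_that("a shared Km touches exactly the laws containing that saturation term", {
  m <- aav_model()
  conc <- setNames(rep(1, nrow(m$species)), m$species$id)
  p1 <- default_parameters(m)
  p2 <- p1
  p2["Km_ATP"] <- p2["Km_ATP"] * 2
  v1 <- evaluate_fluxes(m, conc, p1)
  v2 <- evaluate_fluxes(m, conc, p2)
  changed <- names(v1)[v1 != v2]
  expect_setequal(changed,
                  c("HK", "PFK", "PGK", "PC", "Glu", "Growth", "Rep", "Cep"))
})

test_that("parameter bookkeeping is consistent", {
  m <- aav_model()
  p <- default_parameters(m)
  expect_equal(length(p), 142L)
  expect_false(anyDuplicated(names(p)) > 0)
  kinds <- parameter_kind(names(p))
  expect_equal(sum(kinds == "Km"), 52L)
  expect_equal(sum(kinds == "vmax"), 37L)
  expect_equal(sum(kinds == "initial_concentration"), 53L)
  expect_error(parameter_kind("banana"), "unrecognised")
  # shipped initial state matches the fitted concentrations, auxiliaries zero
  y0 <- initial_state(m)
  expect_equal(unname(y0[c("Gln", "GluAc", "Glc", "Lac", "NH4")]),
               c(4.7, 3.59, 28.23, 13.91, 0.97))
  expect_equal(unname(y0[c("Biomass", "Rep", "Cap")]), c(0, 0, 0))
})
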