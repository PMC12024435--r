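test_that("residuals vanish at the generating parameters and count 5 x T", {
  m <- aav_model()
  truth <- default_parameters(m)
  ds <- generate_dataset(m, truth, noise = noise_model(0, 0), seed = 1)
  r <- fit_residuals(m, ds, truth)
  expect_length(r, 5L * 6L)
  expect_equal(max(abs(r)), 0)
  # perturbing one measured value moves exactly one residual by that amount
  data2 <- ds$noisy
  data2$values[3, "Glc"] <- data2$values[3, "Glc"] + 1
  r2 <- fit_residuals(m, data2, truth)
  expect_equal(sum(r2 != r), 1L)
  expect_equal(sum(r2 - r), 1)
})

test_that("lm_step solves a linear problem in a few accepted steps", {
  fn <- function(p) p - 3
  p <- 0
  lambda <- 1e-3
  for (i in 1:3) {
    st <- lm_step(fn, p, lambda)
    expect_true(st$accepted)
    p <- st$p
    lambda <- st$lambda
  }
  expect_equal(p, 3, tolerance = 1e-6)
  # at the minimum the proposed shift is negligible: rejected as converged
  st <- lm_step(fn, 3)
  expect_false(st$accepted)
  expect_true(st$converged)
})

test_that("lm_step stalls cleanly when no downhill shift exists", {
  # residual grows in every direction but gradient is nonzero and misleading:
  # a function whose trial evaluations always fail
  fn_ok_once <- local({
    calls <- 0
    function(p) {
      calls <<- calls + 1
      if (calls > 2) stop("unstable")  # fails for every trial step
      c(p - 3, 1)
    }
  })
  expect_error(lm_step(fn_ok_once, 0, lambda = 1e9),
               class = "aavmet_stalled")
})

test_that("two-parameter MM fit recovers generating values, matching a grid search", {
  s_grid <- c(0.2, 0.5, 1, 2, 4, 8, 16)
  vmax_true <- 2.7; km_true <- 1.9
  y <- vmax_true * s_grid / (km_true + s_grid)
  resid_log <- function(q) y - exp(q[1]) * s_grid / (exp(q[2]) + s_grid)

  opt <- aavmet:::lm_optimize(resid_log, log(c(1, 1)), max_iter = 100)
  est <- exp(opt$p)
  expect_equal(est, c(vmax_true, km_true), tolerance = 1e-4,
               ignore_attr = TRUE)

  # independent oracle: dense grid search over (vmax, Km)
  vg <- seq(1, 5, length.out = 161)
  kg <- seq(0.5, 4, length.out = 141)
  ssq_grid <- outer(vg, kg, function(v, k) {
    vapply(seq_along(v), function(i) {
      sum((y - v[i] * s_grid / (k[i] + s_grid))^2)
    }, numeric(1))
  })
  best <- arrayInd(which.min(ssq_grid), dim(ssq_grid))
  expect_equal(est[1], vg[best[1]], tolerance = diff(vg[1:2]) / vg[best[1]] + 1e-9)
  expect_equal(est[2], kg[best[2]], tolerance = diff(kg[1:2]) / kg[best[2]] + 1e-9)
  expect_lte(opt$ssq, min(ssq_grid))

  # cross-check against an independent LM implementation
  if (requireNamespace("minpack.lm", quietly = TRUE)) {
    nls_fit <- minpack.lm::nls.lm(par = log(c(1, 1)), fn = resid_log)
    expect_equal(est, exp(nls_fit$par), tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("fitting at the optimum converges immediately with no accepted steps", {
  m <- aav_model()
  truth <- default_parameters(m)
  ds <- generate_dataset(m, truth, noise = noise_model(0, 0), seed = 1)
  fit <- fit_kinetics(m, ds, free = c("vmax_HK", "vmax_GLNS"),
                      start = truth, block_size = 2)
  expect_true(fit$converged)
  expect_equal(fit$n_cycles, 1L)
  expect_equal(fit$n_iterations, 0L)
  expect_lt(fit$ssq_total, 1e-12)
})

test_that("blockwise fit recovers perturbed parameters from noiseless data", {
  m <- aav_model()
  truth <- default_parameters(m)
  ds <- generate_dataset(m, truth, noise = noise_model(0, 0), seed = 1)
  start <- truth
  start[recovery_quartet] <- start[recovery_quartet] * 1.3
  fit <- fit_kinetics(m, ds, free = recovery_quartet, start = start,
                      block_size = 2)
  rel <- abs(coef(fit, "free")[recovery_quartet] / truth[recovery_quartet] - 1)
  expect_lt(max(rel), 0.05)
  # accepted-step monotonicity and improvement over the start
  expect_true(all(diff(fit$history) <= 1e-12))
  expect_lte(fit$ssq_total,
             sum(fit_residuals(m, ds, start)^2) + 1e-12)
})

test_that("permuting the block schedule leaves the optimum essentially unchanged", {
  m <- aav_model()
  truth <- default_parameters(m)
  ds <- generate_dataset(m, truth, noise = noise_model(0, 0), seed = 1)
  start <- truth
  start[recovery_quartet] <- start[recovery_quartet] * 1.3
  fit_fwd <- fit_kinetics(m, ds, free = recovery_quartet, start = start,
                          schedule = list(recovery_quartet[1:2],
                                          recovery_quartet[3:4]))
  fit_rev <- fit_kinetics(m, ds, free = recovery_quartet, start = start,
                          schedule = list(recovery_quartet[4:3],
                                          recovery_quartet[2:1]))
  # both reach (near) zero residual: compare on the data scale
  scale <- sum(ds$clean$values^2)
  expect_lt(abs(fit_fwd$ssq_total - fit_rev$ssq_total) / scale, 0.01)
})

test_that("fit configuration is validated", {
  m <- aav_model()
  ds <- generate_dataset(m, noise = noise_model(0, 0), seed = 1)
  expect_error(fit_kinetics(m, ds, free = c("vmax_HK", "C0_Glc")),
               "fixed by the data")
  expect_error(fit_kinetics(m, ds, free = c("vmax_HK", "vmax_NOPE")),
               "unknown free parameter")
  expect_error(fit_kinetics(m, ds, free = c("vmax_HK", "vmax_GLNS"),
                            block_size = 1), "between 2 and 10")
  expect_error(fit_kinetics(m, ds, free = c("vmax_HK", "vmax_GLNS"),
                            schedule = list("vmax_HK")), "partition")
  # default free set: everything except the five measured C0
  expect_length(free_parameters(m), 52L + 37L + 48L)
})

test_that("the residual report is additive and in squared units", {
  m <- aav_model()
  truth <- default_parameters(m)
  ds <- generate_dataset(m, truth, noise = noise_model(0.05, 0.02), seed = 3)
  fit <- fit_kinetics(m, ds, free = c("vmax_HK", "vmax_GLNS"),
                      start = truth, max_cycles = 2)
  rep <- report_fit(fit)
  expect_equal(rep$species, c("Gln", "GluAc", "Glc", "Lac", "NH4", "total"))
  expect_equal(rep$ssq[6], sum(rep$ssq[1:5]))
  expect_equal(rep$root_ssq, sqrt(rep$ssq))
  expect_equal(fit$ssq_total, sum(residuals(fit)^2))
  expect_equal(fit$smse, fit$ssq_total / 30)
  # methods are coherent
  expect_equal(unname(fitted(fit)$values + residuals(fit)),
               unname(ds$noisy$values))
  expect_equal(predict(fit)$values, fitted(fit)$values)
  expect_length(coef(fit), 142L)
})
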