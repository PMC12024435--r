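#' Residuals of a parameter set against observed profiles
#'
#' Simulates the model under `params`, extracts the observed species at the
#' data times and returns the flattened residual vector
#' (measured - predicted), species-blocked: all times for glutamine, then
#' glutamic acid, glucose, lactate, ammonium.
#'
#' @param model a `metabolic_model`.
#' @param data an `observed_profiles` object (see [read_profiles()] and
#'   [generate_dataset()]).
#' @param params full named parameter vector.
#' @return Numeric residual vector of length `n_species_observed * n_times`
#'   (mM). Simulation failures propagate as errors.
#' @export
fit_residuals <- function(model, data, params) {
  data <- as_observed_profiles(data, model)
  pred <- predict_profiles(model, params, data$times)
  as.vector(data$values - pred$values)
}

# simulate and observe at arbitrary times (prepending t = 0 if needed)
predict_profiles <- function(model, params, times) {
  sim_times <- times
  if (sim_times[1] != 0) sim_times <- c(0, sim_times)
  traj <- simulate_model(model, params, times = sim_times)
  obs <- observe(traj)
  keep <- match(times, obs$times)
  structure(list(times = times,
                 values = obs$values[keep, , drop = FALSE]),
            class = "observed_profiles")
}

#' One damped Gauss-Newton (Levenberg/Marquardt) step
#'
#' Computes the finite-difference Jacobian of the predictions at `p`,
#' solves the damped normal equations
#' `(J'J + lambda diag(J'J)) dp = J' r` and applies the adaptive damping
#' schedule: an accepted step (lower sum of squares) divides `lambda` by
#' 10; a rejected trial multiplies it by 10 and retries. A trial whose
#' residual evaluation fails is treated as non-improving.
#'
#' @param resid_fn function mapping a parameter vector to a residual vector
#'   (measured - predicted).
#' @param p current parameter vector.
#' @param lambda current Marquardt damping parameter.
#' @param h_rel relative finite-difference step for the Jacobian.
#' @param lambda_max damping ceiling; exceeding it without an accepted step
#'   raises a stalled-step error (condition class `aavmet_stalled`).
#' @param step_tol if the proposed shift is below this relative size the
#'   step is rejected as converged.
#' @return List with `p`, `ssq`, `lambda`, `accepted`, `converged`.
#' @examples
#' # linear problem: exact Gauss-Newton, converges in a few steps
#' st <- lm_step(function(p) p - 3, p = 0)
#' st$p
#' @export
lm_step <- function(resid_fn, p, lambda = 1e-3, h_rel = 1e-6,
                    lambda_max = 1e10, step_tol = 1e-10) {
  r0 <- resid_fn(p)
  ssq0 <- sum(r0^2)
  n_p <- length(p)
  # J = d(prediction)/dp = -d(residual)/dp, forward differences
  J <- matrix(0, length(r0), n_p)
  for (j in seq_len(n_p)) {
    h <- h_rel * max(abs(p[j]), 1)
    pj <- p
    pj[j] <- pj[j] + h
    J[, j] <- -(resid_fn(pj) - r0) / h
  }
  A0 <- crossprod(J)
  g <- crossprod(J, r0)
  d0 <- diag(A0)
  d0[d0 <= 0] <- max(d0, .Machine$double.eps)
  repeat {
    delta <- tryCatch(
      solve(A0 + lambda * diag(d0, nrow = n_p), g),
      error = function(e) NULL
    )
    if (!is.null(delta)) {
      delta <- drop(delta)
      if (max(abs(delta) / pmax(abs(p), 1)) < step_tol) {
        return(list(p = p, ssq = ssq0, lambda = lambda,
                    accepted = FALSE, converged = TRUE))
      }
      ssq1 <- tryCatch(sum(resid_fn(p + delta)^2), error = function(e) Inf)
      if (is.finite(ssq1) && ssq1 < ssq0) {
        return(list(p = p + delta, ssq = ssq1, lambda = lambda / 10,
                    accepted = TRUE, converged = FALSE))
      }
    }
    lambda <- lambda * 10
    if (lambda > lambda_max) {
      stop(structure(
        class = c("aavmet_stalled", "error", "condition"),
        list(message = "Levenberg/Marquardt step stalled: no acceptable shift below damping ceiling",
             call = sys.call(-1))
      ))
    }
  }
}

# run lm_step to convergence on one residual function
lm_optimize <- function(resid_fn, p, max_iter = 50, rel_tol = 1e-8) {
  lambda <- 1e-3
  ssq <- sum(resid_fn(p)^2)
  history <- numeric()
  for (it in seq_len(max_iter)) {
    # a stalled step or a Jacobian evaluation lost to integrator failure
    # ends the block visit; the current parameters stay
    st <- tryCatch(lm_step(resid_fn, p, lambda),
                   error = function(e) NULL)
    if (is.null(st) || st$converged) break
    improved <- (ssq - st$ssq) / max(ssq, .Machine$double.eps)
    p <- st$p
    lambda <- st$lambda
    ssq <- st$ssq
    history <- c(history, ssq)
    if (improved < rel_tol) break
  }
  list(p = p, ssq = ssq, history = history)
}

#' Block-coordinate NGL/M parameter estimation
#'
#' Fits kinetic parameters (Km, vmax) and free initial concentrations to
#' observed metabolite profiles by nonlinear least squares, a few
#' parameters at a time: the free parameters are split into blocks of
#' `block_size` (2-10), each block is optimised by damped Gauss-Newton
#' steps while the rest stay fixed, and the cycle over blocks repeats until
#' the parameters no longer change appreciably. Parameters are fitted on
#' the log scale, which enforces positivity across their 1e-7 to 30 mM
#' span.
#'
#' The five measured species have known initial concentrations, so their
#' `C0_*` entries are never free; by default every other parameter
#' (52 Km + 37 vmax + 48 C0) is fitted.
#'
#' @param model a `metabolic_model`.
#' @param data observed profiles: an `observed_profiles` object, a
#'   `synthetic_dataset` (its noisy profiles are used) or a data frame in
#'   the profile CSV layout.
#' @param free names of the parameters to fit; defaults to
#'   [free_parameters()] of the model.
#' @param start full starting parameter vector (defaults to the model's
#'   shipped values).
#' @param block_size parameters fitted at a time, between 2 and 10.
#' @param schedule optional list of character vectors giving explicit block
#'   compositions; overrides `block_size`.
#' @param max_cycles maximum outer passes over all blocks.
#' @param outer_tol outer convergence: maximum relative parameter change
#'   across a full cycle.
#' @param inner_tol inner convergence: relative sum-of-squares improvement
#'   below which a block stops.
#' @param max_inner maximum accepted steps per block visit.
#' @param verbose print per-cycle progress.
#' @return A `kinetic_fit` object with components `parameters` (full
#'   optimized vector), `ssq_total` and `ssq_per_species` (mM^2), `smse`
#'   (ssq_total / n residuals), `n_iterations`, `converged`, `history`
#'   (ssq after each accepted step), plus the model, data and free-parameter
#'   list. Has `print`, `summary`, `coef`, `fitted`, `residuals`,
#'   `predict`, `plot` and `simulate` methods.
#' @examples
#' \donttest{
#' m <- aav_model()
#' truth <- default_parameters(m)
#' ds <- generate_dataset(m, truth, noise = noise_model(0, 0), seed = 1)
#' start <- perturb_parameters(truth, c("vmax_HK", "Km_Glc"), c(1.3, 1.3), seed = 1)
#' fit <- fit_kinetics(m, ds, free = c("vmax_HK", "Km_Glc"), start = start,
#'                     block_size = 2)
#' coef(fit, "free")
#' }
#' @export
fit_kinetics <- function(model, data, free = free_parameters(model),
                         start = default_parameters(model),
                         block_size = 4, schedule = NULL,
                         max_cycles = 20, outer_tol = 1e-4,
                         inner_tol = 1e-8, max_inner = 50,
                         verbose = FALSE) {
  stopifnot(inherits(model, "metabolic_model"))
  data <- as_observed_profiles(data, model)
  if (is.null(schedule)) {
    if (block_size < 2 || block_size > 10) {
      stop("'block_size' must be between 2 and 10")
    }
    schedule <- split(free, ceiling(seq_along(free) / block_size))
  }
  covered <- unlist(schedule)
  if (!setequal(covered, free) || anyDuplicated(covered)) {
    stop("'schedule' must partition the free parameters")
  }
  fixed_c0 <- paste0("C0_", model$species$id[model$species$fixed_initial])
  if (any(free %in% fixed_c0)) {
    stop("initial concentrations of the measured species are fixed by the ",
         "data and cannot be fitted: ",
         paste(intersect(free, fixed_c0), collapse = ", "))
  }
  missing <- setdiff(free, names(start))
  if (length(missing)) {
    stop("unknown free parameter: ", paste(missing, collapse = ", "))
  }

  params <- start
  resid_for <- function(block) {
    function(logq) {
      p <- params
      p[block] <- exp(logq)
      fit_residuals(model, data, p)
    }
  }
  ssq_of <- function(p) sum(fit_residuals(model, data, p)^2)

  ssq <- ssq_of(params)
  history <- ssq
  best <- list(params = params, ssq = ssq)
  n_iter <- 0L
  converged <- FALSE
  floor_log <- log(1e-12)   # guard against log(0) for zero-valued starts

  for (cycle in seq_len(max_cycles)) {
    cycle_start <- params[free]
    for (block in schedule) {
      q0 <- pmax(log(params[block]), floor_log)
      opt <- lm_optimize(resid_for(block), q0,
                         max_iter = max_inner, rel_tol = inner_tol)
      if (opt$ssq < ssq) {
        params[block] <- exp(opt$p)
        ssq <- opt$ssq
        history <- c(history, opt$history[opt$history <= ssq_last(history)])
        n_iter <- n_iter + length(opt$history)
        if (ssq < best$ssq) best <- list(params = params, ssq = ssq)
      }
    }
    delta <- max(abs(params[free] - cycle_start) /
                   pmax(abs(cycle_start), 1e-12))
    if (verbose) {
      message(sprintf("cycle %d: ssq = %.6g, max rel change = %.3g",
                      cycle, ssq, delta))
    }
    if (delta < outer_tol) {
      converged <- TRUE
      break
    }
  }

  params <- best$params
  res_mat <- residual_matrix(model, data, params)
  ssq_sp <- colSums(res_mat^2)
  structure(
    list(model = model, data = data, free = free, start = start,
         parameters = params,
         ssq_total = sum(ssq_sp), ssq_per_species = ssq_sp,
         smse = sum(ssq_sp) / length(res_mat),
         n_residuals = length(res_mat),
         n_iterations = n_iter, n_cycles = cycle,
         converged = converged, history = history),
    class = "kinetic_fit"
  )
}

ssq_last <- function(h) if (length(h)) h[length(h)] else Inf

residual_matrix <- function(model, data, params) {
  pred <- predict_profiles(model, params, data$times)
  data$values - pred$values
}

#' Default free parameters of a model
#'
#' All Km and vmax parameters plus the initial concentrations of every
#' species whose t = 0 value was not measured.
#'
#' @param model a `metabolic_model`.
#' @return Character vector of parameter names.
#' @export
free_parameters <- function(model) {
  c(paste0("Km_", names(model$km)),
    paste0("vmax_", names(model$vmax)),
    paste0("C0_", model$species$id[!model$species$fixed_initial]))
}

#' Per-species residual report of a fit
#'
#' Sum of squared residuals per observed metabolite and in total, together
#' with their square roots (root-ssq), in mM^2 and mM respectively.
#'
#' @param fit a `kinetic_fit`.
#' @return Data frame with columns `species`, `ssq`, `root_ssq`; the last
#'   row is the total.
#' @export
report_fit <- function(fit) {
  stopifnot(inherits(fit, "kinetic_fit"))
  ssq <- fit$ssq_per_species
  out <- data.frame(
    species = c(names(ssq), "total"),
    ssq = c(unname(ssq), fit$ssq_total),
    root_ssq = sqrt(c(unname(ssq), fit$ssq_total)),
    row.names = NULL
  )
  out
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Block-coordinate NGL/M kinetic fit\n")
  cat(sprintf("  %d free parameters, %d residuals; %d accepted steps over %d cycles (%s)\n",
              length(x$free), x$n_residuals, x$n_iterations, x$n_cycles,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  ssq total = %.6g mM^2, SMSE = %.6g mM^2\n",
              x$ssq_total, x$smse))
  invisible(x)
}

#' @export
summary.kinetic_fit <- function(object, ...) {
  chg <- object$parameters[object$free] / object$start[object$free]
  structure(
    list(fit = object, report = report_fit(object),
         moved = sort(abs(log(chg)), decreasing = TRUE)),
    class = "summary.kinetic_fit"
  )
}

#' @export
print.summary.kinetic_fit <- function(x, ...) {
  print(x$fit)
  cat("\nResiduals by species:\n")
  print(x$report, row.names = FALSE)
  top <- utils::head(names(x$moved), 5L)
  if (length(top)) {
    cat("\nLargest parameter movements (|log fitted/start|):\n")
    print(round(x$moved[top], 4))
  }
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, which = c("all", "free"), ...) {
  which <- match.arg(which)
  if (which == "free") object$parameters[object$free] else object$parameters
}

#' @export
fitted.kinetic_fit <- function(object, ...) {
  predict_profiles(object$model, object$parameters, object$data$times)
}

#' @export
residuals.kinetic_fit <- function(object, ...) {
  residual_matrix(object$model, object$data, object$parameters)
}

#' @export
predict.kinetic_fit <- function(object, times = object$data$times, ...) {
  predict_profiles(object$model, object$parameters, times)
}

#' @export
plot.kinetic_fit <- function(x, ...) {
  obs <- x$data
  dense <- seq(0, max(obs$times), length.out = 101)
  pred <- predict_profiles(x$model, x$parameters, dense)
  sp <- colnames(obs$values)
  old <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (s in sp) {
    ylim <- range(obs$values[, s], pred$values[, s])
    graphics::plot(obs$times, obs$values[, s], pch = 8, ylim = ylim,
                   xlab = "time (h)", ylab = "mM", main = s, ...)
    graphics::lines(dense, pred$values[, s], lwd = 2)
  }
  invisible(x)
}

#' Simulate replicate datasets from a fitted model
#'
#' Draws `nsim` synthetic noisy datasets from the fitted parameter set,
#' using the package's measurement-noise model.
#'
#' @param object a `kinetic_fit`.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param noise a [noise_model()].
#' @param ... unused.
#' @return List of `synthetic_dataset` objects.
#' @export
simulate.kinetic_fit <- function(object, nsim = 1, seed = NULL,
                                 noise = noise_model(), ...) {
  if (is.null(seed)) seed <- 1L
  lapply(seq_len(nsim), function(i) {
    generate_dataset(object$model, object$parameters,
                     times = object$data$times,
                     noise = noise, seed = seed + i - 1L)
  })
}
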