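#' Saltelli-type paired sample matrices
#'
#' Draws the two independent uniform base matrices A and B over the given
#' parameter ranges plus the k cross matrices `AB[[i]]` (A with column i
#' replaced by B's), the design from which first-order Sobol indices are
#' estimated with (k + 2) * n model runs.
#'
#' @param ranges named list (or 2-row matrix) of `c(lower, upper)` per
#'   parameter; all parameters vary independently and uniformly.
#' @param n_base number of base samples n (>= 2).
#' @param seed integer seed; the design is reproducible.
#' @return List with matrices `A`, `B` (n x k, named columns) and list
#'   `AB` of k matrices.
#' @export
sample_parameter_space <- function(ranges, n_base, seed = 1L) {
  if (is.matrix(ranges)) {
    ranges <- stats::setNames(
      lapply(seq_len(ncol(ranges)), function(i) ranges[, i]),
      colnames(ranges)
    )
  }
  k <- length(ranges)
  if (k < 1) stop("'ranges' must contain at least one parameter")
  if (n_base < 2) stop("'n_base' must be at least 2")
  lo <- vapply(ranges, `[`, numeric(1), 1L)
  hi <- vapply(ranges, `[`, numeric(1), 2L)
  if (any(!(lo < hi))) {
    stop("every range needs lower < upper; offending: ",
         paste(names(ranges)[!(lo < hi)], collapse = ", "))
  }
  set.seed(seed)
  draw <- function() {
    m <- matrix(stats::runif(n_base * k), n_base, k)
    m <- sweep(sweep(m, 2, hi - lo, "*"), 2, lo, "+")
    colnames(m) <- names(ranges)
    m
  }
  A <- draw()
  B <- draw()
  AB <- lapply(seq_len(k), function(i) {
    m <- A
    m[, i] <- B[, i]
    m
  })
  names(AB) <- names(ranges)
  list(A = A, B = B, AB = AB)
}

#' First-order Sobol indices from paired ensembles
#'
#' Estimates `S_i = V[E[Y|X_i]] / V[Y]` for each parameter with the Jansen
#' estimator `V_i = V[Y] - mean((Y_B - Y_ABi)^2) / 2`, where Y_A, Y_B and
#' Y_ABi are the model outputs on the matrices of a Saltelli design.
#' Missing outputs (failed runs) are excluded pairwise. Percentile
#' bootstrap confidence intervals are attached.
#'
#' @param yA,yB numeric output vectors on the A and B matrices.
#' @param yAB n x k matrix of outputs on the AB cross matrices (one column
#'   per parameter).
#' @param n_boot bootstrap replicates for the confidence intervals (0 to
#'   skip).
#' @param seed seed for the bootstrap resampling.
#' @param conf confidence level.
#' @return Data frame with `parameter`, `S`, `CI_low`, `CI_high`, `SE`
#'   (bootstrap standard error), plus attributes `total_variance`, `mean`
#'   (f0) and `degenerate` (TRUE when the output variance vanishes, in
#'   which case all indices are 0).
#' @export
first_order_indices <- function(yA, yB, yAB, n_boot = 100L, seed = 1L,
                                conf = 0.95) {
  yAB <- as.matrix(yAB)
  k <- ncol(yAB)
  pars <- colnames(yAB) %||% paste0("X", seq_len(k))
  est <- function(idx) {
    a <- yA[idx]; b <- yB[idx]; ab <- yAB[idx, , drop = FALSE]
    vy <- stats::var(c(a, b), na.rm = TRUE)
    if (!is.finite(vy) || vy < .Machine$double.eps) {
      return(rep(0, k))
    }
    vapply(seq_len(k), function(i) {
      d2 <- (b - ab[, i])^2
      (vy - mean(d2, na.rm = TRUE) / 2) / vy
    }, numeric(1))
  }
  n <- length(yA)
  S <- est(seq_len(n))
  vy_full <- stats::var(c(yA, yB), na.rm = TRUE)
  degenerate <- !is.finite(vy_full) || vy_full < .Machine$double.eps
  ci <- matrix(NA_real_, k, 2)
  se <- rep(NA_real_, k)
  if (n_boot > 0 && !degenerate) {
    set.seed(seed)
    boots <- replicate(n_boot, est(sample.int(n, n, replace = TRUE)))
    if (k == 1) boots <- matrix(boots, nrow = 1)
    probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
    ci <- t(apply(boots, 1, stats::quantile, probs = probs, na.rm = TRUE))
    se <- apply(boots, 1, stats::sd, na.rm = TRUE)
  } else if (degenerate) {
    se <- rep(0, k)
  }
  out <- data.frame(parameter = pars, S = S,
                    CI_low = ci[, 1], CI_high = ci[, 2], SE = se,
                    row.names = NULL)
  attr(out, "total_variance") <- if (degenerate) 0 else vy_full
  attr(out, "mean") <- mean(c(yA, yB), na.rm = TRUE)
  attr(out, "degenerate") <- degenerate
  out
}

#' Run the model over a batch of parameter samples
#'
#' One simulate-and-observe pass per sample row; parameters not present in
#' the sample stay at the values in `params`. Failed integrations are
#' recorded as `NA` rows and counted; more than `max_fail_frac` failures
#' aborts with a suggestion to narrow the ranges.
#'
#' @param model a `metabolic_model`.
#' @param samples matrix of parameter samples (columns named by parameter).
#' @param params base full parameter vector.
#' @param outputs observed species to report.
#' @param times simulation time grid (h).
#' @param max_fail_frac tolerated fraction of failed runs.
#' @return List with `Y` (rows = samples; columns = one aggregate column
#'   per output plus one column per output x time) and `n_failed`.
#' @export
evaluate_model_batch <- function(model, samples, params = default_parameters(model),
                                 outputs = setdiff(model$observed, "GluAc"),
                                 times = seq(0, 120, by = 24),
                                 max_fail_frac = 0.1) {
  samples <- as.matrix(samples)
  cols <- batch_output_names(outputs, times)
  Y <- matrix(NA_real_, nrow(samples), length(cols),
              dimnames = list(NULL, cols))
  n_failed <- 0L
  for (r in seq_len(nrow(samples))) {
    p <- params
    p[colnames(samples)] <- samples[r, ]
    y <- tryCatch(batch_outputs(model, p, outputs, times),
                  error = function(e) NULL)
    if (is.null(y)) n_failed <- n_failed + 1L else Y[r, ] <- y
  }
  if (n_failed > max_fail_frac * nrow(samples)) {
    stop(sprintf(
      "%d of %d model evaluations failed; consider narrower parameter ranges",
      n_failed, nrow(samples)))
  }
  list(Y = Y, n_failed = n_failed)
}

batch_output_names <- function(outputs, times) {
  c("aggregate",
    paste0(rep(outputs, each = length(times)), "@t",
           rep(times, length(outputs))))
}

# scalar + time-resolved outputs for one parameter vector; the aggregate is
# the summed mean absolute excursion of each analysed output from its
# initial value over the grid
batch_outputs <- function(model, params, outputs, times) {
  obs <- observe(simulate_model(model, params, times = times))
  vals <- obs$values[, outputs, drop = FALSE]
  agg <- sum(colMeans(abs(sweep(vals, 2, vals[1, ], "-"))))
  c(agg, as.vector(vals))
}

#' Sobol first-order global sensitivity analysis of the model
#'
#' Varies a subset of the kinetic parameters simultaneously and uniformly
#' over finite ranges (default 0.5x to 1.5x their current values),
#' simulates the model over a Saltelli design and estimates the first-order
#' Sobol index of every parameter: aggregate (scalarized trajectory
#' excursion summed over the analysed outputs) and time-resolved per output
#' species. Glutamic acid is excluded from the analysed outputs by default,
#' since the model informs it only through the AAV protein-synthesis laws.
#'
#' @param model a `metabolic_model`.
#' @param params base full parameter vector.
#' @param subset `"vmax"`, `"Km"`, `"all"` or an explicit character vector
#'   of parameter names.
#' @param ranges optional named list of `c(lower, upper)` overriding the
#'   default `range_factor` scaling; parameters not listed keep the
#'   default.
#' @param range_factor multiplicative `c(lower, upper)` applied to the
#'   current value of each varied parameter.
#' @param n_base base sample count of the Saltelli design (total model runs
#'   = (k + 2) * n_base).
#' @param seed integer seed (sampling and bootstrap).
#' @param outputs analysed observed species.
#' @param times simulation grid (h).
#' @param n_boot bootstrap replicates for confidence intervals.
#' @return A `sobol_result`: list with `first_order` (aggregate data
#'   frame), `time_resolved` (parameter x output x time array of S_i),
#'   `time_resolved_se` (matching bootstrap standard errors),
#'   `total_variance`, `mean`, `n_failed`, `n_base`, `seed`, `ranges`.
#' @seealso [rank_parameters()], [write_sobol_results()]
#' @export
sobol_sensitivity <- function(model, params = default_parameters(model),
                              subset = "vmax", ranges = NULL,
                              range_factor = c(0.5, 1.5),
                              n_base = 1024L, seed = 1L,
                              outputs = setdiff(model$observed, "GluAc"),
                              times = seq(0, 120, by = 24),
                              n_boot = 100L) {
  stopifnot(inherits(model, "metabolic_model"))
  sel <- if (length(subset) == 1 && subset %in% c("vmax", "Km", "all")) {
    switch(subset,
           vmax = paste0("vmax_", names(model$vmax)),
           Km = paste0("Km_", names(model$km)),
           all = c(paste0("vmax_", names(model$vmax)),
                   paste0("Km_", names(model$km))))
  } else {
    missing <- setdiff(subset, names(params))
    if (length(missing)) {
      stop("unknown parameter in subset: ", paste(missing, collapse = ", "))
    }
    subset
  }
  rng <- stats::setNames(lapply(sel, function(nm) {
    if (!is.null(ranges[[nm]])) {
      ranges[[nm]]
    } else {
      v <- params[[nm]]
      if (v <= 0) {
        stop("parameter '", nm, "' has a nonpositive value; supply an ",
             "explicit range for it")
      }
      v * range_factor
    }
  }), sel)

  design <- sample_parameter_space(rng, n_base, seed = seed)
  evA <- evaluate_model_batch(model, design$A, params, outputs, times)
  evB <- evaluate_model_batch(model, design$B, params, outputs, times)
  evAB <- lapply(design$AB, evaluate_model_batch,
                 model = model, params = params,
                 outputs = outputs, times = times)
  n_failed <- evA$n_failed + evB$n_failed +
    sum(vapply(evAB, `[[`, integer(1), "n_failed"))

  cols <- colnames(evA$Y)
  per_col <- lapply(seq_along(cols), function(j) {
    yAB <- vapply(evAB, function(e) e$Y[, j], numeric(n_base))
    first_order_indices(evA$Y[, j], evB$Y[, j], yAB,
                        n_boot = n_boot, seed = seed)
  })
  names(per_col) <- cols

  k <- length(sel)
  dn <- list(sel, outputs, paste0("t", times))
  tr <- array(NA_real_, dim = c(k, length(outputs), length(times)),
              dimnames = dn)
  tr_se <- array(NA_real_, dim = dim(tr), dimnames = dn)
  for (o in seq_along(outputs)) {
    for (t in seq_along(times)) {
      fo_ot <- per_col[[paste0(outputs[o], "@t", times[t])]]
      tr[, o, t] <- fo_ot$S
      tr_se[, o, t] <- fo_ot$SE
    }
  }
  structure(
    list(first_order = per_col$aggregate,
         time_resolved = tr, time_resolved_se = tr_se,
         total_variance = vapply(per_col, attr, numeric(1), "total_variance"),
         mean = vapply(per_col, attr, numeric(1), "mean"),
         n_failed = n_failed, n_base = n_base, seed = seed,
         ranges = rng, outputs = outputs, times = times),
    class = "sobol_result"
  )
}

#' Rank parameters by first-order index
#'
#' Descending aggregate `S_i` with cumulative sums (the cumulative fraction
#' of output variance explained by the leading parameters); ties broken
#' alphabetically by parameter name.
#'
#' @param result a `sobol_result`, or a data frame with columns
#'   `parameter` and `S`.
#' @param group restrict to `"vmax"` or `"Km"` parameters, or `"all"`.
#' @return Data frame `parameter`, `S`, `cumulative`.
#' @export
rank_parameters <- function(result, group = c("all", "vmax", "Km")) {
  group <- match.arg(group)
  fo <- if (inherits(result, "sobol_result")) result$first_order else result
  if (group != "all") {
    fo <- fo[startsWith(fo$parameter, paste0(group, "_")), , drop = FALSE]
  }
  if (!nrow(fo)) {
    return(data.frame(parameter = character(), S = numeric(),
                      cumulative = numeric()))
  }
  ord <- order(-fo$S, fo$parameter)
  out <- fo[ord, c("parameter", "S")]
  out$cumulative <- cumsum(out$S)
  rownames(out) <- NULL
  out
}

#' @export
print.sobol_result <- function(x, ...) {
  cat("Sobol first-order sensitivity analysis\n")
  cat(sprintf("  %d parameters, n_base = %d ((k+2)n = %d runs, %d failed)\n",
              nrow(x$first_order), x$n_base,
              (nrow(x$first_order) + 2L) * x$n_base, x$n_failed))
  cat(sprintf("  outputs: %s at %d times; aggregate V[Y] = %.4g\n",
              paste(x$outputs, collapse = ", "), length(x$times),
              x$total_variance[["aggregate"]]))
  cat("  top aggregate indices:\n")
  print(utils::head(rank_parameters(x), 8), row.names = FALSE)
  invisible(x)
}

#' @export
plot.sobol_result <- function(x, n = 15, ...) {
  rk <- utils::head(rank_parameters(x), n)
  old <- graphics::par(mar = c(4, 9, 2, 1))
  on.exit(graphics::par(old))
  graphics::barplot(rev(rk$S), names.arg = rev(rk$parameter), horiz = TRUE,
                    las = 1, xlab = "first-order Sobol index", ...)
  invisible(x)
}
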