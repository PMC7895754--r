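#' Normalize a simulated or measured series
#'
#' Normalization conventions used throughout the calibration corpus:
#' `t0` (divide by the first element), `max` (by the series maximum),
#' `last_timepoint` (by the final element), `named_reference_timepoint`
#' (by the value at a given time; requires `times`), and
#' `named_reference_condition` (by an externally supplied reference value).
#'
#' @param values Numeric series (> 0 reference required).
#' @param mode One of the modes above.
#' @param reference Reference value (`named_reference_condition`) or time
#'   (`named_reference_timepoint`).
#' @param times Time stamps aligned with `values` (reference-timepoint
#'   mode).
#' @return The normalized series.
#' @export
normalize_series <- function(values, mode, reference = NULL, times = NULL) {
  mode <- match.arg(mode, c("t0", "max", "last_timepoint",
                            "named_reference_timepoint",
                            "named_reference_condition"))
  ref <- switch(mode,
    t0 = values[1],
    max = max(values),
    last_timepoint = values[length(values)],
    named_reference_timepoint = {
      if (is.null(times) || is.null(reference))
        stop("named_reference_timepoint needs 'times' and 'reference'")
      i <- match(reference, times)
      if (is.na(i)) stop("reference time ", reference, " not in series")
      values[i]
    },
    named_reference_condition = {
      if (is.null(reference))
        stop("named_reference_condition needs a 'reference' value")
      reference
    })
  if (!is.finite(ref) || ref <= 0)
    stop("normalization reference must be positive (got ", ref, ")")
  values / ref
}

#' Define a calibration dataset
#'
#' @param condition A [stimulation_protocol()] describing the experiment.
#' @param species Readout species id.
#' @param readout Readout mode (`"level"`, `"mRNA"`, `"production_rate"`).
#' @param times Measurement times in hours.
#' @param values Measured values, already normalized per `mode`.
#' @param mode Normalization mode (see [normalize_series()]).
#' @param reference Reference value/time for the named-reference modes.
#' @param weight Positive weight in the objective.
#' @param id Dataset label.
#' @return An object of class `mp_dataset`.
#' @export
calibration_dataset <- function(condition, species, readout, times, values,
                                mode = "t0", reference = NULL, weight = 1,
                                id = NULL) {
  stopifnot(inherits(condition, "mp_protocol"), length(times) == length(values),
            length(times) >= 1, weight > 0)
  structure(list(condition = condition, species = species,
                 readout = readout, times = times, values = values,
                 mode = mode, reference = reference, weight = weight,
                 id = id %||% paste0(condition$name, ":", species)),
            class = "mp_dataset")
}

# simulate all unique conditions once for a parameter vector
simulate_conditions <- function(net, datasets, settings, state) {
  keys <- vapply(datasets, function(d) d$condition$name, "")
  sims <- list()
  for (i in seq_along(datasets)) {
    k <- keys[i]
    if (is.null(sims[[k]])) {
      tg <- sort(unique(c(0, unlist(lapply(
        datasets[keys == k], `[[`, "times")),
        datasets[[i]]$condition$duration)))
      sims[[k]] <- simulate_protocol(net, datasets[[i]]$condition, settings,
                                     time_grid = tg, state = state)
    }
  }
  sims
}

#' Weighted least-squares calibration objective
#'
#' Simulates every dataset's condition (one shared pre-equilibrated
#' baseline per parameter vector), normalizes the simulated readout with
#' the dataset's own mode, and returns the weighted sum of squared
#' residuals against the (already normalized) data.
#'
#' @param net An `mp_network`.
#' @param overrides Named numeric vector of parameter values to apply
#'   (empty for the nominal objective).
#' @param datasets List of [calibration_dataset()] objects.
#' @param settings [solver_settings()].
#' @return Scalar objective value (`>= 0`).
#' @export
calibration_objective <- function(net, overrides = NULL, datasets,
                                  settings = solver_settings(rel_tol = 1e-6)) {
  if (!is.null(overrides) && length(overrides))
    net <- set_parameters(net, overrides)
  state <- equilibrate(net, settings)
  sims <- simulate_conditions(net, datasets, settings, state)
  total <- 0
  for (d in datasets) {
    sim <- sims[[d$condition$name]]
    v <- get_readout(sim, d$species, d$readout)
    idx <- match(d$times, sim$time)
    sim_norm <- normalize_series(v[idx], d$mode, d$reference, d$times)
    total <- total + d$weight * sum((sim_norm - d$values) ^ 2)
  }
  total
}

#' Fit free parameters against calibration datasets
#'
#' Multi-start bounded local search (`stats::nlminb`) in log10-parameter
#' space; start points are Latin-hypercube draws within the bounds (the
#' first start is the nominal value). Deterministic for a given seed.
#'
#' @param net An `mp_network`.
#' @param free Character vector of free parameter ids (empty: returns the
#'   nominal objective unchanged).
#' @param datasets List of [calibration_dataset()] objects.
#' @param lower,upper Named bounds on the natural scale; default
#'   `nominal / 100` and `nominal * 100`.
#' @param n_starts Number of multi-start points (default 5).
#' @param seed Integer seed.
#' @param settings [solver_settings()].
#' @param maxit Iteration budget per start.
#' @param include_nominal_start Use the nominal parameter values as the
#'   first start (default TRUE). Disable to probe flat directions of the
#'   objective from randomized starts only (e.g. in bootstrap
#'   identifiability analyses).
#' @return List of class `mp_fit`: estimates (named vector), objective,
#'   converged flag, seed, per-start table.
#' @export
fit_parameters <- function(net, free, datasets, lower = NULL, upper = NULL,
                           n_starts = 5, seed = 1,
                           settings = solver_settings(rel_tol = 1e-6),
                           maxit = 200, include_nominal_start = TRUE) {
  nominal <- parameter_values(net)
  if (!length(free)) {
    obj <- calibration_objective(net, NULL, datasets, settings)
    return(structure(list(estimates = numeric(0), objective = obj,
                          converged = TRUE, seed = seed, starts = NULL),
                     class = "mp_fit"))
  }
  stopifnot(all(free %in% names(nominal)))
  if (is.null(lower)) lower <- nominal[free] / 100
  if (is.null(upper)) upper <- nominal[free] * 100
  stopifnot(all(lower > 0), all(upper > lower))
  f <- function(lx) {
    x <- stats::setNames(10 ^ lx, free)
    tryCatch(calibration_objective(net, x, datasets, settings),
             error = function(e) 1e10)
  }
  llo <- log10(lower[free]); lhi <- log10(upper[free])
  n_random <- if (include_nominal_start) n_starts - 1 else n_starts
  starts <- rbind(if (include_nominal_start)
                    pmin(pmax(log10(nominal[free]), llo), lhi),
                  if (n_random > 0)
                    log10(lhs_sample(stats::setNames(
                      lapply(free, function(p) c(lower[[p]], upper[[p]])),
                      free), n_random, seed)))
  best <- NULL
  tab <- data.frame(start = integer(), objective = numeric(),
                    convergence = integer())
  for (s in seq_len(nrow(starts))) {
    res <- stats::nlminb(starts[s, ], f, lower = llo, upper = lhi,
                         control = list(iter.max = maxit, eval.max = 2 * maxit))
    tab <- rbind(tab, data.frame(start = s, objective = res$objective,
                                 convergence = res$convergence))
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  structure(list(estimates = stats::setNames(10 ^ best$par, free),
                 objective = best$objective,
                 converged = any(tab$convergence == 0) ||
                   best$objective < min(tab$objective) * (1 + 1e-9),
                 seed = seed, starts = tab),
            class = "mp_fit")
}

#' @export
print.mp_fit <- function(x, ...) {
  cat("<mp_fit> objective = ", signif(x$objective, 4), ", ",
      length(x$estimates), " fitted parameter(s)\n", sep = "")
  if (length(x$estimates)) print(signif(x$estimates, 4))
  invisible(x)
}

#' Bootstrap uncertainty of fitted parameters
#'
#' Dataset-level block bootstrap: whole datasets are resampled with
#' replacement, each replicate is refit, and per-parameter dispersion is
#' summarized as the coefficient of variation across replicates.
#'
#' @param net An `mp_network`.
#' @param free Free parameter ids.
#' @param datasets List of [calibration_dataset()] objects.
#' @param n_boot Number of bootstrap replicates (`>= 2`).
#' @param seed Integer seed.
#' @param ... Passed to [fit_parameters()].
#' @return List of class `mp_bootstrap`: replicates (n_boot x p matrix of
#'   estimates), cv (named per-parameter coefficient of variation), seed.
#' @export
bootstrap_uncertainty <- function(net, free, datasets, n_boot = 20, seed = 1,
                                  ...) {
  stopifnot(n_boot >= 2, length(datasets) >= 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  idx <- matrix(sample.int(length(datasets), n_boot * length(datasets),
                           replace = TRUE), n_boot)
  reps <- matrix(NA_real_, n_boot, length(free),
                 dimnames = list(NULL, free))
  for (b in seq_len(n_boot)) {
    fit <- fit_parameters(net, free, datasets[idx[b, ]],
                          seed = seed + b, ...)
    reps[b, ] <- fit$estimates[free]
  }
  cv <- apply(reps, 2, function(x) stats::sd(x) / mean(x))
  structure(list(replicates = reps, cv = cv, seed = seed,
                 resamples = idx),
            class = "mp_bootstrap")
}

#' Generate synthetic calibration datasets
#'
#' Simulates the given conditions, samples the readouts on a realistic
#' 0-48 h grid, applies multiplicative log-normal noise, and attaches a
#' normalization mode (randomly drawn among `t0`, `max`, `last_timepoint`
#' unless fixed). Stands in for a literature corpus in recovery tests;
#' seed-deterministic.
#'
#' @param net An `mp_network` (typically with perturbed "true" parameters).
#' @param conditions Named list of protocols.
#' @param readouts Data frame with columns species, readout.
#' @param noise_sd Log-normal noise standard deviation (natural log scale;
#'   default 0.1, i.e. ~10% multiplicative noise; 0 = exact curves).
#' @param seed Integer seed.
#' @param times Sampling times (default `c(0, 1, 2, 4, 8, 24, 48)` clipped
#'   to each condition's duration).
#' @param mode Normalization mode, or `"random"`.
#' @param settings [solver_settings()].
#' @return List of [calibration_dataset()] objects.
#' @export
generate_synthetic_datasets <- function(net, conditions, readouts,
                                        noise_sd = 0.1, seed = 1,
                                        times = c(0, 1, 2, 4, 8, 24, 48),
                                        mode = "random",
                                        settings = solver_settings()) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  state <- equilibrate(net, settings)
  out <- list()
  for (nm in names(conditions)) {
    cond <- conditions[[nm]]
    tg <- sort(unique(c(times[times <= cond$duration], 0, cond$duration)))
    sim <- simulate_protocol(net, cond, settings, time_grid = tg,
                             state = state)
    for (i in seq_len(nrow(readouts))) {
      v <- get_readout(sim, readouts$species[i], readouts$readout[i])
      v <- v[match(times[times <= cond$duration], sim$time)]
      noisy <- v * exp(stats::rnorm(length(v), 0, noise_sd))
      m <- if (identical(mode, "random"))
        sample(c("t0", "max", "last_timepoint"), 1) else mode
      out[[length(out) + 1]] <- calibration_dataset(
        cond, readouts$species[i], readouts$readout[i],
        times = times[times <= cond$duration],
        values = normalize_series(noisy, m),
        mode = m,
        id = paste0(nm, ":", readouts$species[i]))
    }
  }
  out
}
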