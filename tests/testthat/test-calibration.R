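test_that("normalize_series implements every mode", {
  expect_equal(normalize_series(c(2, 4, 8), "t0"), c(1, 2, 4))
  expect_equal(normalize_series(c(2, 4, 8), "max"), c(0.25, 0.5, 1))
  expect_equal(normalize_series(c(2, 4, 8), "last_timepoint"),
               c(0.25, 0.5, 1))
  expect_equal(normalize_series(c(2, 4, 8), "named_reference_timepoint",
                                reference = 1, times = c(0, 1, 2)),
               c(0.5, 1, 2))
  expect_equal(normalize_series(c(2, 4, 8), "named_reference_condition",
                                reference = 4), c(0.5, 1, 2))
  expect_error(normalize_series(c(0, 1), "t0"), "positive")
  expect_error(normalize_series(1:3, "named_reference_timepoint",
                                reference = 9, times = c(0, 1, 2)),
               "not in series")
})

test_that("t0 and named-reference normalizations are idempotent", {
  x <- c(3, 6, 12, 9)
  n1 <- normalize_series(x, "t0")
  expect_equal(normalize_series(n1, "t0"), n1)
  n2 <- normalize_series(x, "named_reference_timepoint", reference = 1,
                         times = 0:3)
  expect_equal(normalize_series(n2, "named_reference_timepoint",
                                reference = 1, times = 0:3), n2)
})

toy_conditions <- function() list(
  a = stimulation_protocol(events = dose_event(0, "X", 500, "copies"),
                           duration = 12, name = "a"),
  b = stimulation_protocol(events = dose_event(0, "X", 2000, "copies"),
                           duration = 12, name = "b"))

test_that("the objective is zero for self-generated data and scales with weights", {
  truth <- synth_decay_network(ks = 150, kd = 0.6)
  ds <- generate_synthetic_datasets(truth, toy_conditions(),
                                    data.frame(species = "X",
                                               readout = "level"),
                                    noise_sd = 0, seed = 2, mode = "t0")
  expect_lt(calibration_objective(truth, NULL, ds), 1e-8)
  # dataset order does not matter
  expect_equal(calibration_objective(truth, c(ks = 200), ds),
               calibration_objective(truth, c(ks = 200), rev(ds)))
  # doubling the weights doubles the objective
  ds2 <- lapply(ds, function(d) { d$weight <- 2; d })
  obj1 <- calibration_objective(truth, c(ks = 200, kd = 0.9), ds)
  obj2 <- calibration_objective(truth, c(ks = 200, kd = 0.9), ds2)
  expect_equal(obj2, 2 * obj1)
})

test_that("perturbing a fitted parameter increases the objective", {
  truth <- synth_decay_network(ks = 150, kd = 0.6)
  ds <- generate_synthetic_datasets(truth, toy_conditions(),
                                    data.frame(species = "X",
                                               readout = "level"),
                                    noise_sd = 0, seed = 2, mode = "t0")
  at_opt <- calibration_objective(truth, NULL, ds)
  for (f in c(1.05, 0.95)) {
    expect_gt(calibration_objective(truth, c(kd = 0.6 * f), ds), at_opt)
    expect_gt(calibration_objective(truth, c(ks = 150 * f), ds), at_opt)
  }
})

test_that("noiseless synthetic data recovers parameters within 5%", {
  truth <- synth_decay_network(ks = 180, kd = 0.8)
  ds <- generate_synthetic_datasets(truth, toy_conditions(),
                                    data.frame(species = "X",
                                               readout = "level"),
                                    noise_sd = 0, seed = 3, mode = "t0")
  fit <- fit_parameters(synth_decay_network(), c("ks", "kd"), ds,
                        n_starts = 4, seed = 5, maxit = 100)
  expect_lt(max(abs(fit$estimates / c(ks = 180, kd = 0.8) - 1)), 0.05)
  expect_true(fit$converged)
})

test_that("a fit with zero free parameters returns the nominal objective", {
  truth <- synth_decay_network(ks = 150, kd = 0.6)
  ds <- generate_synthetic_datasets(truth, toy_conditions(),
                                    data.frame(species = "X",
                                               readout = "level"),
                                    noise_sd = 0, seed = 2, mode = "t0")
  fit <- fit_parameters(truth, character(), ds)
  expect_length(fit$estimates, 0)
  expect_equal(fit$objective, calibration_objective(truth, NULL, ds))
})

test_that("generated fixtures are seed-deterministic and noise-free at sd 0", {
  truth <- synth_decay_network(ks = 150, kd = 0.6)
  ro <- data.frame(species = "X", readout = "level")
  d1 <- generate_synthetic_datasets(truth, toy_conditions(), ro,
                                    noise_sd = 0.2, seed = 4)
  d2 <- generate_synthetic_datasets(truth, toy_conditions(), ro,
                                    noise_sd = 0.2, seed = 4)
  expect_equal(lapply(d1, `[[`, "values"), lapply(d2, `[[`, "values"))
  d3 <- generate_synthetic_datasets(truth, toy_conditions(), ro,
                                    noise_sd = 0.2, seed = 5)
  expect_false(isTRUE(all.equal(d1[[1]]$values, d3[[1]]$values)))
})

test_that("forced-identical bootstrap resamples give identical fits", {
  truth <- synth_decay_network(ks = 150, kd = 0.6)
  ds <- generate_synthetic_datasets(truth, toy_conditions()["a"],
                                    data.frame(species = "X",
                                               readout = "level"),
                                    noise_sd = 0, seed = 2, mode = "t0")
  # a single dataset: every resample is necessarily the same block, and the
  # two replicates differ only through their fit seeds -> force those equal
  boot <- bootstrap_uncertainty(truth, "kd", ds, n_boot = 2, seed = 1,
                                n_starts = 1, maxit = 50)
  expect_equal(boot$replicates[1, ], boot$replicates[2, ])
})
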