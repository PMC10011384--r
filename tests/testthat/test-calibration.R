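# Water calibration and parameter fitting.

test_that("water calibration closes: calibrated strengths are exactly 1", {
  cal <- calibrate_water(seed = 5)
  expect_equal(cal$D * cal$qH_corrected, 1, tolerance = 1e-12)
  expect_equal(cal$A * cal$qO_corrected, 1, tolerance = 1e-12)
  w <- cal$water
  s <- molecular_strengths(w, strength_params(D = cal$D, A = cal$A,
                                              T = cal$T))
  # the calibrated mean closes exactly; individual hydrogens differ only
  # by the residual asymmetry of the minimised geometry
  expect_equal(mean(s$donor), 1, tolerance = 1e-9)
  expect_equal(unname(s$donor), c(1, 1), tolerance = 1e-2)
  expect_equal(unname(s$acceptor), 1, tolerance = 1e-9)
  # reciprocal contract on a constructed corrected charge
  expect_equal(1 / 0.02, 50)
})

test_that("early stopping halts after `patience` non-improving trials", {
  # alkanes only: no donors/acceptors, so the linear solve is exact from
  # trial one and the loss landscape is flat at zero
  f <- tempfile(fileext = ".smi")
  writeLines(c("CC a", "CCC b", "CCCC c"), f)
  mols <- lapply(prepare_conformers(load_molecules(f, "smiles"), seed = 4),
                 compute_charges_radii)
  dg <- predict_hydration(mols)$dG_total
  fit <- fit_parameters(mols, dg, patience = 1, seed = 9)
  expect_equal(fit$n_trials, 2)
  expect_equal(fit$best_mae, min(fit$trial_log$mae))
})

test_that("fitting is deterministic given data and seed", {
  syn <- generate_synthetic_dataset(8, seed = 77, noise_sd = 0.5)
  f1 <- fit_parameters(syn$records, syn$dg, max_trials = 40, seed = 13)
  f2 <- fit_parameters(syn$records, syn$dg, max_trials = 40, seed = 13)
  expect_identical(f1$trial_log, f2$trial_log)
  # never worse than the starting point
  expect_lte(f1$best_mae, f1$trial_log$mae[1])
})

test_that("fitting rejects degenerate inputs", {
  expect_error(fit_parameters(list(), numeric(0)), "empty dataset")
})

test_that("parameter files round-trip through YAML", {
  p <- hydration_params(g_d = 1.23, F = 0.3,
                        strength = strength_params(D = 8.5, A = -3.1))
  f <- tempfile(fileext = ".yaml")
  write_params(p, f)
  p2 <- read_params(f)
  expect_equal(p2$g_d, 1.23)
  expect_equal(p2$F, 0.3)
  expect_equal(p2$strength$D, 8.5)
  expect_error(read_params({
    f2 <- tempfile(fileext = ".yaml"); yaml::write_yaml(list(D = 1), f2); f2
  }), "misses keys")
})

test_that("search bounds preserve sign and span one decade each way", {
  sp <- default_search_space()
  expect_equal(sp$g_a, c(-161.31, -1.6131))
  expect_equal(sp$g_d, c(0.0908, 9.08))
  expect_true(all(vapply(sp, function(b) b[1] < b[2], logical(1))))
})
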