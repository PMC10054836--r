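test_that("initial_guess recovers the gross spectrum shape", {
  # near-pure resistor: r_media dominates everywhere
  r_only <- circuit_params(100, 1e-4, 1, 1e-4, 1)
  g <- initial_guess(simulate_impedance(r_only))
  expect_lt(abs(g$r_media - 100) / 100, 0.01)
  # known barrier: guessed TEER within 10 %
  p <- barrier_preset("pre")
  g2 <- initial_guess(simulate_impedance(p))
  expect_lt(rel_err(g2$r1 + g2$r2, 746), 0.10)
  expect_true(all(unlist(g2) > 0))
})

test_that("initial_guess falls back with a warning on degenerate input", {
  short <- simulate_impedance(barrier_preset("pre"), c(10, 20, 30))
  expect_warning(initial_guess(short), class = "episens_guess_fallback")
  expect_error(initial_guess(tibble::tibble(frequency_hz = numeric(),
                                            z_real_ohm_cm2 = numeric(),
                                            z_imag_ohm_cm2 = numeric())),
               class = "episens_invalid_input")
})

test_that("noiseless spectra are refit to the generating parameters", {
  truth <- circuit_params(20, 300, 2.4, 446, 7.2)
  fit <- fit_circuit(simulate_impedance(truth, log_freq_grid(50)))
  for (nm in c("r_media", "r1", "c1", "r2", "c2")) {
    expect_lt(rel_err(fit$params[[nm]], truth[[nm]]), 1e-3)
  }
  expect_true(fit$identifiable_split)
  expect_true(all(is.finite(fit$stderr)))
})

test_that("fitting is invariant under swapping the generator element labels", {
  a <- circuit_params(20, 300, 2.4, 446, 7.2)
  b <- circuit_params(20, 446, 7.2, 300, 2.4)
  fa <- fit_circuit(simulate_impedance(a))
  fb <- fit_circuit(simulate_impedance(b))
  expect_equal(fa$metrics$teer_ohm_cm2, fb$metrics$teer_ohm_cm2,
               tolerance = 1e-8)
  expect_equal(fa$metrics$c_cell_uf_cm2, fb$metrics$c_cell_uf_cm2,
               tolerance = 1e-8)
})

test_that("TEER and series capacitance are recovered across random circuits", {
  set.seed(5)
  grid <- log_freq_grid(50)
  for (i in 1:25) {
    truth <- rand_params()
    fit <- fit_circuit(simulate_impedance(truth, grid))
    m <- barrier_metrics(truth)
    expect_lt(rel_err(fit$metrics$teer_ohm_cm2, m$teer_ohm_cm2), 1e-3)
    expect_lt(rel_err(fit$metrics$c_cell_uf_cm2, m$c_cell_uf_cm2), 1e-3)
  }
})

test_that("TEER is robust to 1 % proportional instrument noise", {
  truth <- barrier_preset("pre")
  errs <- vapply(1:100, function(s) {
    spec <- gen_spectrum(truth, noise = noise_model("proportional_gaussian",
                                                    0.01, seed = s))
    rel_err(fit_circuit(spec)$metrics$teer_ohm_cm2, 746)
  }, 0)
  expect_lt(median(errs), 0.02)
})

test_that("the fit sits at a local optimum of the weighted objective", {
  set.seed(9)
  grid <- log_freq_grid(40)
  for (i in 1:20) {
    truth <- rand_params()
    spec <- simulate_impedance(truth, grid)
    fit <- fit_circuit(spec)
    chi_fit <- oracle_chi2(fit$params, spec)
    for (nm in c("r_media", "r1", "c1", "r2", "c2")) {
      for (fac in c(0.8, 1.2)) {
        pert <- unclass(fit$params)
        pert[[nm]] <- pert[[nm]] * fac
        expect_gt(oracle_chi2(pert, spec), chi_fit)
      }
    }
  }
})

test_that("equal time constants are flagged unidentifiable but TEER survives", {
  # tau1 = tau2 = 1 ms: the two-RC model collapses to a single arc
  truth <- circuit_params(20, 200, 5, 400, 2.5)
  fit <- fit_circuit(simulate_impedance(truth, log_freq_grid(50)))
  expect_false(fit$identifiable_split)
  expect_lt(rel_err(fit$metrics$teer_ohm_cm2, 600), 0.005)
  # c_cell = tau / TEER stays identifiable too
  expect_lt(rel_err(fit$metrics$c_cell_uf_cm2,
                    barrier_metrics(truth)$c_cell_uf_cm2), 0.005)
})

test_that("degenerate and iteration-capped fits raise typed errors", {
  flat <- tibble::tibble(frequency_hz = log_freq_grid(20),
                         z_real_ohm_cm2 = 100, z_imag_ohm_cm2 = 0)
  expect_error(fit_circuit(flat), class = "episens_invalid_input")
  spec <- gen_spectrum(barrier_preset("pre"),
                       noise = noise_model("proportional_gaussian", 0.01,
                                           seed = 7))
  err <- tryCatch(fit_circuit(spec, max_iterations = 1),
                  episens_convergence_error = function(e) e)
  expect_s3_class(err, "episens_convergence_error")
  expect_s3_class(err$best_params, "circuit_params")
})

test_that("condition comparison reports signed TEER changes", {
  pre <- fit_circuit(simulate_impedance(barrier_preset("pre")))
  post <- fit_circuit(simulate_impedance(barrier_preset("post")))
  cmp <- compare_conditions(pre, post)
  expect_equal(cmp$delta_teer, 458, tolerance = 1e-6)
  expect_equal(cmp$delta_teer_pct, 100 * 458 / 746, tolerance = 1e-6)
  expect_equal(compare_conditions(pre, pre)$delta_teer_pct, 0)
  rev <- compare_conditions(post, pre)
  expect_lt(rev$delta_teer_pct, 0)
  expect_equal(rev$delta_teer, -458, tolerance = 1e-6)
})

test_that("fit objects expose tidy, glance and autoplot", {
  fit <- fit_circuit(simulate_impedance(barrier_preset("pre")))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "unit"))
  expect_equal(td$term, c("r_media", "r1", "c1", "r2", "c2"))
  gl <- glance(fit)
  expect_equal(gl$teer_ohm_cm2, 746, tolerance = 1e-6)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
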