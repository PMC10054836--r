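test_that("protocol presets carry the instrument settings", {
  cu <- swv_protocol("Cu")
  expect_equal(
    unlist(cu[c("precondition_potential_v", "precondition_time_s",
                "e_start_v", "e_end_v", "step_v", "amplitude_v",
                "frequency_hz", "cleaning_potential_v", "cleaning_time_s")]),
    c(precondition_potential_v = -1.0, precondition_time_s = 30,
      e_start_v = -0.2, e_end_v = 0.5, step_v = 0.004, amplitude_v = 0.020,
      frequency_hz = 25, cleaning_potential_v = 0.3, cleaning_time_s = 90)
  )
  zn <- swv_protocol("Zn")
  expect_equal(
    unlist(zn[c("precondition_potential_v", "e_start_v", "e_end_v",
                "step_v", "amplitude_v", "frequency_hz")]),
    c(precondition_potential_v = -1.2, e_start_v = -1.0, e_end_v = -0.2,
      step_v = 0.008, amplitude_v = 0.050, frequency_hz = 50)
  )
  expect_error(swv_protocol("Cu", step_v = -0.001),
               class = "episens_invalid_input")
  expect_error(swv_protocol("Cu", e_end_v = -0.2),
               class = "episens_invalid_input")
})

test_that("potential grids are arithmetic and sized by the scan window", {
  g_cu <- potential_grid(swv_protocol("Cu"))
  expect_length(g_cu, 176)
  expect_equal(g_cu[1], -0.2)
  expect_equal(g_cu[176], 0.5)
  expect_equal(unique(round(diff(g_cu), 12)), 0.004)
  g_zn <- potential_grid(swv_protocol("Zn"))
  expect_length(g_zn, 101)
  expect_equal(range(g_zn), c(-1.0, -0.2))
  expect_error(potential_grid(swv_protocol("Cu", step_v = 1)),
               class = "episens_invalid_input")
})

test_that("baseline correction removes any straight line", {
  pr <- swv_protocol("Cu")
  grid <- potential_grid(pr)
  line <- voltammogram(pr, 2e-7 + 5e-7 * grid)
  expect_lt(max(abs(baseline_correct(line)$current_a)), 1e-18)
  flat <- voltammogram(pr, rep(0, length(grid)))
  expect_equal(baseline_correct(flat)$current_a, rep(0, length(grid)))
  # Gaussian + line: the peak region is recovered within 1 % of A
  gauss <- 1e-6 * exp(-(grid - 0.1)^2 / (2 * 0.03^2))
  v <- voltammogram(pr, gauss + 2e-7 + 5e-7 * grid)
  corr <- baseline_correct(v)
  core <- abs(grid - 0.1) < 0.06
  expect_lt(max(abs(corr$current_a[core] - gauss[core])), 0.01 * 1e-6)
  expect_equal(corr$potential_v, grid)
  expect_error(baseline_correct(v, flank_fraction = 0.5),
               class = "episens_invalid_input")
  expect_error(baseline_correct(v[1:10, ], flank_fraction = 0.05),
               class = "episens_invalid_input")
})

test_that("find_peak locates the oxidation peak and rejects blanks", {
  pr <- swv_protocol("Cu")
  v <- gen_voltammogram(pr, peak_center = 0.1, peak_height = 1e-6,
                        noise = noise_model("none"))
  pk <- find_peak(v)
  expect_true(pk$found)
  expect_lt(rel_err(pk$i_peak_a, 1e-6), 0.005)
  expect_lte(abs(pk$e_peak_v - 0.1), pr$step_v)
  # flat zero trace: no peak (the pre-transport basolateral case)
  blank <- voltammogram(pr, rep(0, 176))
  expect_false(find_peak(blank)$found)
  # two peaks, only the in-window one is returned
  grid <- potential_grid(pr)
  two <- voltammogram(pr, 1e-6 * exp(-(grid - 0.1)^2 / (2 * 0.03^2)) +
                          3e-6 * exp(-(grid - 0.3)^2 / (2 * 0.02^2)))
  pk2 <- find_peak(two, window = c(0, 0.2))
  expect_lte(abs(pk2$e_peak_v - 0.1), pr$step_v)
  expect_lt(rel_err(pk2$i_peak_a, 1e-6), 0.01)
  expect_error(find_peak(v, window = c(2, 3)),
               class = "episens_invalid_input")
})

test_that("peak height is invariant under added baselines and linear in amplitude", {
  pr <- swv_protocol("Cu")
  grid <- potential_grid(pr)
  base_v <- gen_voltammogram(pr, peak_center = 0.08, peak_height = 2e-6,
                             noise = noise_model("none"))
  h0 <- find_peak(base_v)$i_peak_a
  set.seed(21)
  for (i in 1:20) {
    slope <- runif(1, -1e-6, 1e-6)
    icpt <- runif(1, -1e-6, 1e-6)
    shifted <- voltammogram(pr, base_v$current_a + icpt + slope * grid)
    expect_lt(rel_err(find_peak(shifted)$i_peak_a, h0), 0.01)
  }
  for (k in c(0.1, 0.5, 2, 10)) {
    scaled <- voltammogram(pr, base_v$current_a * k)
    expect_lt(rel_err(find_peak(scaled)$i_peak_a, k * h0), 0.005)
  }
})

test_that("peak potential is hit to one step anywhere in the window", {
  pr <- swv_protocol("Zn")
  for (center in seq(-0.53, -0.37, by = 0.02)) {
    v <- gen_voltammogram(pr, peak_center = center, peak_height = 1e-6,
                          noise = noise_model("none"))
    pk <- find_peak(v)
    expect_true(pk$found)
    expect_lte(abs(pk$e_peak_v - center), pr$step_v)
  }
})
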