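test_that("points placed exactly on the printed Cu line are recovered", {
  line <- calibration_line("Cu")
  conc <- calibration_concentrations()
  d <- tibble::tibble(
    concentration_m = conc,
    peak_current_a = line$slope * log10(conc) + line$intercept
  )
  cal <- fit_calibration(d, ion = "Cu")
  expect_equal(cal$slope, 1.64e-7, tolerance = 1e-10)
  expect_equal(cal$intercept, 1.97e-6, tolerance = 1e-10)
  expect_equal(cal$r, 1, tolerance = 1e-12)
  expect_equal(cal$rsd_max_pct, 0)
  expect_equal(cal$n_points, 5L)
})

test_that("arbitrary exact lines are recovered to numerical precision", {
  set.seed(31)
  for (i in 1:20) {
    slope <- 10^runif(1, -8, -6)
    icpt <- 10^runif(1, -6, -5)
    conc <- 10^runif(5, -11, -6)
    d <- tibble::tibble(concentration_m = conc,
                        peak_current_a = slope * log10(conc) + icpt)
    cal <- fit_calibration(d)
    expect_lt(rel_err(cal$slope, slope), 1e-10)
    expect_lt(rel_err(cal$intercept, icpt), 1e-10)
    expect_equal(cal$r, 1, tolerance = 1e-9)
  }
})

test_that("the regression agrees with closed-form OLS on noisy replicates", {
  set.seed(8)
  d <- gen_calibration_set("Cu", replicates = 3,
                           noise = noise_model("proportional_gaussian", 0.05))
  cal <- fit_calibration(d)
  means <- tapply(d$peak_current_a, d$concentration_m, mean)
  want <- oracle_ols(log10(as.numeric(names(means))), as.numeric(means))
  expect_equal(cal$slope, unname(want["slope"]), tolerance = 1e-12)
  expect_equal(cal$intercept, unname(want["intercept"]), tolerance = 1e-12)
})

test_that("degenerate calibration inputs are handled", {
  d_flat <- tibble::tibble(concentration_m = c(1e-9, 1e-8, 1e-7),
                           peak_current_a = 1e-6)
  expect_warning(cal <- fit_calibration(d_flat), "correlation undefined")
  expect_equal(cal$slope, 0)
  expect_equal(cal$r, 0)
  expect_error(fit_calibration(tibble::tibble(concentration_m = c(1e-9, 1e-8),
                                              peak_current_a = c(1, 2))),
               class = "episens_invalid_input")
  expect_error(fit_calibration(tibble::tibble(
    concentration_m = rep(1e-9, 4), peak_current_a = 1:4
  )), class = "episens_invalid_input")
  expect_error(fit_calibration(tibble::tibble(concentration_m = c(-1, 1, 2),
                                              peak_current_a = c(1, 2, 3))),
               class = "episens_invalid_input")
})

test_that("noisy calibration stays linear and the RSD tracks the noise level", {
  set.seed(13)
  rs <- numeric(100)
  slopes <- numeric(100)
  rsd_point <- numeric(100)
  rsd_max <- numeric(100)
  for (s in 1:100) {
    d <- gen_calibration_set("Cu", replicates = 5,
                             noise = noise_model("proportional_gaussian", 0.05))
    cal <- fit_calibration(d)
    rs[s] <- cal$r
    slopes[s] <- cal$slope
    rsd_point[s] <- median(cal$points$rsd_pct)
    rsd_max[s] <- cal$rsd_max_pct
  }
  expect_gte(median(rs), 0.99)
  expect_lt(rel_err(median(slopes), 1.64e-7), 0.10)
  # each point's RSD estimates the 5 % generator CV within sampling error
  expect_lt(abs(median(rsd_point) - 5) / 5, 0.30)
  # the max over points is upward-biased (order statistic of 5 noisy
  # estimates) but must still track the generator CV
  expect_gte(median(rsd_max), median(rsd_point))
  expect_lt(median(rsd_max), 2 * 5)
})

test_that("the detection limit follows 3 sigma over slope", {
  line <- calibration_line("Cu")
  conc <- calibration_concentrations()
  cal <- fit_calibration(tibble::tibble(
    concentration_m = conc,
    peak_current_a = line$slope * log10(conc) + line$intercept
  ))
  expect_equal(lod(cal, 0), 0)
  # sigma inverted from the reported Cu detection limit: consistency only
  expect_equal(lod(cal, 1.372e-19), 2.51e-12, tolerance = 1e-3)
  expect_equal(lod(cal, 2 * 1.372e-19), 2 * lod(cal, 1.372e-19))
  expect_error(lod(cal, -1), class = "episens_invalid_input")
  down <- cal
  down$slope <- -1e-7
  expect_error(lod(down, 1e-9), class = "episens_invalid_input")
})

test_that("concentration prediction inverts the calibration line", {
  for (ion in c("Cu", "Zn")) {
    line <- calibration_line(ion)
    conc <- calibration_concentrations()
    cal <- fit_calibration(tibble::tibble(
      concentration_m = conc,
      peak_current_a = line$slope * log10(conc) + line$intercept
    ), ion = ion)
    for (c0 in c(1e-9, 1e-6)) {
      pred <- predict_concentration(cal, line$slope * log10(c0) + line$intercept)
      expect_lt(rel_err(pred$concentration_m, c0), 1e-3)
      expect_false(pred$extrapolated)
    }
    at_icpt <- predict_concentration(cal, line$intercept)
    expect_equal(at_icpt$concentration_m, 1, tolerance = 1e-9)
    expect_true(at_icpt$extrapolated)
  }
})

test_that("calibration objects expose tidy, glance and autoplot", {
  cal <- fit_calibration(gen_calibration_set("Zn", noise = noise_model("none")),
                         ion = "Zn")
  expect_equal(glance(cal)$slope, 5.36e-7, tolerance = 1e-9)
  expect_equal(tidy(cal)$estimate[2], 6.07e-6, tolerance = 1e-9)
  expect_s3_class(ggplot2::autoplot(cal), "ggplot")
})
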