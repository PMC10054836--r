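# Independent oracles, deliberately written as different algebra from the
# package internals.

# Circuit impedance via parallel admittances: Y = 1/R + j w C.
oracle_z <- function(p, f) {
  w <- 2 * pi * f
  p$r_media +
    1 / (1 / p$r1 + 1i * w * p$c1 * 1e-6) +
    1 / (1 / p$r2 + 1i * w * p$c2 * 1e-6)
}

# Textbook OLS in deviation form.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Log-uniform circuit draws over a physiological barrier range: element
# corner frequencies stay inside the 10 Hz - 100 kHz measurement band.
rand_params <- function() {
  lu <- function(lo, hi) 10^stats::runif(1, log10(lo), log10(hi))
  circuit_params(
    r_media = lu(5, 50),
    r1 = lu(100, 1000), c1 = lu(1, 10),
    r2 = lu(100, 1000), c2 = lu(1, 10)
  )
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

# Weighted CNLS objective recomputed test-side (modulus weighting).
oracle_chi2 <- function(p, spec) {
  z_obs <- complex(real = spec$z_real_ohm_cm2,
                   imaginary = spec$z_imag_ohm_cm2)
  z_mod <- oracle_z(p, spec$frequency_hz)
  sum(Mod(z_obs - z_mod)^2 / Mod(z_obs)^2)
}
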