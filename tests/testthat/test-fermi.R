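test_that("Fermi residue forms: half height, causal step, rectangle limit", {
  tt <- seq(0, 30, 0.1)
  r <- fermi_residue(tt, A = 2, k = 0.3, tau0 = 8)
  expect_equal(r[tt == 8], 1)                       # A/2 at tau0
  expect_true(all(diff(r) < 0))

  rd <- fermi_residue(tt, A = 2, k = 0.3, tau0 = 8, tau_d = 2.8,
                      variant = "fermi_delta")
  expect_true(all(rd[tt < 2.8] == 0))
  expect_equal(rd[tt == 2.8 + 8], 1)                # kernel shifted by tau_d

  # large k: rectangle of height A on [tau_d, tau_d + tau0]
  rk <- fermi_residue(tt, A = 2, k = 500, tau0 = 5, tau_d = 2,
                      variant = "fermi_delta")
  expect_equal(rk[tt > 2.01 & tt < 6.9], rep(2, sum(tt > 2.01 & tt < 6.9)),
               tolerance = 1e-6)
  expect_equal(rk[tt > 7.1], rep(0, sum(tt > 7.1)), tolerance = 1e-6)
})

test_that("fit window lands on the analytic minimum between the two modes", {
  p <- aif_params()
  aif <- synthesize_aif(p)
  # analytic minimum of the two-Gaussian mixture between its modes
  mix <- function(t) {
    exp(-(t - p$time_to_peak)^2 / (2 * p$first_pass_sd^2)) +
      p$recirc_amplitude_fraction *
        exp(-(t - p$time_to_peak - p$recirc_delay)^2 / (2 * p$recirc_sd^2))
  }
  tmin <- stats::optimize(mix, c(p$time_to_peak,
                                 p$time_to_peak + p$recirc_delay))$minimum
  got <- detect_fit_window(aif)
  expect_lte(abs(aif$times[got] - tmin), aif$dt + 1e-9)
})

test_that("fit window falls back to the last sample without recirculation", {
  aif <- synthesize_aif(aif_params(recirc_amplitude_fraction = 0))
  expect_equal(detect_fit_window(aif), length(aif$times))
  flat <- perf_curve(seq(0, 7, 0.7), rep(1, 11))
  expect_error(detect_fit_window(flat), "flat")
})

test_that("fit window separates two constructed peaks", {
  tt <- seq(0, 59.5, 0.7)
  v <- dnorm(tt, 15, 3) + 0.4 * dnorm(tt, 35, 4)
  aif <- perf_curve(tt, v)
  got <- detect_fit_window(aif)
  ipk1 <- which.max(v)
  ipk2 <- which(abs(tt - 35) < 0.35)
  expect_gt(got, ipk1)
  expect_lt(got, ipk2)
  expect_equal(tt[got], tt[ipk1 - 1 + which.min(v[ipk1:ipk2])])
})

test_that("model convolution: linearity in A and Fourier = direct time domain", {
  # short curve so the O(N^2) direct reference stays cheap
  tm <- seq(0, by = 0.7, length.out = 30)
  aif <- perf_curve(tm, dnorm(tm, 6, 2) * 5e-3)
  n <- length(tm)
  direct <- function(pars, variant) {
    os <- 20
    tf <- seq(0, tm[n], by = aif$dt / os)
    caf <- approx(tm, aif$values, xout = tf)$y
    rf <- fermi_residue(tf, pars$A, pars$k, pars$tau0,
                        if (is.null(pars$tau_d)) 0 else pars$tau_d, variant)
    full <- numeric(length(caf))
    for (i in seq_along(caf)) {
      j <- seq_len(i)
      full[i] <- sum(caf[j] * rf[i - j + 1]) * aif$dt / os
    }
    full[1 + os * (seq_len(n) - 1)] / 60
  }
  pars <- list(A = 1.7, k = 0.25, tau0 = 6, tau_d = 1.4)
  fft_ver <- convolve_model(aif, pars, "fermi_delta")
  dir_ver <- direct(pars, "fermi_delta")
  expect_lt(max(abs(fft_ver - dir_ver)), 1e-10 * max(abs(dir_ver)))

  # linearity: doubling A doubles the model exactly
  pars2 <- pars; pars2$A <- 2 * pars$A
  expect_equal(convolve_model(aif, pars2, "fermi_delta"), 2 * fft_ver,
               tolerance = 1e-12)

  # a near-impulse unit-mass residue reproduces the AIF (scaled by 1/60)
  # only the t = 0 fine-grid sample falls inside the shoulder, so the
  # discrete kernel mass is A * (dt/20)
  imp <- list(A = 1 / 0.035, k = 400, tau0 = 0.035 / 2)
  model <- convolve_model(aif, imp, "fermi")
  expect_lt(max(abs(model - aif$values / 60)) / max(aif$values / 60), 0.02)
})

test_that("parameter recovery on self-generated noiseless data within 1%", {
  aif <- default_aif()
  true_pars <- list(A = 2, k = 0.1, tau0 = 8, tau_d = 2.8)
  ct <- perf_curve(aif$times, convolve_model(aif, true_pars, "fermi_delta"))
  fit <- fermi_fit(ct, aif, "fermi_delta")
  true_mbf <- max(fermi_residue(seq(0, 59, 0.01), true_pars$A, true_pars$k,
                                true_pars$tau0, true_pars$tau_d,
                                "fermi_delta"))
  expect_lt(abs(fit$mbf - true_mbf) / true_mbf, 0.01)
  expect_true(fit$converged)
  # delay recovered within one sample
  expect_lt(abs(fit$params[["tau_d"]] - 2.8), 0.7 + 1e-9)
})

test_that("MBF is scale-equivariant on noiseless curves", {
  aif <- default_aif()
  ct <- generate_tissue_curve(aif, kinetic_params(2, 0.07),
                              time_dilation = 60)
  f1 <- fermi_fit(ct, aif, "fermi")
  f3 <- fermi_fit(perf_curve(ct$times, 3 * ct$values), aif, "fermi")
  expect_equal(f3$mbf / f1$mbf, 3, tolerance = 1e-4)
})

test_that("unmodelled delay causes underestimation; tau_d repairs it", {
  aif <- default_aif()
  ct0 <- generate_tissue_curve(aif, kinetic_params(2, 0.07),
                               time_dilation = 60)
  ct28 <- generate_tissue_curve(aif, kinetic_params(2, 0.07), delay = 2.8,
                                time_dilation = 60)
  m0 <- fermi_fit(ct0, aif, "fermi")$mbf
  m28 <- fermi_fit(ct28, aif, "fermi")$mbf
  expect_lt(m28, m0)
  fd <- fermi_fit(ct28, aif, "fermi_delta")
  expect_lt(abs(fd$params[["tau_d"]] - 2.8), 0.7 + 1e-9)
  expect_gt(fd$mbf, m28)
})

test_that("all-zero tissue yields an A = 0 fit, not an error", {
  aif <- default_aif()
  z <- perf_curve(aif$times, numeric(length(aif$times)))
  fit <- fermi_fit(z, aif, "fermi")
  expect_equal(fit$mbf, 0)
  expect_true(fit$converged)
})

test_that("Fermi-delta slope against truth is near unity on the zero-delay
          phantom and declines strictly with unmodelled delay", {
  slopes <- sapply(c(0, 1.4, 2.8), function(d) {
    ph <- mini_phantom(delay = d, nreal = 1, seed = 21)
    Y <- phantom_curves(ph)
    we <- detect_fit_window(ph$aif)
    est <- sapply(seq_len(nrow(Y)), function(i)
      fermi_fit(perf_curve(ph$aif$times, Y[i, ]), ph$aif, "fermi",
                window_end = we)$mbf)
    estd <- sapply(seq_len(nrow(Y)), function(i)
      fermi_fit(perf_curve(ph$aif$times, Y[i, ]), ph$aif, "fermi_delta",
                window_end = we)$mbf)
    c(fermi = regression_stats(est, phantom_truth(ph))$slope,
      delta = regression_stats(estd, phantom_truth(ph))$slope)
  })
  expect_gt(slopes["delta", 1], 0.9)
  expect_lt(slopes["delta", 1], 1.1)
  expect_true(all(diff(slopes["fermi", ]) < 0))
})

test_that("fit export row carries the method and window metadata", {
  aif <- default_aif()
  ct <- generate_tissue_curve(aif, kinetic_params(1.5, 0.06),
                              time_dilation = 60)
  row <- fermi_fit_row(fermi_fit(ct, aif, "fermi_delta"))
  expect_named(row, c("method", "mbf", "tau_d", "A", "k", "tau0", "sse",
                      "converged", "window_end_s"))
  expect_equal(row$method, "fermi_delta")
  expect_false(is.na(row$tau_d))
})
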