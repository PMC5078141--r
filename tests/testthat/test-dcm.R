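test_that("haemodynamic transfer kernel is low-pass and region-symmetric", {
  hemo <- default_hemo()
  K <- hemo_transfer(hemo, c(0.01, 10), n_regions = 2)
  expect_lt(Mod(K[2, 1]), 0.01 * Mod(K[1, 1]))
  expect_equal(K[, 1], K[, 2])
  bad <- hemo; bad$kappa <- -1
  expect_error(hemo_transfer(bad, 0.05, 1), "unstable hemodynamics")
})

test_that("linearised kernel gain matches a nonlinear impulse response", {
  hemo <- default_hemo()
  # independent oracle: Euler-integrate the nonlinear cascade driven by a
  # small neural impulse and transform the response
  dt <- 0.01; Tend <- 512; nt <- Tend / dt
  a <- 1e-3                     # impulse amplitude (one bin, integral a*dt)
  s <- 0; f <- 1; v <- 1; q <- 1
  y <- numeric(nt)
  k1 <- 7 * hemo$E0; k2 <- 2; k3 <- 2 * hemo$E0 - 0.2
  for (t in seq_len(nt)) {
    x <- if (t == 1) a else 0
    y[t] <- hemo$V0 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
    ds <- x / dt - hemo$kappa * s - hemo$gamma * (f - 1)
    df <- s
    dv <- (f - v^(1 / hemo$alpha)) / hemo$tau
    dq <- (f * (1 - (1 - hemo$E0)^(1 / f)) / hemo$E0 -
             v^(1 / hemo$alpha) * q / v) / hemo$tau
    s <- s + dt * ds; f <- f + dt * df; v <- v + dt * dv; q <- q + dt * dq
  }
  fgrid <- (1:40) / Tend                       # 0.002 .. 0.078 Hz
  gain_sim <- vapply(fgrid, function(fr)
    Mod(sum(y * exp(-2i * pi * fr * (seq_len(nt) - 1) * dt)) * dt) / a, 0)
  gain_lin <- Mod(hemo_transfer(hemo, fgrid, 1)[, 1])
  expect_lt(max(abs(gain_sim - gain_lin) / gain_lin), 0.1)
})

test_that("predicted cross spectra cover the documented special cases", {
  freqs <- c(0.01, 0.05, 0.1)
  # no endogenous fluctuations: spectrum reduces to diagonal noise
  p0 <- chain2_params(a21 = 0.4, amp_v = 0, amp_e = 2e-4)
  S0 <- predicted_csd(p0, freqs)
  for (k in 1:3) {
    expect_equal(Mod(S0$S[1, 2, k]), 0)
    expect_equal(Re(S0$S[1, 1, k]), 2e-4 * freqs[k]^(-1))
  }
  # disconnected identical regions: diagonal with equal entries
  pd <- dcm_params(diag(-0.5, 3), amp_v = 1e-4)
  Sd <- predicted_csd(pd, freqs)
  for (k in 1:3) {
    expect_equal(Re(Sd$S[1, 1, k]), Re(Sd$S[2, 2, k]))
    expect_equal(Mod(Sd$S[1, 2, k]), 0)
  }
  expect_error(predicted_csd(pd, c(0, 0.1)), "f = 0")
  expect_hermitian_psd(predicted_csd(chain2_params(), freqs))
})

test_that("2-node chain coherence matches the explicit scalar algebra", {
  a21 <- 0.3; self <- -0.4
  p <- chain2_params(a21 = a21, self = self, amp_v = 1e-4, exp_v = 1,
                     amp_e = 1e-6, exp_e = 1)
  freqs <- c(0.02, 0.05, 0.09)
  S <- predicted_csd(p, freqs)
  hemo <- default_hemo()
  K <- hemo_transfer(hemo, freqs, 1)[, 1]
  for (k in seq_along(freqs)) {
    w <- 2i * pi * freqs[k]
    gv <- 1e-4 * freqs[k]^(-1); ge <- 1e-6 * freqs[k]^(-1)
    # explicit inverse of the lower-triangular 2x2 (i w I - A)
    t11 <- K[k] / (w - self)
    t21 <- K[k] * a21 / ((w - self)^2)
    t22 <- K[k] / (w - self)
    s11 <- gv * Mod(t11)^2 + ge
    s21 <- gv * t21 * Conj(t11)
    s22 <- gv * (Mod(t21)^2 + Mod(t22)^2) + ge
    expect_lt(Mod(S$S[1, 1, k] - s11), 1e-10)
    expect_lt(Mod(S$S[2, 1, k] - s21), 1e-10)
    expect_lt(Mod(S$S[2, 2, k] - s22), 1e-10)
    coh <- Mod(s21)^2 / (Re(s11) * Re(s22))
    coh_pkg <- Mod(S$S[2, 1, k])^2 / (Re(S$S[1, 1, k]) * Re(S$S[2, 2, k]))
    expect_equal(coh_pkg, coh, tolerance = 1e-10)
  }
})

test_that("masked couplings are absent from the parameter vector", {
  spec <- tiny_spec(c("R1", "R2", "R3"), list(c("R1", "R2")))
  pr <- spdcm_priors(spec)
  expect_length(pr$idx$a, 1)
  expect_equal(pr$names[pr$idx$a], "R1->R2")
  expect_length(pr$pE, 1 + 3 + 3 + 4)
  # all prior variances strictly positive (masked entries removed, not
  # shrunk to zero variance)
  expect_true(all(pr$pV > 0))
})

test_that("objective reduces to its analytic form on exact data", {
  spec <- tiny_spec(c("R1", "R2"), list(c("R1", "R2")))
  pr <- spdcm_priors(spec)
  freqs <- default_freq_grid(500, 2)
  g <- restdcm:::predict_stacked(pr$pE, spec, pr, freqs)
  n <- 2
  up <- restdcm:::unpack_theta(pr$pE, spec, pr)
  S <- restdcm:::csd_predict_cpp(up$A, up$tau, pr$hemo$kappa, pr$hemo$gamma,
                                 pr$hemo$alpha, pr$hemo$E0, pr$hemo$V0,
                                 up$ampv, up$expv, up$ampe, up$expe, freqs)
  data <- cross_spectra(freqs, S, regions = spec$regions, source = "model")
  for (lambda in c(2, 10)) {
    ne <- length(g)
    expected <- 0.5 * ne * lambda - 0.5 * ne * log(2 * pi) +
      sum(dnorm(pr$pE, pr$pE, sqrt(pr$pV), log = TRUE)) +
      dnorm(lambda, pr$lambda0, sqrt(pr$lambda_v), log = TRUE)
    expect_equal(spdcm_objective(pr$pE, lambda, data, spec, pr), expected)
  }
  # unstable coupling gives the -Inf sentinel (reciprocal excitation
  # exceeding the self-inhibition destabilises the pair)
  spec2 <- tiny_spec(c("R1", "R2"), list(c("R1", "R2"), c("R2", "R1")))
  pr2 <- spdcm_priors(spec2)
  up2 <- restdcm:::unpack_theta(pr2$pE, spec2, pr2)
  S2 <- restdcm:::csd_predict_cpp(up2$A, up2$tau, pr2$hemo$kappa,
                                  pr2$hemo$gamma, pr2$hemo$alpha,
                                  pr2$hemo$E0, pr2$hemo$V0, up2$ampv,
                                  up2$expv, up2$ampe, up2$expe, freqs)
  data2 <- cross_spectra(freqs, S2, regions = spec2$regions, source = "model")
  th_bad <- pr2$pE
  th_bad[pr2$idx$a] <- 3
  expect_identical(spdcm_objective(th_bad, 4, data2, spec2, pr2), -Inf)
})

test_that("analytic-plus-FD gradient matches finite differences of the objective", {
  spec <- tiny_spec(c("R1", "R2"), list(c("R1", "R2"), c("R2", "R1")))
  set.seed(8)
  tru <- random_couplings(spec, seed = 8)
  ts <- simulate_bold(tru, sim_config(n_scans = 400, seed = 9))
  freqs <- default_freq_grid(400, 2)
  data <- csd_from_mar(fit_mar(residualize(ts), 8), freqs)
  # evaluate around a mildly perturbed point in the scaled-data units the
  # inversion uses
  fit <- spdcm_invert(data, spec, opts = list(max_iter = 2))
  pr <- fit$priors
  theta <- pr$pE + rnorm(length(pr$pE), 0, 0.02)
  lambda <- 3
  gr <- spdcm_gradient(theta, lambda, fit$data_scaled, spec, pr)
  h <- 1e-5
  fd <- vapply(seq_along(theta), function(j) {
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    (spdcm_objective(tp, lambda, fit$data_scaled, spec, pr) -
       spdcm_objective(tm, lambda, fit$data_scaled, spec, pr)) / (2 * h)
  }, 0)
  expect_lt(max(abs(gr - fd)) / max(abs(fd)), 1e-4)
})

test_that("inversion recovers a null model and zeroes masked couplings", {
  spec <- tiny_spec(c("R1", "R2"))        # no off-diagonal connections
  tru <- dcm_params(diag(c(-0.4, -0.6)), regions = c("R1", "R2"))
  ts <- simulate_bold(tru, sim_config(n_scans = 800, seed = 15))
  freqs <- default_freq_grid(800, 2)
  data <- csd_from_mar(fit_mar(residualize(ts), 12), freqs)
  fit <- spdcm_invert(data, spec)
  off <- fit$A[upper.tri(fit$A) | lower.tri(fit$A)]
  expect_identical(unname(off), c(0, 0))
  # self-connections close to truth in Hz and within 3 posterior SD on the
  # log scale (Laplace SDs are mildly optimistic under correlated spectral
  # residuals)
  expect_lt(max(abs(diag(fit$A) - c(-0.4, -0.6))), 0.1)
  sd_self <- sqrt(diag(fit$Sigma))[fit$priors$idx$self]
  # a_ii = -0.5 exp(theta) => theta_true = log(-2 a_ii)
  th_true <- log(c(0.4, 0.6) / 0.5)
  th_est <- fit$theta[fit$priors$idx$self]
  expect_true(all(abs(th_est - th_true) < 3 * sd_self + 1e-8))
  expect_false(is.unsorted(fit$trace))
})

test_that("variational optimum matches an exhaustive 1-D grid search", {
  spec <- tiny_spec(c("R1", "R2"), list(c("R1", "R2")))
  tru <- chain2_params(a21 = 0.25)
  ts <- simulate_bold(tru, sim_config(n_scans = 1000, seed = 16))
  freqs <- default_freq_grid(1000, 2)
  data <- csd_from_mar(fit_mar(residualize(ts), 12), freqs)
  fit <- spdcm_invert(data, spec)
  ia <- fit$priors$idx$a
  grid <- seq(-1, 1, by = 0.001)
  obj <- vapply(grid, function(a) {
    th <- fit$theta; th[ia] <- a
    spdcm_objective(th, fit$lambda, fit$data_scaled, spec, fit$priors)
  }, 0)
  a_grid <- grid[which.max(obj)]
  expect_lt(abs(a_grid - fit$theta[ia]), 0.01)
  expect_false(is.unsorted(fit$trace))
})

test_that("model evidence discriminates a sparse truth from a null mask", {
  regions <- c("R1", "R2", "R3")
  spec_true <- tiny_spec(regions, list(c("R1", "R2"), c("R2", "R3")))
  spec_null <- tiny_spec(regions)
  wins <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    tru <- random_couplings(spec_true, seed = 300 + r,
                            range = c(0.2, 0.3), p_negative = 0)
    ts <- simulate_bold(tru, sim_config(n_scans = 500, seed = 400 + r))
    freqs <- default_freq_grid(500, 2)
    data <- csd_from_mar(fit_mar(residualize(ts), 12), freqs)
    ft <- spdcm_invert(data, spec_true, opts = list(max_iter = 24))
    fn <- spdcm_invert(data, spec_null, opts = list(max_iter = 24))
    wins <- wins + (ft$F > fn$F)
    expect_false(is.unsorted(ft$trace))
    expect_false(is.unsorted(fn$trace))
  }
  expect_gte(wins, 0.9 * n_rep)
})

test_that("a redundant parameter never raises the free energy at equal fit", {
  # constructed case: data generated at the prior mean of the nested
  # (edgeless) model, so both models achieve zero residual at their
  # initialisation and differ only in complexity
  spec_n <- tiny_spec(c("R1", "R2"))
  spec_f <- tiny_spec(c("R1", "R2"), list(c("R1", "R2")))
  pr <- spdcm_priors(spec_n)
  freqs <- default_freq_grid(500, 2)
  up <- restdcm:::unpack_theta(pr$pE, spec_n, pr)
  S <- restdcm:::csd_predict_cpp(up$A, up$tau, pr$hemo$kappa, pr$hemo$gamma,
                                 pr$hemo$alpha, pr$hemo$E0, pr$hemo$V0,
                                 up$ampv, up$expv, up$ampe, up$expe, freqs)
  data <- cross_spectra(freqs, S, regions = c("R1", "R2"), source = "model")
  f_n <- spdcm_invert(data, spec_n, opts = list(max_iter = 0))
  f_f <- spdcm_invert(data, spec_f, opts = list(max_iter = 0))
  expect_length(f_n$trace, 1)
  expect_lte(f_f$F, f_n$F)
})

test_that("doubling the data length sharpens the coupling posterior", {
  spec <- tiny_spec(c("R1", "R2"), list(c("R1", "R2"), c("R2", "R1")))
  tru <- random_couplings(spec, seed = 30)
  sds <- vapply(c(1000, 2000), function(ns) {
    ts <- simulate_bold(tru, sim_config(n_scans = ns, seed = 31))
    freqs <- default_freq_grid(ns, 2)
    data <- csd_from_mar(fit_mar(residualize(ts), 12), freqs)
    fit <- spdcm_invert(data, spec)
    mean(sqrt(diag(fit$Sigma))[fit$priors$idx$a])
  }, 0)
  expect_lt(sds[2], sds[1])
})

test_that("evidence table bookkeeping records every subject-model pair", {
  spec <- tiny_spec(c("R1", "R2"), list(c("R1", "R2")))
  g <- quick_group(spec, n_subjects = 1, n_scans = 300, seed = 44)
  F <- model_evidence_table(g$csd, list(spec), opts = list(max_iter = 4))
  expect_equal(dim(F), c(1, 1))
  fit <- spdcm_invert(g$csd[[1]], spec, opts = list(max_iter = 4))
  expect_equal(F[1, 1], fit$F)
  # a failing model is recorded as NA with a warning, not an abort
  bad <- tiny_spec(c("X1", "X2"), list(c("X1", "X2")))
  expect_warning(F2 <- model_evidence_table(g$csd, list(spec, bad),
                                            opts = list(max_iter = 4)),
                 "failed")
  expect_equal(unname(F2[1, 1]), fit$F)
  expect_true(is.na(F2[1, 2]))
  # checkpoint resume reproduces the same matrix without recomputation
  ck <- tempfile(fileext = ".csv")
  suppressWarnings(model_evidence_table(g$csd, list(spec, bad),
                                        opts = list(max_iter = 4),
                                        checkpoint = ck))
  expect_true(file.exists(ck))
})
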