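# Shared fixtures: small systems and quick simulations used across tests.

# A minimal n-region model spec with the given directed edges
# (list of c(from, to) label pairs).
tiny_spec <- function(regions, edges = list(), name = "tiny") {
  n <- length(regions)
  mask <- matrix(0, n, n, dimnames = list(regions, regions))
  for (e in edges) mask[e[2], e[1]] <- 1
  model_spec(regions, mask, family = "t", pattern = "none", name = name)
}

# Two-region chain R1 -> R2 with known coupling.
chain2_params <- function(a21 = 0.25, self = -0.5, ...) {
  A <- matrix(c(self, a21, 0, self), 2, 2)
  dcm_params(A, regions = c("R1", "R2"), ...)
}

# Quick simulated group: returns list(spec, base, truths, ts, csd, freqs).
quick_group <- function(spec, n_subjects = 2, n_scans = 400, seed = 1,
                        subject_sd = 0.05, mar_p = 8, ...) {
  base <- random_couplings(spec, seed = seed, ...)
  cfg <- sim_config(n_scans = n_scans, seed = seed + 1000,
                    subject_sd = subject_sd)
  truths <- make_group_truth(spec, base, cfg, n_subjects)
  freqs <- default_freq_grid(n_scans, cfg$tr)
  ts <- list(); csd <- list()
  for (s in seq_len(n_subjects)) {
    scfg <- cfg
    scfg$seed <- cfg$seed + s
    ts[[s]] <- simulate_bold(truths[[s]], scfg)
    csd[[s]] <- csd_from_mar(fit_mar(residualize(ts[[s]]), mar_p), freqs)
  }
  list(spec = spec, base = base, truths = truths, ts = ts, csd = csd,
       freqs = freqs, cfg = cfg)
}

expect_hermitian_psd <- function(cs, tol = 1e-10) {
  for (k in seq_along(cs$freqs)) {
    Sk <- cs$S[, , k]
    expect_lt(max(abs(Sk - Conj(t(Sk)))), 1e-8 * max(1, max(abs(Sk))))
    ev <- eigen(Sk, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -tol * max(1, max(abs(ev))))
  }
}

# Frobenius norm for complex matrices (base norm() warns on complex input).
frob <- function(M) sqrt(sum(Mod(M)^2))
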