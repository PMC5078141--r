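# Forward simulation: power-law endogenous fluctuations drive a linear
# neural coupling system dx/dt = A x + v(t); the neural states pass through
# the nonlinear balloon haemodynamic cascade; the BOLD read-out is sampled at
# TR and corrupted by power-law observation noise.

# Synthesise a zero-mean real signal of length n with two-sided power
# spectral density amp * |f|^(-expn) (the same spectral convention as the
# cross-spectral estimators: variance = integral of the PSD over
# [-Nyquist, Nyquist]). Frequency-domain synthesis with uniform random
# phases; the DC bin is zero.
powerlaw_noise <- function(n, fs, amp, expn) {
  if (amp == 0) return(numeric(n))
  X <- complex(real = numeric(n), imaginary = numeric(n))
  m <- floor((n - 1) / 2)
  f <- (1:m) * fs / n
  mag <- sqrt(amp * f^(-expn) * fs * n)
  phi <- runif(m, 0, 2 * pi)
  X[2:(m + 1)] <- mag * exp(1i * phi)
  X[n:(n - m + 1)] <- Conj(X[2:(m + 1)])
  if (n %% 2 == 0) {
    fn <- fs / 2
    X[n / 2 + 1] <- sqrt(amp * fn^(-expn) * fs * n) * sign(runif(1) - 0.5)
  }
  Re(fft(X, inverse = TRUE)) / n
}

#' Simulate ROI-level BOLD from a DCM ground truth
#'
#' Integrates the latent dynamics `dx/dt = A x + v(t)` (Euler at `cfg$dt`,
#' `v` power-law endogenous fluctuations synthesised in the frequency
#' domain), passes each region's neural state through the nonlinear balloon
#' haemodynamic cascade, discards the burn-in, samples the BOLD read-out at
#' TR and adds power-law observation noise. The returned signal is
#' `baseline * (1 + y + e)` in arbitrary raw units, so the time-series
#' mean/SD ratio behaves like the signal-to-noise ratio of raw BOLD.
#'
#' @param params a [dcm_params] ground truth.
#' @param cfg a [sim_config].
#' @param mni optional MNI coordinate matrix passed to the result.
#' @param return_latent attach the sampled latent neural states as
#'   attribute `"latent"`.
#' @return an [roi_ts] object (`cfg$n_scans` x n regions).
#' @export
simulate_bold <- function(params, cfg, mni = NULL, return_latent = FALSE) {
  stopifnot(inherits(params, "dcm_params"), inherits(cfg, "sim_config"))
  n <- length(params$regions)
  steps_tr <- round(cfg$tr / cfg$dt)
  n_t <- round(cfg$burn_in / cfg$dt) + steps_tr * cfg$n_scans
  set.seed(cfg$seed)
  v <- vapply(seq_len(n), function(r)
    powerlaw_noise(n_t, 1 / cfg$dt, params$amp_v[r], params$exp_v[r]),
    numeric(n_t))
  h <- params$hemo
  sim <- balloon_sim_cpp(params$A, v, cfg$dt, h$tau, h$kappa, h$gamma,
                         h$alpha, h$E0, h$V0)
  idx <- round(cfg$burn_in / cfg$dt) + 1 + (seq_len(cfg$n_scans) - 1) * steps_tr
  y <- sim$y[idx, , drop = FALSE]
  e <- vapply(seq_len(n), function(r)
    powerlaw_noise(cfg$n_scans, 1 / cfg$tr, params$amp_e[r], params$exp_e[r]),
    numeric(cfg$n_scans))
  out <- roi_ts(cfg$baseline * (1 + y + e), tr = cfg$tr,
                regions = params$regions, mni = mni)
  if (return_latent) attr(out, "latent") <- sim$x[idx, , drop = FALSE]
  out
}

#' Draw a group of subject-level ground-truth parameter sets
#'
#' Each subject's coupling matrix is the base matrix plus independent
#' Gaussian jitter (SD `cfg$subject_sd`, Hz) on the connections allowed by
#' the model mask; masked connections stay exactly zero. Unstable draws are
#' rejected and redrawn (up to 100 times per subject). Deterministic given
#' `cfg$seed`.
#'
#' @param spec the [model_spec] defining the allowed connections.
#' @param base a [dcm_params] whose `A` respects `spec$mask`.
#' @param cfg a [sim_config] (uses `seed` and `subject_sd`).
#' @param n_subjects group size.
#' @return list of `n_subjects` [dcm_params] objects.
#' @export
make_group_truth <- function(spec, base, cfg, n_subjects) {
  stopifnot(inherits(spec, "model_spec"), inherits(base, "dcm_params"))
  off <- !diag(length(spec$regions))
  if (any(base$A[off & spec$mask == 0] != 0))
    stop("base couplings must be zero where the model mask is zero")
  free <- which(spec$mask == 1)
  set.seed(cfg$seed)
  lapply(seq_len(n_subjects), function(s) {
    for (try in 1:100) {
      A <- base$A
      A[free] <- A[free] + rnorm(length(free), 0, cfg$subject_sd)
      if (max(Re(eigen(A, only.values = TRUE)$values)) < -1e-6) {
        p <- base
        p$A <- A
        return(p)
      }
    }
    stop("no stable coupling matrix for subject ", s, " after 100 redraws")
  })
}

#' Simulate voxel time series within one ROI
#'
#' Each voxel is `(1 + N(0, loading_sd)) * region series + white noise`
#' with noise SD equal to `noise_sd` times the series SD. Provides test
#' input for principal-eigenvariate extraction.
#'
#' @param ts an [roi_ts].
#' @param region region label present in `ts`.
#' @param n_voxels number of voxels (>= 1).
#' @param loading_sd SD of the multiplicative voxel loadings.
#' @param noise_sd white-noise SD as a fraction of the series SD.
#' @param seed integer seed.
#' @return numeric matrix, scans x voxels.
#' @export
simulate_voxels <- function(ts, region, n_voxels, loading_sd = 0.1,
                            noise_sd = 0.3, seed = 1) {
  stopifnot(inherits(ts, "roi_ts"))
  if (n_voxels < 1) stop("n_voxels must be >= 1")
  if (!region %in% ts$regions) stop("region ", region, " not present")
  u <- ts$data[, region]
  set.seed(seed)
  load <- 1 + rnorm(n_voxels, 0, loading_sd)
  vox <- outer(u, load)
  if (noise_sd > 0)
    vox <- vox + matrix(rnorm(length(vox), 0, noise_sd * sd(u)), nrow(vox))
  vox
}
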