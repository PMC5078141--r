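# Data features consumed by the spectral DCM engine: discrete cosine bases,
# principal eigenvariates, confound residualisation, and cross-spectral
# density estimates (multivariate autoregressive and Welch).
#
# Spectral convention used throughout the package: S(f) is the two-sided
# spectral density of the TR-sampled process, so that the process covariance
# equals the integral of S over (-Nyquist, Nyquist].

#' Cross-spectral density container
#'
#' @param freqs strictly increasing frequency grid, Hz, in (0, Nyquist].
#' @param S complex array, regions x regions x frequencies; Hermitian and
#'   positive semi-definite at every frequency (checked to 1e-10).
#' @param regions region labels.
#' @param source one of `"mar"`, `"welch"`, `"model"`.
#' @param check verify Hermitian/PSD invariants (default TRUE).
#' @return object of class `cross_spectra`.
#' @export
cross_spectra <- function(freqs, S, regions = NULL,
                          source = c("mar", "welch", "model"),
                          check = TRUE) {
  source <- match.arg(source)
  stopifnot(is.array(S), length(dim(S)) == 3, dim(S)[1] == dim(S)[2],
            dim(S)[3] == length(freqs))
  if (any(freqs <= 0)) stop("frequency grid must be strictly positive")
  if (is.unsorted(freqs, strictly = TRUE)) stop("freqs must be strictly increasing")
  n <- dim(S)[1]
  if (is.null(regions)) regions <- paste0("R", seq_len(n))
  if (check) {
    for (k in seq_along(freqs)) {
      Sk <- S[, , k]
      if (max(abs(Sk - Conj(t(Sk)))) > 1e-8 * max(1, max(abs(Sk))))
        stop("S not Hermitian at f = ", freqs[k])
      ev <- eigen(Sk, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-10 * max(1, max(abs(ev))))
        stop("S not positive semi-definite at f = ", freqs[k])
    }
  }
  dimnames(S) <- list(regions, regions, NULL)
  structure(list(freqs = freqs, S = S, regions = regions, source = source),
            class = "cross_spectra")
}

#' @export
print.cross_spectra <- function(x, ...) {
  cat("cross spectra (", x$source, "): ", length(x$regions), " regions x ",
      length(x$freqs), " frequencies in [",
      signif(min(x$freqs), 3), ", ", signif(max(x$freqs), 3), "] Hz\n", sep = "")
  invisible(x)
}

#' Default analysis frequency grid
#'
#' Logarithmically spaced points over the canonical resting-state band
#' 0.0078-0.1 Hz. Below this band the cross-spectral features of a
#' 1000-scan acquisition are dominated by estimator extrapolation (the MAR
#' spectrum below ~1/128 Hz is unconstrained by the data), which badly
#' distorts the inversion, so the band edge doubles as the grid floor.
#'
#' @param n_scans,tr acquisition length and repetition time (s); the grid
#'   floor is raised to the fundamental frequency 1/(n_scans tr) if that is
#'   higher than `f_min`.
#' @param f_min,f_max band edges, Hz.
#' @param n_freq number of grid points.
#' @return numeric vector of frequencies, Hz.
#' @export
default_freq_grid <- function(n_scans, tr, f_min = 0.0078, f_max = 0.1,
                              n_freq = 12) {
  f0 <- max(f_min, 1 / (n_scans * tr))
  stopifnot(f_max > f0, f_max <= 1 / (2 * tr))
  exp(seq(log(f0), log(f_max), length.out = n_freq))
}

#' Discrete cosine basis over the resting-state band
#'
#' Column k (k = 1..K) is the unit-norm discrete cosine
#' `cos(pi * k * (t + 1/2) / N)` over scans t = 0..N-1, with assigned
#' frequency `k / (2 N tr)`; K = `floor(2 N tr f_max)`. The constant term is
#' excluded. For 1000 scans at TR 2 s and f_max = 0.1 Hz this gives 400
#' functions.
#'
#' @param n_scans number of scans N (>= 2).
#' @param tr repetition time, s.
#' @param f_max maximum frequency, Hz; must not exceed Nyquist.
#' @return list with `columns` (N x K orthonormal matrix) and `freqs` (Hz).
#' @export
dct_basis <- function(n_scans, tr, f_max) {
  stopifnot(n_scans >= 2, tr > 0, f_max > 0)
  if (f_max > 1 / (2 * tr)) stop("f_max exceeds the Nyquist frequency 1/(2 tr)")
  K <- floor(2 * n_scans * tr * f_max)
  t <- seq_len(n_scans) - 1
  cols <- vapply(seq_len(K), function(k)
    cos(pi * k * (t + 0.5) / n_scans), numeric(n_scans))
  cols <- matrix(cols, nrow = n_scans, ncol = K)
  if (K > 0) cols <- sweep(cols, 2, sqrt(colSums(cols^2)), "/")
  list(columns = cols, freqs = seq_len(K) / (2 * n_scans * tr))
}

#' Principal eigenvariate of a voxel matrix
#'
#' First left singular vector of the column-centred voxel matrix, scaled by
#' its singular value divided by sqrt(number of voxels), with the sign
#' chosen so the result correlates non-negatively with the voxel-mean
#' series. This is the standard summary time series of an ROI sphere.
#'
#' @param voxels numeric matrix, scans x voxels (>= 2 of each).
#' @return numeric vector of length `nrow(voxels)`.
#' @export
principal_eigenvariate <- function(voxels) {
  voxels <- as.matrix(voxels)
  if (nrow(voxels) < 2 || ncol(voxels) < 2)
    stop("need at least 2 scans and 2 voxels")
  vc <- scale(voxels, center = TRUE, scale = FALSE)
  if (max(abs(vc)) == 0) stop("degenerate region: voxel matrix has no variance")
  sv <- svd(vc, nu = 1, nv = 0)
  u <- sv$u[, 1] * sv$d[1] / sqrt(ncol(voxels))
  m <- rowMeans(vc)
  if (sd(m) > 0 && cor(u, m) < 0) u <- -u
  u
}

#' Residualise ROI series against confounds
#'
#' Replaces each region series by its least-squares residual against an
#' intercept plus the supplied confound regressors (e.g. head-motion
#' parameters or low-frequency drift terms from [dct_basis()]). With no
#' confounds this simply removes column means.
#'
#' @param ts an [roi_ts].
#' @param confounds numeric matrix with one row per scan, or NULL.
#' @return an [roi_ts] of residuals.
#' @export
residualize <- function(ts, confounds = NULL) {
  stopifnot(inherits(ts, "roi_ts"))
  n <- nrow(ts$data)
  X <- matrix(1, n, 1)
  if (!is.null(confounds) && NCOL(confounds) > 0) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n) stop("confound rows must match the number of scans")
    X <- cbind(X, confounds)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- setdiff(seq_len(ncol(X)), qx$pivot[seq_len(qx$rank)])
    stop("rank-deficient confounds; collinear column(s): ",
         paste(bad - 1L, collapse = ", "))
  }
  res <- qr.resid(qx, ts$data)
  roi_ts(res, tr = ts$tr, regions = ts$regions, mni = ts$mni)
}

#' Fit a multivariate autoregressive model by ordinary least squares
#'
#' Centres the series and fits `y_t = sum_k A_k y_(t-k) + e_t` by OLS; the
#' innovation covariance uses denominator `n_scans - p`. The companion
#' matrix's spectral radius determines the `stable` flag.
#'
#' @param ts an [roi_ts].
#' @param p model order (default 8).
#' @return object of class `mar_model` with fields `p`, `coeff` (list of
#'   n x n matrices), `innovation`, `stable`, `tr`, `regions`.
#' @export
fit_mar <- function(ts, p = 8) {
  stopifnot(inherits(ts, "roi_ts"), p >= 1)
  Y <- scale(ts$data, center = TRUE, scale = FALSE)
  n <- ncol(Y); N <- nrow(Y)
  if (N <= p * n + 1) stop("need n_scans > p * n_regions + 1")
  yt <- Y[(p + 1):N, , drop = FALSE]
  X <- do.call(cbind, lapply(seq_len(p), function(k)
    Y[(p + 1 - k):(N - k), , drop = FALSE]))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("singular MAR design matrix")
  B <- qr.coef(qx, yt)                       # (n p) x n
  resid <- yt - X %*% B
  coeff <- lapply(seq_len(p), function(k)
    t(B[((k - 1) * n + 1):(k * n), , drop = FALSE]))
  comp <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) comp[1:n, ((k - 1) * n + 1):(k * n)] <- coeff[[k]]
  if (p > 1) comp[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
  structure(list(p = p, coeff = coeff,
                 innovation = crossprod(resid) / (N - p),
                 stable = rho < 1, spectral_radius = rho,
                 tr = ts$tr, regions = ts$regions),
            class = "mar_model")
}

#' Parametric cross-spectral density of a fitted MAR model
#'
#' `S(f) = tr * H(f) Sigma H(f)^H` with
#' `H(f) = (I - sum_k A_k exp(-i 2 pi f k tr))^(-1)`.
#'
#' @param mar a [fit_mar()] result (must be stable).
#' @param freqs frequency grid, Hz.
#' @param tr repetition time; defaults to the one stored in `mar`.
#' @return a [cross_spectra] with `source = "mar"`.
#' @export
csd_from_mar <- function(mar, freqs, tr = mar$tr) {
  stopifnot(inherits(mar, "mar_model"))
  if (!mar$stable) stop("MAR fit is unstable (spectral radius ",
                        signif(mar$spectral_radius, 4), ")")
  n <- nrow(mar$innovation)
  S <- array(complex(real = 0), c(n, n, length(freqs)))
  I <- diag(n)
  for (j in seq_along(freqs)) {
    f <- freqs[j]
    Af <- I
    for (k in seq_len(mar$p))
      Af <- Af - mar$coeff[[k]] * exp(-2i * pi * f * k * tr)
    if (kappa_cplx(Af) > 1e12)
      stop("transfer matrix ill-conditioned at f = ", f)
    H <- solve(Af)
    Sk <- tr * H %*% mar$innovation %*% Conj(t(H))
    S[, , j] <- (Sk + Conj(t(Sk))) / 2
  }
  cross_spectra(freqs, S, regions = mar$regions, source = "mar")
}

# 2-norm condition estimate for a complex matrix via singular values.
kappa_cplx <- function(M) {
  d <- svd(M, nu = 0, nv = 0)$d
  if (min(d) == 0) Inf else max(d) / min(d)
}

#' Welch cross-spectral estimator
#'
#' Averaged Hann-tapered cross-periodograms over segments of length
#' `floor(n_scans / 8)` with 50% overlap, interpolated onto the requested
#' grid. Serves as a nonparametric cross-check of [csd_from_mar()].
#'
#' @param ts an [roi_ts].
#' @param freqs frequency grid, Hz; must lie within the resolvable band
#'   (first Welch bin to Nyquist).
#' @param seg_frac segment length as a fraction of the series (default 1/8).
#' @return a [cross_spectra] with `source = "welch"`.
#' @export
csd_welch <- function(ts, freqs, seg_frac = 1 / 8) {
  stopifnot(inherits(ts, "roi_ts"))
  N <- nrow(ts$data); n <- ncol(ts$data); tr <- ts$tr
  L <- floor(N * seg_frac)
  hop <- floor(L / 2)
  starts <- seq(1, N - L + 1, by = hop)
  if (length(starts) < 4) stop("fewer than 4 Welch segments available")
  if (min(freqs) < 1 / (L * tr) || max(freqs) > 1 / (2 * tr))
    stop("frequency grid outside the resolvable band [",
         signif(1 / (L * tr), 3), ", ", signif(1 / (2 * tr), 3), "] Hz")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))   # Hann taper
  U <- sum(w^2)
  nb <- floor(L / 2)
  fbins <- seq_len(nb) / (L * tr)
  acc <- array(complex(real = 0), c(n, n, nb))
  for (s in starts) {
    seg <- ts$data[s:(s + L - 1), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg)) * w
    X <- stats::mvfft(seg)[2:(nb + 1), , drop = FALSE]
    for (k in seq_len(nb))
      acc[, , k] <- acc[, , k] + outer(X[k, ], Conj(X[k, ]))
  }
  acc <- acc * tr / (U * length(starts))
  interp <- function(vals) {
    stats::approx(fbins, vals, xout = freqs, rule = 2)$y
  }
  S <- array(complex(real = 0), c(n, n, length(freqs)))
  for (i in seq_len(n)) for (j in seq_len(n))
    S[i, j, ] <- complex(real = interp(Re(acc[i, j, ])),
                         imaginary = interp(Im(acc[i, j, ])))
  cross_spectra(freqs, S, regions = ts$regions, source = "welch")
}

#' Per-region signal-to-noise ratio
#'
#' Mean divided by standard deviation of each region's raw time series, the
#' conventional SNR summary of resting-state acquisitions.
#'
#' @param ts an [roi_ts].
#' @return named numeric vector.
#' @export
roi_snr <- function(ts) {
  stopifnot(inherits(ts, "roi_ts"))
  sds <- apply(ts$data, 2, sd)
  if (any(sds == 0)) stop("zero-variance region: ",
                          paste(ts$regions[sds == 0], collapse = ", "))
  colMeans(ts$data) / sds
}
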