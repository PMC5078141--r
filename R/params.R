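#' Default-mode-network regions and MNI centre coordinates
#'
#' The six regions used throughout: medial prefrontal cortex (mPFC),
#' posterior cingulate cortex (PCC), left/right inferior parietal cortex
#' (LIPC/RIPC) and left/right parahippocampal gyrus (LHIP/RHIP), with the
#' MNI coordinates (mm) of the sphere centres from which principal
#' eigenvariates are taken.
#'
#' @param regions optional character vector selecting a subset (order kept).
#' @return data.frame with columns `region`, `x`, `y`, `z`.
#' @export
#' @examples
#' dmn_rois(c("mPFC", "PCC", "LIPC", "RIPC", "LHIP"))
dmn_rois <- function(regions = NULL) {
  tab <- data.frame(
    region = c("mPFC", "PCC", "LIPC", "RIPC", "LHIP", "RHIP"),
    x = c(3L, 0L, -50L, 48L, -22L, 19L),
    y = c(54L, -52L, -63L, -69L, -23L, -20L),
    z = c(-2L, 26L, 32L, 35L, -14L, -10L),
    stringsAsFactors = FALSE
  )
  if (is.null(regions)) return(tab)
  miss <- setdiff(regions, tab$region)
  if (length(miss)) stop("unknown region(s): ", paste(miss, collapse = ", "))
  tab[match(regions, tab$region), , drop = FALSE]
}

#' Default balloon-model haemodynamic constants
#'
#' Standard values: signal decay kappa = 0.64 1/s, autoregulatory feedback
#' gamma = 0.32 1/s, mean transit time tau = 2 s, Grubb exponent
#' alpha = 0.32, resting oxygen extraction E0 = 0.4, resting blood volume
#' fraction V0 = 0.04. The BOLD read-out coefficients are derived as
#' k1 = 7 E0, k2 = 2, k3 = 2 E0 - 0.2.
#'
#' @return named list of constants.
#' @export
default_hemo <- function() {
  list(kappa = 0.64, gamma = 0.32, tau = 2, alpha = 0.32, E0 = 0.4, V0 = 0.04)
}

#' DCM parameter set (simulation ground truth and inversion target)
#'
#' @param A square coupling matrix in Hz; `A[i, j]` is the influence of
#'   region j on region i; the diagonal (self-inhibition) must be strictly
#'   negative and the whole system stable (all eigenvalues with negative
#'   real part).
#' @param regions character labels, one per row of `A`.
#' @param hemo haemodynamic constants as from [default_hemo()]; `tau` may be
#'   a vector (one transit time per region).
#' @param amp_v,exp_v amplitude and power-law exponent of the endogenous
#'   neural fluctuation spectrum `amp_v * f^(-exp_v)`; scalar or per region.
#' @param amp_e,exp_e same for the observation-noise spectrum.
#' @return object of class `dcm_params`.
#' @export
dcm_params <- function(A, regions = NULL,
                       hemo = default_hemo(),
                       amp_v = 1e-5, exp_v = 1,
                       amp_e = 1.5e-6, exp_e = 1) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (ncol(A) != n) stop("A must be square")
  if (is.null(regions)) regions <- paste0("R", seq_len(n))
  if (length(regions) != n) stop("length(regions) must match nrow(A)")
  if (any(diag(A) >= 0)) stop("diagonal of A (self-inhibition) must be strictly negative")
  if (max(Re(eigen(A, only.values = TRUE)$values)) >= 0)
    stop("A is not stable: spectral abscissa >= 0")
  rec <- function(x, what, pos = TRUE) {
    x <- rep_len(x, n)
    if (pos && any(x < 0)) stop(what, " must be non-negative")
    x
  }
  hemo$tau <- rep_len(hemo$tau, n)
  stopifnot(hemo$kappa > 0, hemo$gamma > 0, all(hemo$tau > 0),
            hemo$alpha > 0, hemo$E0 > 0, hemo$E0 < 1, hemo$V0 > 0)
  dimnames(A) <- list(regions, regions)
  structure(list(
    A = A, regions = regions, hemo = hemo,
    amp_v = rec(amp_v, "amp_v"), exp_v = rep_len(exp_v, n),
    amp_e = rec(amp_e, "amp_e"), exp_e = rep_len(exp_e, n)
  ), class = "dcm_params")
}

#' @export
print.dcm_params <- function(x, ...) {
  cat("DCM parameters:", length(x$regions), "regions\n")
  cat("coupling matrix A (Hz), rows = to, cols = from:\n")
  print(round(x$A, 3))
  invisible(x)
}

#' Simulation configuration
#'
#' @param n_scans number of BOLD samples per region.
#' @param tr repetition time, seconds.
#' @param dt Euler integration step, seconds; must satisfy `dt <= tr/8`.
#' @param burn_in transient discarded before sampling, seconds (>= 32 s).
#' @param seed integer RNG seed.
#' @param subject_sd between-subject SD (Hz) of the free couplings.
#' @param baseline raw-signal baseline: output is `baseline * (1 + y + e)`,
#'   so the time-series mean/SD ratio mimics raw BOLD signal-to-noise.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_scans = 1000, tr = 2, dt = 0.125, burn_in = 64,
                       seed = 1, subject_sd = 0.05, baseline = 100) {
  stopifnot(n_scans >= 2, tr > 0, dt > 0, burn_in >= 32, baseline > 0)
  if (dt > tr / 8 + 1e-12) stop("dt must be <= tr/8")
  structure(list(n_scans = as.integer(n_scans), tr = tr, dt = dt,
                 burn_in = burn_in, seed = as.integer(seed),
                 subject_sd = subject_sd, baseline = baseline),
            class = "sim_config")
}

#' ROI time-series container
#'
#' @param data numeric matrix, scans x regions; no missing values.
#' @param tr repetition time, seconds.
#' @param regions unique region labels, one per column.
#' @param mni optional integer matrix (regions x 3) of MNI centres, mm.
#' @return object of class `roi_ts`.
#' @export
roi_ts <- function(data, tr, regions = colnames(data), mni = NULL) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("ROI time series must not contain missing values")
  if (is.null(regions)) regions <- paste0("R", seq_len(ncol(data)))
  if (anyDuplicated(regions)) stop("region labels must be unique")
  if (length(regions) != ncol(data)) stop("one label per column required")
  if (!is.null(mni)) {
    mni <- as.matrix(mni)
    if (nrow(mni) != ncol(data) || ncol(mni) != 3)
      stop("mni must be a (regions x 3) matrix")
  }
  colnames(data) <- regions
  structure(list(data = data, tr = tr, regions = regions, mni = mni),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat("ROI time series:", nrow(x$data), "scans x", ncol(x$data),
      "regions, TR =", x$tr, "s\n")
  invisible(x)
}

#' Reference coupling strengths for the DMN region set
#'
#' Group-mean effective-connectivity estimates (Hz) between the six
#' default-mode regions, as published for this network: the four core
#' regions with either hippocampal node included, the PCC-free reduced set,
#' and the inter-hippocampal link (0.44 Hz from LHIP to RHIP, none in the
#' opposite direction). Used as the default simulation ground truth so that
#' synthetic groups carry couplings on the empirically observed scale and
#' sign pattern.
#'
#' @param spec a [model_spec]; the region set selects the matching
#'   reference table, and couplings are zeroed wherever the mask is zero.
#' @param self self-inhibition, Hz.
#' @param ... further arguments passed to [dcm_params()].
#' @return a `dcm_params` whose `A` respects `spec$mask`.
#' @export
dmn_couplings <- function(spec, self = -0.5, ...) {
  stopifnot(inherits(spec, "model_spec"))
  edge <- function(to, from, val) data.frame(to = to, from = from, val = val)
  # five-node tables (columns: from), LHIP and RHIP variants
  tab_lhip <- rbind(
    edge("mPFC", c("PCC", "LIPC", "RIPC", "LHIP"), c(0.15, 0.20, 0.18, 0.16)),
    edge("PCC", c("mPFC", "LIPC", "RIPC", "LHIP"), c(0.10, 0.23, 0.22, 0.29)),
    edge("LIPC", c("mPFC", "PCC", "RIPC", "LHIP"), c(-0.18, 0.02, 0.22, 0.28)),
    edge("RIPC", c("mPFC", "PCC", "LIPC", "LHIP"), c(-0.08, -0.01, 0.21, 0.30)),
    edge("LHIP", c("mPFC", "PCC", "LIPC", "RIPC"), c(0.00, 0.00, 0.11, 0.02)))
  tab_rhip <- rbind(
    edge("mPFC", c("PCC", "LIPC", "RIPC", "RHIP"), c(0.10, 0.19, 0.26, 0.09)),
    edge("PCC", c("mPFC", "LIPC", "RIPC", "RHIP"), c(0.13, 0.27, 0.35, 0.08)),
    edge("LIPC", c("mPFC", "PCC", "RIPC", "RHIP"), c(0.01, 0.00, 0.27, -0.08)),
    edge("RIPC", c("mPFC", "PCC", "LIPC", "RHIP"), c(0.03, -0.05, 0.28, -0.08)),
    edge("RHIP", c("mPFC", "PCC", "LIPC", "RIPC"), c(0.03, -0.03, 0.11, 0.23)))
  tab_red <- rbind(
    edge("mPFC", c("LIPC", "RIPC", "LHIP"), c(0.32, 0.29, 0.23)),
    edge("LIPC", c("mPFC", "RIPC", "LHIP"), c(-0.16, 0.28, 0.18)),
    edge("RIPC", c("mPFC", "LIPC", "LHIP"), c(-0.09, 0.19, 0.27)),
    edge("LHIP", c("mPFC", "LIPC", "RIPC"), c(0.00, 0.15, 0.02)))
  regions <- spec$regions
  tab <- if (setequal(regions, c(CORE_REGIONS, "LHIP", "RHIP"))) {
    rbind(tab_lhip, tab_rhip[tab_rhip$from == "RHIP" | tab_rhip$to == "RHIP", ],
          edge("RHIP", "LHIP", 0.44), edge("LHIP", "RHIP", 0.00))
  } else if (setequal(regions, c(CORE_REGIONS, "LHIP"))) {
    tab_lhip
  } else if (setequal(regions, c(CORE_REGIONS, "RHIP"))) {
    tab_rhip
  } else if (setequal(regions, c("mPFC", "LIPC", "RIPC", "LHIP"))) {
    tab_red
  } else stop("no reference couplings for region set: ",
              paste(regions, collapse = ", "))
  n <- length(regions)
  A <- matrix(0, n, n, dimnames = list(regions, regions))
  for (k in seq_len(nrow(tab)))
    if (tab$to[k] %in% regions && tab$from[k] %in% regions)
      A[tab$to[k], tab$from[k]] <- tab$val[k]
  A[spec$mask == 0] <- 0
  diag(A) <- self
  dcm_params(A, regions = regions, ...)
}

#' Fill a model mask with random coupling strengths
#'
#' Draws a stable ground-truth coupling matrix respecting a model
#' specification: each allowed off-diagonal entry gets magnitude uniform in
#' `range` with sign negative with probability `p_negative`; the diagonal is
#' set to `self` (default -0.5 Hz). Redraws (up to 100 times) until the
#' system is stable.
#'
#' @param spec a [model_spec] (see [full_space()]).
#' @param range magnitude range in Hz.
#' @param p_negative probability of an inhibitory (negative) coupling.
#' @param self self-inhibition value, Hz (negative).
#' @param margin required stability margin: the spectral abscissa of `A`
#'   must be below `-margin` (keeps the coupled system away from the edge
#'   of instability, where latent fluctuations amplify unrealistically).
#' @param seed integer seed.
#' @param ... further arguments passed to [dcm_params()].
#' @return a `dcm_params` object whose `A` respects `spec$mask`.
#' @export
random_couplings <- function(spec, range = c(0.1, 0.3), p_negative = 0.2,
                             self = -0.5, margin = 0.15, seed = 1, ...) {
  stopifnot(inherits(spec, "model_spec"), self < 0)
  n <- length(spec$regions)
  set.seed(seed)
  for (try in 1:100) {
    A <- matrix(0, n, n)
    free <- which(spec$mask == 1)
    mag <- runif(length(free), range[1], range[2])
    sgn <- ifelse(runif(length(free)) < p_negative, -1, 1)
    A[free] <- mag * sgn
    diag(A) <- self
    if (max(Re(eigen(A, only.values = TRUE)$values)) < -margin)
      return(dcm_params(A, regions = spec$regions, ...))
  }
  stop("could not draw a stable coupling matrix in 100 attempts")
}
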