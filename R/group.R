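# Group-level statistics over per-subject inversions: fixed-effects
# Bayesian model selection, family posteriors, win counts, Bayesian model
# averaging (BMA), Bayesian parameter averaging (BPA), cross-subject
# stability of the evidence profiles, and the hippocampal lateralization
# contrast.

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fixed-effects Bayesian model selection
#'
#' Under the assumption that all subjects share one model, the group log
#' evidence of each model is the column sum of the per-subject free
#' energies; posterior model probabilities are its softmax (max-subtracted
#' for numerical stability), with a uniform model prior.
#'
#' @param F numeric matrix of free energies, subjects x models. Rows with
#'   missing values are dropped with a warning.
#' @return named numeric vector of posterior model probabilities (sums to 1).
#' @export
ffx_bms <- function(F) {
  F <- as.matrix(F)
  if (ncol(F) < 1) stop("need at least one model")
  bad <- apply(F, 1, anyNA)
  if (any(bad)) {
    warning(sum(bad), " subject(s) with missing F excluded from FFX BMS")
    F <- F[!bad, , drop = FALSE]
  }
  g <- colSums(F)
  p <- exp(g - max(g))
  p / sum(p)
}

#' Family-level fixed-effects posteriors
#'
#' Groups models into families and computes FFX family evidence as the
#' log-sum-exp of member group evidences minus log family size (a uniform
#' prior over families, corrected for member count so large families do not
#' win by size), normalised across families.
#'
#' @param F free-energy matrix, subjects x models (named columns).
#' @param family_of named character vector or function mapping model name to
#'   family label; every model must be mapped.
#' @return named numeric vector of family posterior probabilities.
#' @export
family_posteriors <- function(F, family_of) {
  F <- as.matrix(F)
  mnames <- colnames(F)
  fam <- if (is.function(family_of)) vapply(mnames, family_of, "")
         else family_of[mnames]
  if (anyNA(fam)) stop("unmapped model(s): ",
                       paste(mnames[is.na(fam)], collapse = ", "))
  bad <- apply(F, 1, anyNA)
  F <- F[!bad, , drop = FALSE]
  g <- colSums(F)
  fams <- unique(fam)
  ev <- vapply(fams, function(f) {
    members <- g[fam == f]
    if (!length(members)) stop("empty family ", f)
    logsumexp(members) - log(length(members))
  }, 0)
  p <- exp(ev - max(ev))
  p <- p / sum(p)
  names(p) <- fams
  p
}

#' Per-model win counts
#'
#' For each subject, the model with the highest free energy gets one win;
#' ties are split by first index with a warning.
#'
#' @param F free-energy matrix, subjects x models.
#' @return named integer vector of wins (sums to the number of subjects).
#' @export
count_wins <- function(F) {
  F <- as.matrix(F)
  wins <- integer(ncol(F))
  names(wins) <- colnames(F)
  for (s in seq_len(nrow(F))) {
    best <- which(F[s, ] == max(F[s, ]))
    if (length(best) > 1)
      warning("tie for subject ", s, "; first model taken")
    wins[best[1]] <- wins[best[1]] + 1L
  }
  wins
}

# Extract the free off-diagonal coupling estimates of a fit as a named
# vector "from->to" (Hz).
coupling_vector <- function(fit) {
  idx <- fit$priors$idx$a
  fit$theta[idx]
}

#' Bayesian model averaging of coupling parameters
#'
#' Per subject, each coupling estimate is the posterior-probability-weighted
#' average over models (weights = softmax of that subject's free energies,
#' optionally restricted to an Occam window); couplings absent from a model
#' contribute zero. Group values are means across subjects, with per-
#' connection two-sided one-sample t-tests (uncorrected and Bonferroni
#' flags).
#'
#' @param results list over subjects, each a list over models of
#'   [spdcm_invert()] fits (may contain NULL for failed inversions).
#' @param F free-energy matrix, subjects x models.
#' @param occam_window restrict weights to models within this many nats of
#'   the subject's best model (`Inf` = all models).
#' @param alpha significance level for the t-tests.
#' @return data.frame with columns `from`, `to`, `mean`, `t`, `p`, `sig`,
#'   `sig_bonf`, plus attribute `"subject_estimates"` (subjects x
#'   connections matrix).
#' @export
bma <- function(results, F, occam_window = Inf, alpha = 0.05) {
  F <- as.matrix(F)
  stopifnot(length(results) == nrow(F))
  all_names <- unique(unlist(lapply(results, function(subj)
    unlist(lapply(subj, function(f) if (!is.null(f)) names(coupling_vector(f)))))))
  est <- matrix(0, nrow(F), length(all_names),
                dimnames = list(rownames(F), all_names))
  for (s in seq_len(nrow(F))) {
    Fs <- F[s, ]
    ok <- !is.na(Fs) & !vapply(results[[s]], is.null, TRUE)
    if (!any(ok)) stop("subject ", s, " has no usable model evidence")
    Fs <- Fs[ok]
    w <- exp(Fs - max(Fs))
    w[Fs < max(Fs) - occam_window] <- 0
    if (all(w == 0)) stop("degenerate BMA weights for subject ", s)
    w <- w / sum(w)
    fits <- results[[s]][ok]
    for (m in seq_along(fits)) {
      cv <- coupling_vector(fits[[m]])
      est[s, names(cv)] <- est[s, names(cv)] + w[m] * cv
    }
  }
  summarise_connections(est, alpha, subject_estimates = TRUE)
}

# Shared per-connection t-test summary used by bma().
summarise_connections <- function(est, alpha, subject_estimates = FALSE) {
  parts <- strsplit(colnames(est), "->", fixed = TRUE)
  out <- data.frame(
    from = vapply(parts, `[`, "", 1),
    to = vapply(parts, `[`, "", 2),
    mean = colMeans(est),
    stringsAsFactors = FALSE, row.names = NULL
  )
  tt <- lapply(seq_len(ncol(est)), function(j) {
    x <- est[, j]
    if (sd(x) == 0) list(statistic = if (mean(x) == 0) 0 else Inf * sign(mean(x)),
                         p.value = if (mean(x) == 0) 1 else 0)
    else t.test(x)
  })
  out$t <- vapply(tt, function(z) unname(z$statistic), 0)
  out$p <- vapply(tt, function(z) z$p.value, 0)
  out$sig <- out$p < alpha
  out$sig_bonf <- out$p < alpha / ncol(est)
  if (subject_estimates) attr(out, "subject_estimates") <- est
  out
}

#' Bayesian parameter averaging over subjects for one model
#'
#' Precision-weighted fusion of single-subject posteriors sharing one
#' model and prior: the group precision is the sum of subject precisions
#' minus (S-1) times the prior precision, and the group mean solves the
#' corresponding normal equations. Per-connection significance uses the
#' one-sided 95% criterion |mean| > 1.645 group posterior SD.
#'
#' @param fits list of [spdcm_invert()] results for the same model.
#' @param priors the shared [spdcm_priors()] (defaults to the first fit's).
#' @return data.frame with columns `from`, `to`, `mean`, `sd`, `sig` for
#'   the coupling parameters, plus attributes `"mean_full"` and
#'   `"cov_full"` over the whole parameter vector.
#' @export
bpa <- function(fits, priors = fits[[1]]$priors) {
  stopifnot(length(fits) >= 1)
  nm <- priors$names
  for (f in fits)
    if (!identical(names(f$theta), nm))
      stop("all fits must share one model/parameterisation")
  S <- length(fits)
  P0 <- diag(1 / priors$pV)
  Pg <- -(S - 1) * P0
  b <- -(S - 1) * P0 %*% priors$pE
  for (f in fits) {
    Ps <- solve(f$Sigma)
    Pg <- Pg + Ps
    b <- b + Ps %*% f$theta
  }
  ev <- eigen(Pg, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("group precision not positive definite (eigenvalues: ",
         paste(signif(range(ev), 4), collapse = " .. "), ")")
  Cg <- solve(Pg)
  mg <- as.vector(Cg %*% b)
  names(mg) <- nm
  ia <- priors$idx$a
  parts <- strsplit(nm[ia], "->", fixed = TRUE)
  sds <- sqrt(diag(Cg))[ia]
  out <- data.frame(
    from = vapply(parts, `[`, "", 1),
    to = vapply(parts, `[`, "", 2),
    mean = mg[ia], sd = sds,
    sig = abs(mg[ia]) > 1.645 * sds,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "mean_full") <- mg
  attr(out, "cov_full") <- Cg
  out
}

#' Cross-subject stability of the evidence profile
#'
#' Pearson correlation between every pair of subjects' free-energy vectors
#' over the model space. High positive correlations indicate that models
#' behave alike across subjects.
#'
#' @param F free-energy matrix, subjects x models (>= 2 models).
#' @return correlation matrix (subjects x subjects, unit diagonal) with
#'   attribute `"mean_offdiag"`.
#' @export
stability_matrix <- function(F) {
  F <- as.matrix(F)
  if (ncol(F) < 2) stop("need at least 2 models")
  if (any(apply(F, 1, sd) == 0))
    stop("constant F row(s): correlation undefined for subject(s) ",
         paste(which(apply(F, 1, sd) == 0), collapse = ", "))
  C <- cor(t(F))
  diag(C) <- 1
  attr(C, "mean_offdiag") <- mean(C[lower.tri(C)])
  C
}

#' Hippocampal lateralization contrast on the six-node model
#'
#' For each target region in {mPFC, LIPC, RIPC}, a paired two-sided t-test
#' across subjects of the LHIP->target versus RHIP->target coupling.
#'
#' @param fits list of [spdcm_invert()] results for the combined six-node
#'   model (see [combine_best()]), one per subject (>= 3).
#' @return data.frame with columns `target`, `mean_diff` (LHIP minus RHIP,
#'   Hz), `t`, `p`.
#' @export
lateralization_contrast <- function(fits) {
  if (length(fits) < 3) stop("need at least 3 subjects")
  targets <- c("mPFC", "LIPC", "RIPC")
  out <- lapply(targets, function(tg) {
    l <- vapply(fits, function(f) f$A[tg, "LHIP"], 0)
    r <- vapply(fits, function(f) f$A[tg, "RHIP"], 0)
    if (all(l == r))
      return(data.frame(target = tg, mean_diff = 0, t = 0, p = 1))
    tt <- t.test(l, r, paired = TRUE)
    data.frame(target = tg, mean_diff = mean(l - r),
               t = unname(tt$statistic), p = tt$p.value)
  })
  do.call(rbind, out)
}
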