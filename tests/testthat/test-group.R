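test_that("fixed-effects BMS posterior behaves like a softmax of summed evidence", {
  # equal columns: uniform posterior
  F <- matrix(5, 4, 3, dimnames = list(NULL, c("m1", "m2", "m3")))
  expect_equal(unname(ffx_bms(F)), rep(1 / 3, 3))
  # one model 20 nats ahead: posterior essentially 1
  F[, 2] <- F[, 2] + 6   # 4 subjects x 6 = 24 nats of group evidence
  expect_gt(ffx_bms(F)["m2"], 0.9999)
  # random matrix: equals direct exp-normalisation computed on small
  # values where no overflow protection is needed
  set.seed(1)
  Fr <- matrix(rnorm(20, sd = 0.5), 5, 4,
               dimnames = list(NULL, paste0("m", 1:4)))
  g <- colSums(Fr)
  expect_equal(unname(ffx_bms(Fr)), unname(exp(g) / sum(exp(g))),
               tolerance = 1e-12)
  # invariance: adding a constant to one subject's whole row changes nothing
  Fr2 <- Fr; Fr2[3, ] <- Fr2[3, ] + 40
  expect_equal(ffx_bms(Fr2), ffx_bms(Fr))
})

test_that("family posteriors apply a size-corrected uniform family prior", {
  F <- matrix(0, 2, 4, dimnames = list(NULL, c("a_1", "a_2", "b_1", "b_2")))
  fam <- c(a_1 = "a", a_2 = "a", b_1 = "b", b_2 = "b")
  expect_equal(unname(family_posteriors(F, fam)), c(0.5, 0.5))
  # unbalanced family sizes with identical member evidences stay uniform
  F3 <- matrix(0, 2, 3, dimnames = list(NULL, c("a_1", "a_2", "b_1")))
  fam3 <- c(a_1 = "a", a_2 = "a", b_1 = "b")
  expect_equal(unname(family_posteriors(F3, fam3)), c(0.5, 0.5))
  # a dominant model carries its family
  F[, "b_2"] <- 15
  expect_gt(family_posteriors(F, fam)["b"], 0.999)
  expect_error(family_posteriors(F, fam[1:3]), "unmapped")
})

test_that("win counting is a per-subject argmax with permutation equivariance", {
  F <- rbind(c(1, 2, 0), c(3, 1, 0), c(0, 1, 4))
  colnames(F) <- c("m1", "m2", "m3")
  w <- count_wins(F)
  expect_equal(unname(w), c(1L, 1L, 1L))
  expect_equal(sum(w), nrow(F))
  expect_equal(sum(count_wins(F[1, , drop = FALSE])), 1L)
  perm <- c(3, 1, 2)
  expect_equal(count_wins(F[, perm]), w[perm])
  expect_warning(count_wins(rbind(c(1, 1, 0))), "tie")
  # stability matrix is invariant under model permutation
  set.seed(2)
  Fr <- matrix(rnorm(40), 4, 10)
  expect_equal(stability_matrix(Fr[, sample(10)]), stability_matrix(Fr))
})

test_that("stability matrix summarises evidence-profile correlations", {
  F <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  S <- stability_matrix(F)
  expect_equal(diag(S), c(a = 1, b = 1, c = 1))
  expect_equal(unname(S[1, 2]), 1)          # identical profile up to scale
  expect_equal(unname(S[1, 3]), -1)         # reversed profile
  expect_equal(S, t(S))
  expect_error(stability_matrix(rbind(c(1, 1), c(1, 2))), "constant")
})

# -- BMA / BPA on real (tiny) fits ------------------------------------------

make_two_model_fits <- function() {
  spec1 <- tiny_spec(c("R1", "R2"), list(c("R1", "R2")), name = "m1")
  spec2 <- tiny_spec(c("R1", "R2"), list(c("R2", "R1")), name = "m2")
  g <- quick_group(spec1, n_subjects = 3, n_scans = 300, seed = 60)
  fits <- lapply(g$csd, function(cs)
    list(spdcm_invert(cs, spec1, opts = list(max_iter = 6)),
         spdcm_invert(cs, spec2, opts = list(max_iter = 6))))
  F <- t(vapply(fits, function(s) c(s[[1]]$F, s[[2]]$F), numeric(2)))
  colnames(F) <- c("m1", "m2")
  list(fits = fits, F = F)
}

test_that("BMA reduces to the single-model posterior under degenerate weights", {
  tm <- make_two_model_fits()
  # force model 1 to dominate every subject
  F1 <- tm$F; F1[, 1] <- F1[, 2] + 50
  tab <- bma(tm$fits, F1)
  est <- attr(tab, "subject_estimates")
  for (s in 1:3) {
    cv <- tm$fits[[s]][[1]]$theta[tm$fits[[s]][[1]]$priors$idx$a]
    expect_equal(unname(est[s, "R1->R2"]), unname(cv), tolerance = 1e-10)
  }
  # symmetric +x/-x estimates under equal weights average to zero
  f <- tm$fits[[1]][[1]]
  fpos <- f; fpos$theta[f$priors$idx$a] <- 0.2
  fneg <- f; fneg$theta[f$priors$idx$a] <- -0.2
  fits_sym <- list(list(fpos, fneg), list(fpos, fneg), list(fpos, fneg))
  Feq <- matrix(1, 3, 2, dimnames = list(NULL, c("m1", "m1b")))
  tab_sym <- bma(fits_sym, Feq)
  expect_equal(tab_sym$mean, 0)
  # occam window excludes far-behind models
  F2 <- tm$F; F2[, 2] <- F2[, 1] - 30
  tab_occ <- bma(tm$fits, F2, occam_window = 20)
  est_occ <- attr(tab_occ, "subject_estimates")
  cv1 <- tm$fits[[1]][[1]]$theta[tm$fits[[1]][[1]]$priors$idx$a]
  expect_equal(unname(est_occ[1, "R1->R2"]), unname(cv1), tolerance = 1e-10)
})

test_that("BPA implements precision-weighted posterior fusion", {
  tm <- make_two_model_fits()
  fits1 <- lapply(tm$fits, `[[`, 1)
  # single subject: BPA equals that subject's posterior
  t1 <- bpa(fits1[1])
  f1 <- fits1[[1]]
  expect_equal(t1$mean, unname(f1$theta[f1$priors$idx$a]), tolerance = 1e-10)
  expect_equal(attr(t1, "cov_full"), unname(f1$Sigma), tolerance = 1e-10,
               ignore_attr = TRUE)
  # S identical subjects with a shared prior: group SD shrinks
  rep3 <- list(fits1[[1]], fits1[[1]], fits1[[1]])
  t3 <- bpa(rep3)
  expect_lt(t3$sd, t1$sd)
  # hand-built 2-parameter oracle: closed-form normal-equation solution
  pr <- f1$priors
  f_a <- f1; f_b <- f1
  f_a$theta[] <- 0; f_a$theta[1:2] <- c(0.3, -0.1)
  f_b$theta[] <- 0; f_b$theta[1:2] <- c(0.1, 0.2)
  # posterior covariances must be tighter than the sharpest prior block
  # (1/256) for the fusion fixture to be self-consistent
  Sa <- diag(length(pr$pE)) * 0.002
  Sb <- diag(length(pr$pE)) * 0.003
  dimnames(Sa) <- dimnames(Sb) <- dimnames(f1$Sigma)
  f_a$Sigma <- Sa; f_b$Sigma <- Sb
  got <- bpa(list(f_a, f_b))
  P0 <- diag(1 / pr$pV)
  Pg <- solve(Sa) + solve(Sb) - P0
  mg <- solve(Pg, solve(Sa) %*% f_a$theta + solve(Sb) %*% f_b$theta -
                P0 %*% pr$pE)
  expect_equal(attr(got, "mean_full"), as.vector(mg), tolerance = 1e-12,
               ignore_attr = TRUE)
  # mismatched parameterisations are rejected
  expect_error(bpa(list(f1, tm$fits[[1]][[2]])), "share")
})

test_that("BPA group uncertainty never exceeds the sharpest subject", {
  tm <- make_two_model_fits()
  fits1 <- lapply(tm$fits, `[[`, 1)
  tg <- bpa(fits1)
  ia <- fits1[[1]]$priors$idx$a
  min_sd <- min(vapply(fits1, function(f) sqrt(diag(f$Sigma))[ia], 0))
  expect_lte(tg$sd, min_sd)
})

test_that("lateralization contrast detects asymmetric hippocampal output", {
  cb <- combine_best()
  pr <- spdcm_priors(cb)
  base_fit <- list(theta = pr$pE, Sigma = diag(length(pr$pE)),
                   priors = pr, spec = cb)
  mk <- function(lhip, rhip, jit) {
    A <- matrix(0, 6, 6, dimnames = list(cb$regions, cb$regions))
    for (tg in c("mPFC", "LIPC", "RIPC")) {
      A[tg, "LHIP"] <- lhip + jit[1]
      A[tg, "RHIP"] <- rhip + jit[2]
    }
    f <- base_fit
    f$A <- A
    f
  }
  set.seed(3)
  fits <- lapply(1:10, function(s) mk(0.25, 0.05, rnorm(2, 0, 0.03)))
  out <- lateralization_contrast(fits)
  expect_equal(out$target, c("mPFC", "LIPC", "RIPC"))
  expect_true(all(out$p < 0.01))
  expect_true(all(out$mean_diff > 0))
  # identical couplings: zero difference, p = 1
  fits0 <- lapply(1:5, function(s) mk(0.2, 0.2, c(0, 0)))
  out0 <- lateralization_contrast(fits0)
  expect_equal(out0$mean_diff, rep(0, 3))
  expect_equal(out0$p, rep(1, 3))
  # swapping the hippocampal labels flips every sign
  fits_sw <- lapply(fits, function(f) {
    A <- f$A
    A[, c("LHIP", "RHIP")] <- A[, c("RHIP", "LHIP")]
    f$A <- A
    f
  })
  out_sw <- lateralization_contrast(fits_sw)
  expect_equal(out_sw$mean_diff, -out$mean_diff)
  expect_error(lateralization_contrast(fits[1:2]), "3 subjects")
})
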