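# Functional connectivity: Fisher-transformed Pearson correlations per
# subject, with group-level one-sample t-tests and Benjamini-Hochberg FDR
# control over the unique region pairs.

#' Subject-level Fisher-z connectivity matrix
#'
#' Pairwise Pearson correlations between region time series, Fisher
#' transformed (`z = atanh(r)`); the diagonal is set to zero.
#'
#' @param ts an [roi_ts] with at least 3 scans and non-constant regions.
#' @return symmetric numeric matrix (regions x regions).
#' @export
fc_subject <- function(ts) {
  stopifnot(inherits(ts, "roi_ts"))
  if (nrow(ts$data) < 3) stop("need at least 3 scans")
  if (any(apply(ts$data, 2, sd) == 0)) stop("constant region series")
  r <- cor(ts$data)
  off <- r[upper.tri(r)]
  if (any(abs(off) >= 1)) stop("degenerate pair: |r| = 1")
  z <- atanh(r)
  diag(z) <- 0
  z
}

#' Group-level functional connectivity with FDR control
#'
#' Per edge (unique region pair), a two-sided one-sample t-test of the
#' subjects' Fisher-z values against zero, with Benjamini-Hochberg
#' correction across the edges at level `q`.
#'
#' @param z_list list of subject z matrices from [fc_subject()] (>= 3
#'   subjects, consistent regions).
#' @param q FDR level (default 0.05).
#' @return object of class `fc_result`: `group_mean` (mean z matrix),
#'   `edges` data.frame (`region1`, `region2`, `mean_z`, `t`, `p`,
#'   `p_fdr`, `significant`), and `q`.
#' @export
fc_group <- function(z_list, q = 0.05) {
  if (length(z_list) < 3) stop("need at least 3 subjects")
  regions <- rownames(z_list[[1]])
  if (is.null(regions)) regions <- paste0("R", seq_len(nrow(z_list[[1]])))
  for (z in z_list)
    if (!all(dim(z) == length(regions)))
      stop("inconsistent region sets across subjects")
  n <- length(regions)
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  zmat <- do.call(rbind, lapply(z_list, function(z) z[pairs]))
  means <- colMeans(zmat)
  tt <- lapply(seq_len(ncol(zmat)), function(j) {
    x <- zmat[, j]
    if (sd(x) == 0) {
      # degenerate spread: a constant nonzero effect is unambiguous
      if (mean(x) == 0) list(statistic = 0, p.value = 1)
      else list(statistic = sign(mean(x)) * Inf, p.value = 0)
    } else t.test(x)
  })
  p <- vapply(tt, function(z) z$p.value, 0)
  p_fdr <- p.adjust(p, method = "BH")
  gm <- matrix(0, n, n, dimnames = list(regions, regions))
  gm[pairs] <- means
  gm <- gm + t(gm)
  edges <- data.frame(
    region1 = regions[pairs[, 1]], region2 = regions[pairs[, 2]],
    mean_z = means,
    t = vapply(tt, function(z) unname(z$statistic), 0),
    p = p, p_fdr = p_fdr, significant = p_fdr < q,
    stringsAsFactors = FALSE
  )
  structure(list(group_mean = gm, edges = edges, q = q,
                 n_subjects = length(z_list)),
            class = "fc_result")
}

#' @export
print.fc_result <- function(x, ...) {
  cat("group functional connectivity over", x$n_subjects, "subjects;",
      sum(x$edges$significant), "of", nrow(x$edges),
      "edges significant at FDR q =", x$q, "\n")
  invisible(x)
}
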