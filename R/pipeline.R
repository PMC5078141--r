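# End-to-end pipeline driver: simulate (or load) a subject group, extract
# cross-spectral features, invert the model space, and produce the group
# inference and functional-connectivity outputs, with a checksummed manifest.

#' Pipeline configuration
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param n_subjects group size.
#' @param n_scans,tr acquisition length and repetition time (s).
#' @param space model space: `"LHIP"` / `"RHIP"` (96 five-node models),
#'   `"reduced"` (72 models, PCC removed), or a list of [model_spec]s.
#' @param truth_model name of the generating model within the space.
#' @param subject_sd between-subject coupling jitter SD, Hz.
#' @param csd `"mar"` or `"welch"` feature estimator.
#' @param mar_order MAR model order.
#' @param n_freq frequency-grid size.
#' @param f_max upper band edge, Hz.
#' @param invert_opts options for [spdcm_invert()].
#' @return config list (class `run_config`).
#' @export
run_config <- function(seed = 1, n_subjects = 4, n_scans = 250, tr = 2,
                       space = "LHIP", truth_model = "a_6",
                       subject_sd = 0.05, csd = c("mar", "welch"),
                       mar_order = 12, n_freq = 12, f_max = 0.1,
                       invert_opts = list(max_iter = 16)) {
  structure(list(seed = as.integer(seed), n_subjects = n_subjects,
                 n_scans = n_scans, tr = tr, space = space,
                 truth_model = truth_model, subject_sd = subject_sd,
                 csd = match.arg(csd), mar_order = mar_order,
                 n_freq = n_freq, f_max = f_max, invert_opts = invert_opts),
            class = "run_config")
}

resolve_space <- function(space) {
  if (is.list(space)) return(space)
  switch(space,
         LHIP = full_space("LHIP"),
         RHIP = full_space("RHIP"),
         reduced = reduced_space(),
         stop("unknown space: ", space))
}

#' Run the full analysis pipeline on a synthetic group
#'
#' Simulates a group from a known ground truth drawn on `truth_model`,
#' writes per-subject TSVs, extracts cross-spectral features, inverts every
#' (subject, model) pair, and writes the group-level outputs: the
#' free-energy matrix, FFX model/family posteriors, win counts, BMA table,
#' BPA table for the winning model, the cross-subject stability matrix and
#' the functional-connectivity summary. A `manifest.json` lists every
#' artifact with an md5 checksum; runs are deterministic given the seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  on_fail <- function(e) stop("pipeline stage `", stage, "` failed: ",
                              conditionMessage(e), call. = FALSE)
  tryCatch({
    space <- resolve_space(config$space)
    truth_spec <- space[[config$truth_model]]
    if (is.null(truth_spec)) stop("truth model not in space")
    rois <- dmn_rois(truth_spec$regions)
    cfg <- sim_config(n_scans = config$n_scans, tr = config$tr,
                      seed = config$seed, subject_sd = config$subject_sd)

    stage <- "simulate"
    base <- random_couplings(truth_spec, seed = config$seed)
    truths <- make_group_truth(truth_spec, base, cfg, config$n_subjects)
    mni <- as.matrix(rois[, c("x", "y", "z")])
    group <- lapply(seq_len(config$n_subjects), function(s) {
      scfg <- cfg
      scfg$seed <- cfg$seed + s
      simulate_bold(truths[[s]], scfg, mni = mni)
    })
    write_dcm_params(base, file.path(out_dir, "truth.json"))
    write_model_space(space, file.path(out_dir, "space.json"))
    for (s in seq_along(group))
      write_roi_tsv(group[[s]], file.path(out_dir,
                                          sprintf("sub-%02d_roi.tsv", s)),
                    extra = list(seed = cfg$seed + s, truth_file = "truth.json"))

    stage <- "features"
    freqs <- default_freq_grid(config$n_scans, config$tr,
                               f_max = config$f_max, n_freq = config$n_freq)
    feats <- lapply(group, function(ts) {
      rts <- residualize(ts)
      if (config$csd == "mar") csd_from_mar(fit_mar(rts, config$mar_order), freqs)
      else csd_welch(rts, freqs)
    })

    stage <- "invert"
    priors <- lapply(space, spdcm_priors)
    fits <- lapply(feats, function(cs)
      lapply(seq_along(space), function(m)
        tryCatch(spdcm_invert(cs, space[[m]], priors = priors[[m]],
                              opts = config$invert_opts),
                 error = function(e) NULL)))
    F <- t(vapply(fits, function(subj)
      vapply(subj, function(f) if (is.null(f)) NA_real_ else f$F, 0),
      numeric(length(space))))
    dimnames(F) <- list(sprintf("sub-%02d", seq_along(group)),
                        vapply(space, `[[`, "", "name"))
    write_fmatrix(F, file.path(out_dir, "fmatrix.csv"))

    stage <- "group"
    post <- ffx_bms(F)
    fam_base <- family_posteriors(F, vapply(space, `[[`, "", "family"))
    fam_pat <- family_posteriors(F, vapply(space, `[[`, "", "pattern"))
    wins <- count_wins(F)
    stab <- stability_matrix(F)
    jsonlite::write_json(list(model_posterior = as.list(post),
                              family_posterior_base = as.list(fam_base),
                              family_posterior_pattern = as.list(fam_pat)),
                         file.path(out_dir, "bms.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.table(data.frame(model = names(wins), wins = as.integer(wins)),
                file.path(out_dir, "wins.csv"), sep = ",", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(round(unclass(stab), 10), check.names = FALSE),
                file.path(out_dir, "stability.csv"), sep = ",",
                col.names = NA, quote = FALSE)
    bma_tab <- bma(fits, F)
    write.table(bma_tab, file.path(out_dir, "bma.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    winner <- which.max(post)
    win_fits <- lapply(fits, `[[`, winner)
    ok <- !vapply(win_fits, is.null, TRUE)
    bpa_tab <- tryCatch(bpa(win_fits[ok]), error = function(e) NULL)
    if (!is.null(bpa_tab))
      write.table(bpa_tab, file.path(out_dir, "bpa.csv"), sep = ",",
                  quote = FALSE, row.names = FALSE)

    stage <- "fc"
    fc <- fc_group(lapply(group, function(ts) fc_subject(residualize(ts))))
    write.table(fc$edges, file.path(out_dir, "fc.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)

    stage <- "manifest"
    files <- setdiff(list.files(out_dir), "manifest.json")
    sums <- tools::md5sum(file.path(out_dir, files))
    manifest <- list(
      package_version = as.character(utils::packageVersion("restdcm")),
      seed = config$seed,
      config_hash = {
        hashable <- unclass(config)
        if (is.list(hashable$space))
          hashable$space <- vapply(hashable$space, `[[`, "", "name")
        tmp <- tempfile(fileext = ".json")
        jsonlite::write_json(hashable, tmp, auto_unbox = TRUE, digits = NA)
        unname(tools::md5sum(tmp))
      },
      n_subjects = config$n_subjects,
      n_models = length(space),
      n_F_entries = sum(!is.na(F)),
      winning_model = names(post)[winner],
      artifacts = lapply(seq_along(files), function(i)
        list(file = files[i], md5 = unname(sums[i])))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  }, error = on_fail)
}
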