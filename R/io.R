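# Plain-text interchange formats: TSV for time series (with a JSON sidecar
# for TR / region / coordinate metadata), JSON for model spaces and
# parameter sets, CSV for evidence matrices.

sidecar_path <- function(path) sub("\\.tsv$", ".json", path)

#' Write an ROI time-series TSV with JSON sidecar
#'
#' The TSV has one column per region (header row = region labels); the
#' sidecar JSON records `tr`, `regions`, `mni` and optional provenance
#' fields.
#'
#' @param ts an [roi_ts].
#' @param path output TSV path (sidecar gets the same name with `.json`).
#' @param extra named list merged into the sidecar (e.g. `seed`,
#'   `truth_file`).
#' @return `path`, invisibly.
#' @export
write_roi_tsv <- function(ts, path, extra = list()) {
  stopifnot(inherits(ts, "roi_ts"))
  write.table(format(ts$data, digits = 15, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(list(tr = ts$tr, regions = ts$regions), extra)
  if (!is.null(ts$mni)) meta$mni <- unname(apply(ts$mni, 1, as.integer,
                                                 simplify = FALSE))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an ROI time-series TSV with JSON sidecar
#'
#' @param path TSV path written by [write_roi_tsv()].
#' @return an [roi_ts].
#' @export
read_roi_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing sidecar JSON: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$tr)) stop("sidecar ", sc, ": required field `tr` missing")
  if (is.null(meta$regions)) stop("sidecar ", sc, ": required field `regions` missing")
  dat <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (!identical(colnames(dat), as.character(meta$regions)))
    stop("TSV columns do not match sidecar regions in ", path)
  mni <- if (!is.null(meta$mni)) {
    if (is.list(meta$mni)) do.call(rbind, meta$mni) else as.matrix(meta$mni)
  }
  roi_ts(as.matrix(dat), tr = meta$tr, regions = meta$regions, mni = mni)
}

#' Write a model space to JSON
#'
#' Layout: `{regions, models: [{name, family, pattern, mask}]}` with each
#' mask flattened row-major.
#'
#' @param space list of [model_spec] objects sharing one region set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_space <- function(space, path) {
  regions <- space[[1]]$regions
  models <- lapply(space, function(s) {
    stopifnot(identical(s$regions, regions))
    list(name = s$name, family = s$family, pattern = s$pattern,
         mask = as.integer(t(s$mask)))
  })
  jsonlite::write_json(list(regions = regions, models = unname(models)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model space from JSON
#'
#' @param path path written by [write_model_space()].
#' @return named list of [model_spec] objects.
#' @export
read_model_space <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$regions) || is.null(obj$models))
    stop("model-space JSON ", path, ": need fields `regions` and `models`")
  regions <- obj$regions
  n <- length(regions)
  out <- list()
  for (k in seq_len(nrow(obj$models))) {
    m <- obj$models[k, ]
    mask <- matrix(unlist(m$mask), n, n, byrow = TRUE)
    out[[m$name]] <- model_spec(regions, mask, family = m$family,
                                pattern = as.character(m$pattern),
                                name = m$name)
  }
  out
}

#' Write / read a free-energy matrix as CSV
#'
#' Rows are subjects, columns are model names.
#'
#' @param F numeric matrix with dimnames.
#' @param path CSV path.
#' @return `path` (write) or the matrix (read).
#' @export
write_fmatrix <- function(F, path) {
  write.table(data.frame(F, check.names = FALSE), path, sep = ",",
              col.names = NA, quote = FALSE)
  invisible(path)
}

#' @rdname write_fmatrix
#' @export
read_fmatrix <- function(path) {
  as.matrix(read.table(path, header = TRUE, sep = ",", row.names = 1,
                       check.names = FALSE))
}

#' Write / read ground-truth DCM parameters as JSON
#'
#' @param params a [dcm_params].
#' @param path JSON path.
#' @return `path` (write) or a [dcm_params] (read).
#' @export
write_dcm_params <- function(params, path) {
  stopifnot(inherits(params, "dcm_params"))
  jsonlite::write_json(list(
    regions = params$regions, A = apply(params$A, 1, c, simplify = FALSE),
    hemo = params$hemo, amp_v = params$amp_v, exp_v = params$exp_v,
    amp_e = params$amp_e, exp_e = params$exp_e
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dcm_params
#' @export
read_dcm_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- if (is.list(obj$A)) do.call(rbind, obj$A) else as.matrix(obj$A)
  dcm_params(A, regions = obj$regions, hemo = as.list(obj$hemo),
             amp_v = obj$amp_v, exp_v = obj$exp_v,
             amp_e = obj$amp_e, exp_e = obj$exp_e)
}
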