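# Structured model spaces over DMN regions.
#
# A model is a binary directed adjacency mask over an ordered region set:
# mask[i, j] = 1 means the connection j -> i is allowed (self-connections are
# handled implicitly by the inversion engine, so the diagonal is always 0).
# The space is the cross product of "base families" (topologies over the four
# core DMN nodes) and "inclusion patterns" (ways of wiring one additional
# region, e.g. a hippocampal node, into the base set).

CORE_REGIONS <- c("mPFC", "PCC", "LIPC", "RIPC")

#' Construct a model specification
#'
#' @param regions ordered character labels.
#' @param mask binary matrix, `mask[i, j] = 1` iff the directed connection
#'   j -> i is allowed; zero diagonal.
#' @param family base-family label (`a`..`h`, or primed variants).
#' @param pattern inclusion-pattern label (`1`..`12`, primed, or `none`).
#' @param name model name; defaults to `<family>_<pattern>`.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(regions, mask, family = "a", pattern = "none",
                       name = NULL) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "double"
  n <- length(regions)
  if (!all(dim(mask) == n)) stop("mask must be square, matching regions")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  if (any(diag(mask) != 0)) stop("mask diagonal must be zero")
  dimnames(mask) <- list(regions, regions)
  if (is.null(name))
    name <- if (identical(pattern, "none")) family else paste0(family, "_", pattern)
  structure(list(regions = regions, mask = mask, family = family,
                 pattern = pattern, name = name),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model", x$name, "over {", paste(x$regions, collapse = ", "), "}:",
      sum(x$mask), "directed edges\n")
  invisible(x)
}

# Helper: set both directions between two nodes.
add_edge <- function(mask, from, to) {
  mask[to, from] <- 1
  mask
}

#' Eight base-family topologies over the four core DMN nodes
#'
#' Family `a` is the complete digraph over mPFC, PCC, LIPC, RIPC. Families
#' `b`, `c`, `d` are driver-dominant variants in which all connections INTO
#' the driver set (mPFC; PCC; the bilateral pair LIPC+RIPC) are removed,
#' everything else staying reciprocal (for `d` the LIPC-RIPC pair itself is
#' retained). Families `e`-`h` repeat `a`-`d` with both LIPC<->RIPC
#' connections deleted.
#'
#' @param regions region labels; defaults to the four core DMN nodes.
#' @return named list of 8 `model_spec` objects (`a`..`h`).
#' @export
base_families <- function(regions = CORE_REGIONS) {
  stopifnot(all(CORE_REGIONS %in% regions))
  n <- length(regions)
  full <- matrix(1, n, n, dimnames = list(regions, regions)); diag(full) <- 0
  drop_into <- function(mask, drivers, keep_pair = FALSE) {
    # remove all edges into the driver set (rows = targets)
    mask[drivers, ] <- 0
    if (keep_pair) {
      mask["LIPC", "RIPC"] <- full["LIPC", "RIPC"]
      mask["RIPC", "LIPC"] <- full["RIPC", "LIPC"]
    }
    diag(mask) <- 0
    mask
  }
  drop_pair <- function(mask) {
    mask["LIPC", "RIPC"] <- 0
    mask["RIPC", "LIPC"] <- 0
    mask
  }
  masks <- list(
    a = full,
    b = drop_into(full, "mPFC"),
    c = drop_into(full, "PCC"),
    d = drop_into(full, c("LIPC", "RIPC"), keep_pair = TRUE)
  )
  masks <- c(masks, lapply(masks, drop_pair))
  names(masks) <- letters[1:8]
  Map(function(m, fam) model_spec(regions, m, family = fam, pattern = "none"),
      masks, names(masks))
}

#' Twelve inclusion patterns for wiring one new region into a base set
#'
#' Given a new region (e.g. LHIP) and a base region set, returns the 12 edge
#' templates: (1) reciprocal with every base region; (2) disconnected;
#' (3) outputs to all; (4) inputs from all; (5) inputs from all plus outputs
#' to LIPC/RIPC; (6) inputs from LIPC/RIPC plus outputs to all; (7) inputs
#' from LIPC/RIPC only; (8) outputs to LIPC/RIPC only; (9)-(12) repeat
#' (5)-(8) with mPFC/PCC substituted for LIPC/RIPC. When the base set lacks
#' a region mentioned by a template (the reduced, PCC-free space), edges
#' touching it are dropped.
#'
#' @param new_region label of the added region.
#' @param base character vector of base region labels (3 or 4 regions).
#' @return named list (`1`..`12`) of two-column `from`/`to` edge matrices.
#' @export
inclusion_patterns <- function(new_region, base = CORE_REGIONS) {
  lat <- c("LIPC", "RIPC")
  med <- c("mPFC", "PCC")
  if (!all(lat %in% base)) stop("base must contain LIPC and RIPC")
  keep <- function(x) intersect(x, base)
  edges <- function(inputs = character(), outputs = character()) {
    rbind(
      if (length(inputs)) cbind(from = inputs, to = new_region),
      if (length(outputs)) cbind(from = new_region, to = outputs)
    )
  }
  pats <- list(
    `1` = edges(base, base),
    `2` = edges(),
    `3` = edges(outputs = base),
    `4` = edges(inputs = base),
    `5` = edges(inputs = base, outputs = keep(lat)),
    `6` = edges(inputs = keep(lat), outputs = base),
    `7` = edges(inputs = keep(lat)),
    `8` = edges(outputs = keep(lat)),
    `9` = edges(inputs = base, outputs = keep(med)),
    `10` = edges(inputs = keep(med), outputs = base),
    `11` = edges(inputs = keep(med)),
    `12` = edges(outputs = keep(med))
  )
  pats
}

# Apply an edge template to a base mask extended with the new region.
extend_mask <- function(base_spec, new_region, edge_set) {
  regions <- c(base_spec$regions, new_region)
  n <- length(regions)
  mask <- matrix(0, n, n, dimnames = list(regions, regions))
  mask[seq_len(n - 1), seq_len(n - 1)] <- base_spec$mask
  if (!is.null(edge_set) && nrow(edge_set) > 0)
    for (k in seq_len(nrow(edge_set)))
      mask[edge_set[k, "to"], edge_set[k, "from"]] <- 1
  mask
}

#' The full 96-model space with one hippocampal region included
#'
#' Cross product of the 8 base families with the 12 inclusion patterns for
#' `region` (LHIP or RHIP), giving 96 five-node models named
#' `<family>_<pattern>` (e.g. `a_6`).
#'
#' @param region added region, `"LHIP"` or `"RHIP"`.
#' @return list of 96 `model_spec` objects, names `a_1` .. `h_12`.
#' @export
full_space <- function(region = c("LHIP", "RHIP")) {
  region <- match.arg(region)
  fams <- base_families()
  pats <- inclusion_patterns(region)
  out <- list()
  for (fam in names(fams)) {
    for (p in names(pats)) {
      mask <- extend_mask(fams[[fam]], region, pats[[p]])
      spec <- model_spec(c(CORE_REGIONS, region), mask,
                         family = fam, pattern = p)
      out[[spec$name]] <- spec
    }
  }
  out
}

# Deduplicate masks after removing a region from each base family; labels the
# survivors with primed family letters, verifying that exactly the six
# expected distinct topologies remain (c collapses into a, g into e).
reduced_base_families <- function(drop_region = "PCC") {
  fams <- base_families()
  keep <- setdiff(CORE_REGIONS, drop_region)
  red <- lapply(fams, function(s)
    model_spec(keep, s$mask[keep, keep], family = paste0(s$family, "′"),
               pattern = "none"))
  sig <- vapply(red, function(s) paste(s$mask, collapse = ""), "")
  survivors <- red[!duplicated(sig)]
  if (length(survivors) != 6)
    stop("PCC-removed deduplication did not yield 6 families (got ",
         length(survivors), ")")
  expected <- paste0(c("a", "b", "d", "e", "f", "h"), "′")
  got <- unname(vapply(survivors, `[[`, "", "family"))
  if (!setequal(got, expected))
    stop("unexpected surviving family labels: ", paste(got, collapse = ", "))
  survivors
}

#' The reduced 72-model space: LHIP included, PCC removed
#'
#' Removing PCC from the 8 base families leaves only 6 distinct topologies
#' (c collapses into a and g into e), labelled a', e', b', f', d', h'.
#' Crossing these with the 12 PCC-free inclusion patterns for LHIP gives 72
#' four-node models.
#'
#' @return list of 72 `model_spec` objects over mPFC, LIPC, RIPC, LHIP.
#' @export
reduced_space <- function() {
  fams <- reduced_base_families("PCC")
  base <- setdiff(CORE_REGIONS, "PCC")
  pats <- inclusion_patterns("LHIP", base)
  out <- list()
  for (fam in fams) {
    for (p in names(pats)) {
      mask <- extend_mask(fam, "LHIP", pats[[p]])
      spec <- model_spec(c(base, "LHIP"), mask, family = fam$family,
                         pattern = paste0(p, "′"),
                         name = paste0(fam$family, "_", p, "′"))
      out[[spec$name]] <- spec
    }
  }
  out
}

#' Six-node model combining the best LHIP and RHIP inclusions
#'
#' Base family `a` (complete digraph over the four core nodes), pattern 1
#' (full reciprocal inclusion) for RHIP and pattern 6 (inputs from
#' LIPC/RIPC, outputs to all) for LHIP, plus both inter-hippocampal
#' connections, which lets the inversion shrink whichever direction the data
#' do not support.
#'
#' @return a 6-region `model_spec` named `a_1+6`.
#' @export
combine_best <- function() {
  regions <- c(CORE_REGIONS, "LHIP", "RHIP")
  fam_a <- base_families()[["a"]]
  n <- length(regions)
  mask <- matrix(0, n, n, dimnames = list(regions, regions))
  mask[CORE_REGIONS, CORE_REGIONS] <- fam_a$mask
  for (e in list(inclusion_patterns("RHIP")[["1"]],
                 inclusion_patterns("LHIP")[["6"]]))
    for (k in seq_len(nrow(e))) mask[e[k, "to"], e[k, "from"]] <- 1
  mask["RHIP", "LHIP"] <- 1
  mask["LHIP", "RHIP"] <- 1
  model_spec(regions, mask, family = "a", pattern = "1+6", name = "a_1+6")
}
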