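#' Variant-by-score feature tables
#'
#' A `feature_matrix` couples a numeric variants x scores matrix with a
#' feature specification (name, group, provenance, direction) and the
#' missingness mask recorded before imputation. Two feature groups are
#' distinguished, mirroring the ACMG evidence classes they feed:
#' `functional` (assay readouts; strong evidence) and `computational`
#' (in-silico predictors; supporting evidence).
#'
#' @name feature_table
NULL

#' Construct a feature matrix
#'
#' @param values Numeric matrix, rownames = variant keys, colnames = feature
#'   names. `NA` marks missing scores.
#' @param spec data.frame with columns `name`, `group`
#'   (`"functional"`/`"computational"`), and optionally `source`,
#'   `direction`. Defaults to [default_feature_spec()] restricted to the
#'   matrix columns; columns absent from the default spec are grouped
#'   `computational`.
#' @return An object of class `feature_matrix` with elements `values`,
#'   `mask` (TRUE where observed), `spec`, `imputed` (flag).
#' @export
feature_matrix <- function(values, spec = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) stop("feature matrix needs variant rownames")
  if (is.null(colnames(values))) stop("feature matrix needs feature colnames")
  if (is.null(spec)) {
    def <- default_feature_spec()
    spec <- def[match(colnames(values), def$name), ]
    miss <- is.na(spec$name)
    spec$name[miss] <- colnames(values)[miss]
    spec$group[miss] <- "computational"
    spec$source[miss] <- "user"
    spec$direction[miss] <- "higher_deleterious"
    rownames(spec) <- NULL
  }
  spec <- as.data.frame(spec)
  require_columns(spec, c("name", "group"), "feature spec")
  if (!all(colnames(values) %in% spec$name)) {
    stop("feature spec is missing entries for: ",
         paste(setdiff(colnames(values), spec$name), collapse = ", "))
  }
  spec <- spec[match(colnames(values), spec$name), , drop = FALSE]
  if (anyDuplicated(spec$name)) stop("duplicate feature names in spec")
  if (!all(spec$group %in% c("functional", "computational"))) {
    stop("feature groups must be 'functional' or 'computational'")
  }
  structure(
    list(values = values, mask = !is.na(values), spec = spec,
         imputed = !anyNA(values)),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$values), "variants x", ncol(x$values),
      "features\n")
  cat("  functional:", sum(x$spec$group == "functional"),
      "  computational:", sum(x$spec$group == "computational"), "\n")
  cat(sprintf("  missing entries: %d (%.1f%%)%s\n",
              sum(!x$mask), 100 * mean(!x$mask),
              if (x$imputed) ", imputed" else ""))
  invisible(x)
}

#' Default 42-feature specification
#'
#' The default layout mirrors the score set used for TP53 functionality
#' profiling: 14 functional-assay readouts (8 yeast promoter-specific
#' transactivation activities plus their average and median, one mammalian
#' cell-cycle-arrest screen readout covering the DNA-binding domain, and
#' three mammalian-screen readouts: dominant-negative activity, loss of
#' function and etoposide response) and 28 computational predictor scores.
#'
#' @return data.frame with columns `name`, `group`, `source`, `direction`.
#' @export
default_feature_spec <- function() {
  promoters <- c("WAF1", "MDM2", "BAX", "14-3-3-s", "AIP1", "GADD45",
                 "NOXA", "P53R2")
  functional <- data.frame(
    name = c(paste0("trans_", promoters), "trans_average", "trans_median",
             "cell_cycle_arrest", "dominant_negative", "lof_screen",
             "etoposide_response"),
    group = "functional",
    source = c(rep("yeast_transactivation", 10L), "mammalian_arrest_screen",
               rep("mammalian_phenotype_screen", 3L)),
    direction = c(rep("lower_deleterious", 11L), "higher_deleterious",
                  "higher_deleterious", "lower_deleterious"),
    stringsAsFactors = FALSE
  )
  comp_names <- c(
    "SIFT", "Polyphen2_HDIV", "Polyphen2_HVAR", "LRT", "MutationTaster",
    "MutationAssessor", "FATHMM", "PROVEAN", "VEST3", "MetaSVM", "MetaLR",
    "M-CAP", "REVEL", "MutPred", "CADD", "DANN", "fathmm-MKL", "Eigen",
    "GenoCanyon", "GERP++", "phyloP100way", "phastCons100way", "SiPhy",
    "integrated_fitCons", "CHASM", "EVE", "Condel", "BayesDel"
  )
  computational <- data.frame(
    name = comp_names, group = "computational",
    source = c(rep("dbNSFP", 24L), rep("other_in_silico", 4L)),
    direction = ifelse(comp_names %in% c("SIFT", "FATHMM", "PROVEAN"),
                       "lower_deleterious", "higher_deleterious"),
    stringsAsFactors = FALSE
  )
  rbind(functional, computational)
}

#' Read a feature table from TSV/CSV
#'
#' First column is the variant key; remaining columns are scores. Empty
#' cells and "NA" read as missing.
#'
#' @param path File path.
#' @param spec Optional feature spec data.frame or path to a YAML spec.
#' @return A `feature_matrix`.
#' @export
read_feature_table <- function(path, spec = NULL) {
  df <- read_table_auto(path)
  if (is.character(spec) && length(spec) == 1L) spec <- read_feature_spec(spec)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1L]]
  feature_matrix(values, spec = spec)
}

#' Read/write a feature specification in YAML
#'
#' @param path File path.
#' @param spec data.frame as returned by [default_feature_spec()].
#' @return The spec data.frame (read) or `path` invisibly (write).
#' @export
read_feature_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(rbind, lapply(raw, function(f) {
    data.frame(name = f$name, group = f$group,
               source = f$source %||% "user",
               direction = f$direction %||% "higher_deleterious",
               stringsAsFactors = FALSE)
  }))
}

#' @rdname read_feature_spec
#' @export
write_feature_spec <- function(spec, path) {
  yaml::write_yaml(unname(apply(spec, 1L, as.list, simplify = FALSE)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Impute missing scores with per-feature medians
#'
#' Each missing cell is replaced by the median of the observed values of its
#' feature. `fit_on` controls which variants the medians are computed from:
#' `"all"` (default, whole-table imputation) or a subset of variant keys
#' (e.g. the training partition, to rule out information leakage into
#' held-out sets).
#'
#' @param m A `feature_matrix`.
#' @param fit_on `"all"` or character vector of variant keys.
#' @return An imputed `feature_matrix`; the pre-imputation mask is retained.
#' @export
impute_median <- function(m, fit_on = "all") {
  stopifnot(inherits(m, "feature_matrix"))
  values <- m$values
  rows <- if (identical(fit_on, "all")) seq_len(nrow(values)) else {
    idx <- match(fit_on, rownames(values))
    if (anyNA(idx)) stop("fit_on names variants absent from the matrix")
    idx
  }
  med <- apply(values[rows, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
  dead <- !is.finite(med)
  if (any(dead)) {
    stop("feature(s) entirely missing within the imputation subset: ",
         paste(colnames(values)[dead], collapse = ", "))
  }
  for (j in seq_len(ncol(values))) {
    nas <- is.na(values[, j])
    if (any(nas)) values[nas, j] <- med[[j]]
  }
  out <- m
  out$values <- values
  out$imputed <- TRUE
  out
}

#' Subset a feature matrix to a named feature set
#'
#' @param m A `feature_matrix`.
#' @param set_id `"all"`, `"functional"` or `"computational"`.
#' @return A `feature_matrix` restricted to the chosen group.
#' @export
select_features <- function(m, set_id = c("all", "functional", "computational")) {
  stopifnot(inherits(m, "feature_matrix"))
  set_id <- match.arg(set_id)
  if (set_id == "all") return(m)
  keep <- m$spec$group == set_id
  out <- m
  out$values <- m$values[, keep, drop = FALSE]
  out$mask <- m$mask[, keep, drop = FALSE]
  out$spec <- m$spec[keep, , drop = FALSE]
  out
}

#' Classical multidimensional scaling of a feature matrix
#'
#' Torgerson (classical) MDS on the Euclidean distance matrix of the
#' imputed feature values, keeping the top two components. Used to check
#' that labeled training variants occupy the same region of score space as
#' the unlabeled remainder. Deterministic up to axis sign.
#'
#' @param m An imputed `feature_matrix` (or plain numeric matrix).
#' @return Matrix of `n x 2` coordinates (class `mds_embedding`), columns
#'   centered at zero.
#' @export
mds_embed <- function(m) {
  values <- if (inherits(m, "feature_matrix")) m$values else as.matrix(m)
  if (anyNA(values)) stop("impute the feature matrix before embedding")
  if (nrow(values) < 3L) stop("MDS embedding needs at least 3 variants")
  coords <- suppressWarnings(stats::cmdscale(stats::dist(values), k = 2L))
  if (ncol(coords) < 2L) {
    # degenerate (e.g. collinear) configurations span < 2 dimensions
    coords <- cbind(coords, matrix(0, nrow(coords), 2L - ncol(coords)))
  }
  colnames(coords) <- c("MDS1", "MDS2")
  class(coords) <- c("mds_embedding", class(coords))
  coords
}
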