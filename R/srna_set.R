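#' Expression set for small RNA count data
#'
#' A lightweight container in the limma `EList` idiom: a numeric
#' feature-by-sample matrix plus a `samples` data frame carrying sample
#' metadata, a `units` tag recording the current expression scale, and an
#' optional feature-to-RNA-class map.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   Row names are annotation labels, column names are sample ids.
#' @param samples data frame with one row per column of `values`; must
#'   contain columns `sample_id`, `donor_id` and `component`. A logical
#'   `is_whole_blood` column is added (default `FALSE`) when absent.
#' @param units one of `"reads"`, `"RPM"`, `"log2RPM"`.
#' @param classes optional named character vector mapping feature labels to
#'   RNA classes.
#'
#' @return An object of class `srna_set`: a list with elements `values`,
#'   `samples`, `units` and `classes`.
#' @export
srna_set <- function(values, samples, units = c("reads", "RPM", "log2RPM"),
                     classes = NULL) {
  units <- match.arg(units)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature labels in `values`")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in `values`")
  if (any(values < 0)) stop("negative expression values")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "donor_id", "component")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("`samples` lacks required column(s): ", paste(miss, collapse = ", "))
  if (!"is_whole_blood" %in% names(samples)) samples$is_whole_blood <- FALSE
  if (nrow(samples) != ncol(values))
    stop("`samples` rows must match `values` columns")
  if (!identical(as.character(samples$sample_id), colnames(values)))
    stop("`samples$sample_id` must equal colnames(values) in order")
  if (!is.null(classes)) {
    classes <- classes[rownames(values)]
    if (anyNA(classes)) stop("`classes` does not cover every feature")
    names(classes) <- rownames(values)
  }
  structure(list(values = values, samples = samples, units = units,
                 classes = classes),
            class = "srna_set")
}

#' @export
print.srna_set <- function(x, ...) {
  cat(sprintf("srna_set: %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$units))
  comp <- table(x$samples$component)
  cat("components:", paste(sprintf("%s (%d)", names(comp), comp),
                           collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.srna_set <- function(x) dim(x$values)

#' Subset an expression set by features and/or samples
#'
#' Keeps the sample metadata and feature class map in step with the
#' matrix.
#'
#' @param x an [srna_set()].
#' @param features,samples row/column indices (numeric, logical, or
#'   names); `NULL` keeps everything.
#' @return The subset [srna_set()].
#' @export
subset_set <- function(x, features = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  smp <- x$samples[match(colnames(v), x$samples$sample_id), , drop = FALSE]
  rownames(smp) <- NULL
  srna_set(v, smp, x$units,
           classes = if (is.null(x$classes)) NULL else x$classes[rownames(v)])
}

stopifnot_units <- function(x, units) {
  if (!inherits(x, "srna_set")) stop("expected an `srna_set` object")
  if (!identical(x$units, units))
    stop(sprintf("expected units '%s' but got '%s'", units, x$units))
  invisible(x)
}
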