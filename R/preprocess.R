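#' Inclusion filter on sequence-level records
#'
#' Keeps a sequence iff it is longer than `min_len_exclusive` nucleotides
#' AND it has at least one read in at least `min_samples` samples of at
#' least one blood component type.
#'
#' @param records a [seq_records()] object.
#' @param sample_meta data frame mapping `sample_id` to `component` for
#'   every count column.
#' @param min_samples minimum number of samples with >= 1 read within a
#'   single component (default 3).
#' @param min_len_exclusive length threshold; sequences must be strictly
#'   longer (default 17 nt).
#' @return The filtered `seq_records` object.
#' @export
prefilter_sequences <- function(records, sample_meta, min_samples = 3,
                                min_len_exclusive = 17) {
  stopifnot(inherits(records, "seq_records"))
  idx <- match(colnames(records$counts), sample_meta$sample_id)
  if (anyNA(idx))
    stop("sample(s) without component metadata: ",
         paste(setdiff(colnames(records$counts), sample_meta$sample_id),
               collapse = ", "))
  comp <- as.character(sample_meta$component[idx])
  detected <- records$counts > 0
  # per component: number of samples with >= 1 read, for every sequence
  n_by_comp <- vapply(unique(comp), function(cc)
    rowSums(detected[, comp == cc, drop = FALSE]), numeric(nrow(detected)))
  if (is.null(dim(n_by_comp))) n_by_comp <- matrix(n_by_comp, nrow = 1)
  pass_reads <- apply(n_by_comp >= min_samples, 1, any)
  len <- records$assignments$length_nt[
    match(rownames(records$counts), records$assignments$seq_id)]
  keep <- rownames(records$counts)[pass_reads & len > min_len_exclusive]
  seq_records(
    records$assignments[records$assignments$seq_id %in% keep, , drop = FALSE],
    records$counts[keep, , drop = FALSE])
}

#' Reads-per-million normalization
#'
#' Scales every sample column so it sums to one million reads.
#'
#' @param x an [srna_set()] in `reads` units.
#' @return The set in `RPM` units.
#' @export
rpm_normalize <- function(x) {
  stopifnot_units(x, "reads")
  libsize <- colSums(x$values)
  zero <- colnames(x$values)[libsize == 0]
  if (length(zero))
    stop("sample(s) with zero library size: ", paste(zero, collapse = ", "))
  x$values <- sweep(x$values, 2, libsize, "/") * 1e6
  x$units <- "RPM"
  x
}

#' log2(RPM + 1) transform
#'
#' @param x an [srna_set()] in `RPM` units.
#' @return The set in `log2RPM` units.
#' @export
log_transform <- function(x) {
  stopifnot_units(x, "RPM")
  x$values <- log2(x$values + 1)
  x$units <- "log2RPM"
  x
}

#' Discard low-expressed features
#'
#' Removes every feature whose expression never reaches `threshold` RPM.
#' The comparison is strict: a feature whose maximum (or mean, see
#' `method`) RPM is `< threshold` is dropped; exactly `threshold` is kept.
#'
#' @param x an [srna_set()] in `RPM` units.
#' @param threshold RPM cutoff (default 2).
#' @param method `"max"` (default) drops features with max RPM below the
#'   cutoff in every sample; `"mean"` uses the feature mean instead.
#' @return The filtered set, still in `RPM` units.
#' @export
low_expression_filter <- function(x, threshold = 2,
                                  method = c("max", "mean")) {
  stopifnot_units(x, "RPM")
  method <- match.arg(method)
  stat <- if (method == "max") apply(x$values, 1, max)
          else rowMeans(x$values)
  keep <- which(stat >= threshold)
  subset_set(x, features = keep)
}
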