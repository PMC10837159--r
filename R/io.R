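# canonical dialect: TSV, UTF-8, '.' decimal separator, one header line

#' Write / read a data frame as canonical TSV
#'
#' @param x data frame.
#' @param path file path.
#' @return `read_tsv_table` returns a data frame; `write_tsv_table`
#'   returns `path` invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}

#' @rdname write_tsv_table
#' @param required_cols columns that must be present; an error lists any
#'   that are missing.
#' @export
read_tsv_table <- function(path, required_cols = NULL) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8", na.strings = "NA")
  if (!is.null(required_cols)) {
    miss <- setdiff(required_cols, names(x))
    if (length(miss))
      stop("table ", path, " lacks required column(s): ",
           paste(miss, collapse = ", "))
  }
  x
}

#' Write / read an expression set as TSV plus sidecars
#'
#' The matrix goes to `<prefix>_matrix.tsv` (feature rows, first column
#' `feature`), sample metadata to `<prefix>_samples.tsv`, and a small
#' metadata sidecar (units, optional feature classes) to
#' `<prefix>_meta.tsv`.
#'
#' @param x an [srna_set()].
#' @param prefix path prefix for the three files.
#' @return `read_srna_set` returns an [srna_set()]; `write_srna_set`
#'   returns `prefix` invisibly.
#' @export
write_srna_set <- function(x, prefix) {
  stopifnot(inherits(x, "srna_set"))
  mat <- data.frame(feature = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_table(mat, paste0(prefix, "_matrix.tsv"))
  write_tsv_table(x$samples, paste0(prefix, "_samples.tsv"))
  meta <- data.frame(feature = rownames(x$values),
                     rna_class = if (is.null(x$classes)) NA_character_
                                 else unname(x$classes[rownames(x$values)]),
                     units = x$units, stringsAsFactors = FALSE)
  write_tsv_table(meta, paste0(prefix, "_meta.tsv"))
  invisible(prefix)
}

#' @rdname write_srna_set
#' @export
read_srna_set <- function(prefix) {
  mat <- read_tsv_table(paste0(prefix, "_matrix.tsv"),
                        required_cols = "feature")
  smp <- read_tsv_table(paste0(prefix, "_samples.tsv"),
                        required_cols = c("sample_id", "donor_id",
                                          "component"))
  meta <- read_tsv_table(paste0(prefix, "_meta.tsv"),
                         required_cols = c("feature", "units"))
  v <- as.matrix(mat[, -1, drop = FALSE])
  rownames(v) <- mat$feature
  cls <- if (all(is.na(meta$rna_class))) NULL
         else stats::setNames(meta$rna_class, meta$feature)
  srna_set(v, smp, units = meta$units[1], classes = cls)
}

#' Write a sequence-level assignment table
#'
#' One row per candidate annotation; read counts repeat across a
#' sequence's candidate rows and are taken from the first occurrence when
#' read back.
#'
#' @param records a [seq_records()] object.
#' @param path TSV path.
#' @return `read_assignment_table` returns a [seq_records()] object.
#' @export
write_assignment_table <- function(records, path) {
  stopifnot(inherits(records, "seq_records"))
  asn <- records$assignments
  cnt <- records$counts[asn$seq_id, , drop = FALSE]
  write_tsv_table(cbind(asn, as.data.frame(cnt, check.names = FALSE)), path)
  invisible(path)
}

#' @rdname write_assignment_table
#' @export
read_assignment_table <- function(path) {
  x <- read_tsv_table(path, required_cols = c("seq_id", "length_nt",
                                              "rna_class", "parent_gene",
                                              "start_pos"))
  meta_cols <- c("seq_id", "length_nt", "rna_class", "parent_gene",
                 "start_pos")
  first <- !duplicated(x$seq_id)
  cnt <- as.matrix(x[first, setdiff(names(x), meta_cols), drop = FALSE])
  if (!is.numeric(cnt)) stop("malformed numeric count cell in ", path)
  rownames(cnt) <- x$seq_id[first]
  seq_records(x[, meta_cols], cnt)
}

#' Write a simulated cohort to a directory
#'
#' Donors, blood counts, sorting metrics and counts as plain TSV; the
#' ground truth additionally as feature-keyed TSV sidecars.
#'
#' @param cohort output of [simulate_cohort()].
#' @param records optional [seq_records()] from [simulate_counts()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, records = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_table(cohort$donors, file.path(dir, "donors.tsv"))
  bc <- data.frame(donor_id = rownames(cohort$blood_counts),
                   cohort$blood_counts, check.names = FALSE)
  write_tsv_table(bc, file.path(dir, "blood_counts.tsv"))
  write_tsv_table(cohort$sort_samples, file.path(dir, "sort_samples.tsv"))
  tr <- cohort$truth
  prof <- data.frame(feature = colnames(tr$component_profiles),
                     t(tr$component_profiles), check.names = FALSE)
  write_tsv_table(prof, file.path(dir, "truth_profiles.tsv"))
  contrib <- data.frame(feature = rownames(tr$true_contributions),
                        tr$true_contributions, check.names = FALSE)
  write_tsv_table(contrib, file.path(dir, "truth_contributions.tsv"))
  write_tsv_table(data.frame(feature = names(tr$marker_map),
                             marker_component = unname(tr$marker_map)),
                  file.path(dir, "truth_markers.tsv"))
  write_tsv_table(tr$alpha, file.path(dir, "truth_alpha.tsv"))
  write_tsv_table(data.frame(sample_id = tr$outlier_samples),
                  file.path(dir, "truth_outliers.tsv"))
  if (!is.null(records))
    write_assignment_table(records, file.path(dir, "assignments.tsv"))
  invisible(dir)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Executes simulate -> annotate/collapse -> prefilter -> QC -> normalize
#' -> low-expression filter -> deconvolve -> profiles -> markers, writing
#' every intermediate table plus a JSON run manifest into `out_dir`.
#' Re-running with an identical config reproduces byte-identical tables.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param qc_seed seed for the embedding stage.
#' @return List with the fitted `blood_deconv` object, the `qc_report`,
#'   the final expression sets, and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, qc_seed = config$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- stage("simulate", simulate_cohort(config))
  records <- stage("simulate", simulate_counts(cohort, config))
  write_cohort(cohort, records, file.path(out_dir, "cohort"))

  smeta <- cohort$sort_samples[, c("sample_id", "donor_id", "component")]
  records <- stage("prefilter", prefilter_sequences(records, smeta))
  counts <- stage("annotate", collapse_counts(records, smeta))
  write_srna_set(counts, file.path(out_dir, "counts"))

  rpm <- stage("normalize", rpm_normalize(counts))
  logm <- log_transform(rpm)
  qc <- stage("qc", qc_samples(logm, cohort$sort_samples, seed = qc_seed))
  write_tsv_table(data.frame(sample_id = rownames(qc$embedding),
                             qc$embedding),
                  file.path(out_dir, "embedding.tsv"))
  write_tsv_table(data.frame(
    sample_id = c(qc$excluded_purity, qc$excluded_embedding),
    reason = c(rep("purity", length(qc$excluded_purity)),
               rep("embedding", length(qc$excluded_embedding)))),
    file.path(out_dir, "qc_exclusions.tsv"))

  keep <- match(qc$pass, colnames(rpm$values))
  rpm_pass <- subset_set(rpm, samples = keep)
  rpm_filt <- stage("normalize", low_expression_filter(rpm_pass))
  write_srna_set(rpm_filt, file.path(out_dir, "rpm"))

  contents <- stage("deconvolve",
                    sample_contents(cohort$sort_samples,
                                    cohort$blood_counts,
                                    config$plasma_fraction))
  fit <- stage("deconvolve", blood_deconv(rpm_filt, contents))
  write_tsv_table(data.frame(feature = rownames(fit$P), fit$P,
                             check.names = FALSE),
                  file.path(out_dir, "contributions.tsv"))
  write_tsv_table(data.frame(feature = rownames(fit$xbar), fit$xbar,
                             check.names = FALSE),
                  file.path(out_dir, "scaled_means.tsv"))

  prof <- stage("profile", component_profile(rpm_filt))
  write_tsv_table(prof, file.path(out_dir, "profiles.tsv"))
  cprof <- stage("profile", class_profile(rpm_filt))
  write_tsv_table(cprof, file.path(out_dir, "class_profiles.tsv"))
  markers <- stage("markers",
                   overrepresented_srnas(log_transform(rpm_filt)))
  write_tsv_table(markers, file.path(out_dir, "markers.tsv"))

  manifest <- list(
    config = unclass(config)[setdiff(names(config),
                                     c("blood_count_means",
                                       "content_per_cell"))],
    qc_seed = qc_seed,
    n_samples = list(input = qc$n_input, pass = qc$n_pass),
    input_checksums = vapply(list.files(file.path(out_dir, "cohort"),
                                        full.names = TRUE),
                             function(f) unname(tools::md5sum(f)),
                             character(1)))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(out_dir, "manifest.json"))
  list(fit = fit, qc = qc, rpm = rpm_filt, counts = counts,
       markers = markers, out_dir = out_dir)
}
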