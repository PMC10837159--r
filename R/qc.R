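#' Purity filter for sorted cellular fractions
#'
#' A cellular fraction enters the dataset only if its flow-cytometry purity
#' exceeds `threshold_pct` (strictly). Plasma and whole-blood samples carry
#' no sorting purity and bypass the filter.
#'
#' @param sort_samples data frame of sorting metrics with columns
#'   `sample_id`, `component`, `purity_pct` (NA allowed for plasma).
#' @param threshold_pct purity cutoff in percent (default 70).
#' @param plasma_components component names exempt from the filter.
#' @return List with character vectors `pass` and `fail` of sample ids.
#' @export
purity_filter <- function(sort_samples, threshold_pct = 70,
                          plasma_components = c("plasma", "whole_blood")) {
  cellular <- !(sort_samples$component %in% plasma_components)
  if (anyNA(sort_samples$purity_pct[cellular]))
    stop("missing purity for cellular fraction(s): ",
         paste(sort_samples$sample_id[cellular &
               is.na(sort_samples$purity_pct)], collapse = ", "))
  fail <- cellular & sort_samples$purity_pct <= threshold_pct
  list(pass = as.character(sort_samples$sample_id[!fail]),
       fail = as.character(sort_samples$sample_id[fail]))
}

#' Two-dimensional t-SNE embedding of samples
#'
#' Embeds samples of a log-scale expression set into two dimensions with
#' t-distributed stochastic neighbour embedding. Deterministic given
#' `seed`; perplexity is reduced automatically when few samples are
#' available.
#'
#' @param x an [srna_set()] in `log2RPM` units.
#' @param seed integer RNG seed.
#' @param perplexity t-SNE perplexity (default 30, capped at
#'   `(n - 1) / 3`).
#' @return Numeric matrix (samples x 2) with sample ids as row names.
#' @export
embed_samples <- function(x, seed = 1, perplexity = 30) {
  stopifnot_units(x, "log2RPM")
  n <- ncol(x$values)
  if (n < 4) stop("need at least 4 samples to embed")
  perplexity <- min(perplexity, floor((n - 1) / 3))
  if (perplexity < 1)
    stop("too few samples for any valid perplexity; need n >= 4")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fit <- Rtsne::Rtsne(t(x$values), dims = 2, perplexity = perplexity,
                      pca = TRUE, partial_pca = FALSE, check_duplicates = FALSE,
                      max_iter = 500, verbose = FALSE, num_threads = 1)
  coords <- fit$Y
  rownames(coords) <- colnames(x$values)
  colnames(coords) <- c("tsne1", "tsne2")
  coords
}

#' Flag samples that do not cluster with their component
#'
#' Operationalizes visual outlier exclusion: in the 2-D embedding, a sample
#' is flagged when fewer than `min_same_frac` of its `k` nearest neighbours
#' (Euclidean) share its component label.
#'
#' @param coords samples x 2 coordinate matrix with sample id row names.
#' @param component_labels character vector of component labels, parallel
#'   to the rows of `coords`.
#' @param k number of neighbours (default 15). Automatically capped at one
#'   less than the smallest component size, so that a correctly labelled
#'   sample in a tight cluster can always reach a same-label majority.
#' @param min_same_frac minimum fraction of same-component neighbours
#'   (default 0.5).
#' @return Character vector of flagged sample ids.
#' @export
flag_outliers <- function(coords, component_labels, k = 15,
                          min_same_frac = 0.5) {
  if (k <= 0) stop("`k` must be positive")
  n <- nrow(coords)
  if (k >= n) stop("`k` must be smaller than the number of samples")
  component_labels <- as.character(component_labels)
  if (length(component_labels) != n)
    stop("`component_labels` must match rows of `coords`")
  k <- max(1L, min(k, min(table(component_labels)) - 1L))
  d <- as.matrix(stats::dist(coords))
  same_frac <- vapply(seq_len(n), function(i) {
    nn <- order(d[i, ])[-1][seq_len(k)]   # drop self
    mean(component_labels[nn] == component_labels[i])
  }, numeric(1))
  rownames(coords)[same_frac < min_same_frac]
}

#' Sample quality control: purity and embedding outliers
#'
#' Runs the full QC stage: purity filtering of sorting metrics, t-SNE
#' embedding of the purity-passing samples, and kNN-majority outlier
#' flagging.
#'
#' @param x an [srna_set()] in `log2RPM` units (component fractions only).
#' @param sort_samples sorting-metrics data frame (see [purity_filter()]).
#' @param purity_threshold purity cutoff in percent.
#' @param k,min_same_frac outlier-flagging parameters, see
#'   [flag_outliers()].
#' @param perplexity t-SNE perplexity.
#' @param seed RNG seed recorded in the report.
#' @return A `qc_report` list: `excluded_purity`, `excluded_embedding`,
#'   `pass`, `n_input`, `n_pass`, `embedding`, `parameters`.
#' @export
qc_samples <- function(x, sort_samples, purity_threshold = 70, k = 15,
                       min_same_frac = 0.5, perplexity = 30, seed = 1) {
  stopifnot_units(x, "log2RPM")
  pur <- purity_filter(sort_samples, purity_threshold)
  keep <- intersect(colnames(x$values), pur$pass)
  x_pass <- subset_set(x, samples = match(keep, colnames(x$values)))
  coords <- embed_samples(x_pass, seed = seed, perplexity = perplexity)
  flagged <- flag_outliers(coords, x_pass$samples$component, k = k,
                           min_same_frac = min_same_frac)
  n_input <- ncol(x$values)
  pass <- setdiff(keep, flagged)
  structure(list(
    excluded_purity = intersect(colnames(x$values), pur$fail),
    excluded_embedding = flagged,
    pass = pass,
    n_input = n_input,
    n_pass = length(pass),
    embedding = coords,
    parameters = list(purity_threshold = purity_threshold, k = k,
                      min_same_frac = min_same_frac,
                      perplexity = perplexity, seed = seed)),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Sample quality control\n")
  cat(sprintf("  input samples:        %d\n", x$n_input))
  cat(sprintf("  excluded (purity):    %d (%.1f%%)\n",
              length(x$excluded_purity),
              100 * length(x$excluded_purity) / max(x$n_input, 1)))
  n_embed <- x$n_input - length(x$excluded_purity)
  cat(sprintf("  excluded (embedding): %d (%.1f%%)\n",
              length(x$excluded_embedding),
              100 * length(x$excluded_embedding) / max(n_embed, 1)))
  cat(sprintf("  passing:              %d\n", x$n_pass))
  invisible(x)
}
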