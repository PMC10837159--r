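#' Relative sRNA profile per blood component
#'
#' Mean RPM per feature within each component, divided by the sum of all
#' mean RPM values of that component. Features contributing less than
#' `others_threshold` of a component's profile are pooled into an
#' `"others"` entry.
#'
#' @param x an [srna_set()] in `RPM` units.
#' @param others_threshold proportion below which features are pooled
#'   (default 0.02).
#' @return Data frame with columns `component`, `entry`, `proportion`;
#'   proportions sum to 1 within each component.
#' @export
component_profile <- function(x, others_threshold = 0.02) {
  stopifnot_units(x, "RPM")
  comp <- as.character(x$samples$component)
  out <- lapply(unique(comp), function(cc) {
    j <- which(comp == cc)
    if (!length(j)) stop("component without samples: ", cc)
    m <- rowMeans(x$values[, j, drop = FALSE])
    p <- m / sum(m)
    small <- p < others_threshold
    ent <- c(rownames(x$values)[!small],
             if (any(small)) "others")
    prop <- c(p[!small], if (any(small)) sum(p[small]))
    data.frame(component = cc, entry = ent, proportion = unname(prop),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Class-aggregated sRNA profile per blood component
#'
#' RPM values of all features of the same RNA class are summed per sample
#' first; class sums are then averaged within each component and
#' normalized to proportions. (Sum-then-mean, not mean-then-sum.)
#'
#' @param x an [srna_set()] in `RPM` units with a feature class map
#'   (or supply `class_map`).
#' @param class_map optional named character vector feature -> RNA class.
#' @return Data frame `component`, `entry` (RNA class), `proportion`.
#' @export
class_profile <- function(x, class_map = NULL) {
  stopifnot_units(x, "RPM")
  if (is.null(class_map)) class_map <- x$classes
  if (is.null(class_map)) stop("no feature class map available")
  cls <- class_map[rownames(x$values)]
  if (anyNA(cls))
    stop("feature(s) without RNA class: ",
         paste(rownames(x$values)[is.na(cls)], collapse = ", "))
  per_sample <- rowsum(x$values, group = cls)   # class x sample sums
  comp <- as.character(x$samples$component)
  out <- lapply(unique(comp), function(cc) {
    m <- rowMeans(per_sample[, comp == cc, drop = FALSE])
    data.frame(component = cc, entry = rownames(per_sample),
               proportion = unname(m / sum(m)), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Overrepresented sRNAs per blood component (one-vs-rest Wilcoxon)
#'
#' For every component, each feature's log2(RPM+1) expression in that
#' component's samples is compared against all other samples with a
#' two-sided Wilcoxon rank-sum test; p-values are Benjamini-Hochberg
#' adjusted across features within the component. A feature passes when
#' its fold change is positive, the adjusted p-value is below `alpha`, and
#' it is expressed (RPM > 0) in every sample of the component.
#'
#' @param x an [srna_set()] in `log2RPM` units (component fractions).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param min_lfc minimum log2 fold change; the default 0 requires any
#'   increase.
#' @return Data frame with one row per (component, feature):
#'   `component`, `feature`, `log2_fold_change`, `p_value`, `adj_p_value`,
#'   `expressed_in_all_group_samples`, `passes`. Fold change is
#'   `log2((mean RPM group + 1) / (mean RPM rest + 1))`.
#' @export
overrepresented_srnas <- function(x, alpha = 0.05, min_lfc = 0) {
  stopifnot_units(x, "log2RPM")
  comp <- as.character(x$samples$component)
  counts <- table(comp)
  if (any(counts < 2))
    stop("component(s) with fewer than 2 samples: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  rpm <- 2^x$values - 1    # invert the log for fold changes / detection
  out <- lapply(unique(comp), function(cc) {
    grp <- comp == cc
    pv <- apply(x$values, 1, function(v)
      suppressWarnings(stats::wilcox.test(v[grp], v[!grp])$p.value))
    mg <- rowMeans(rpm[, grp, drop = FALSE])
    mr <- rowMeans(rpm[, !grp, drop = FALSE])
    lfc <- log2((mg + 1) / (mr + 1))
    in_all <- apply(rpm[, grp, drop = FALSE] > 0, 1, all)
    adj <- stats::p.adjust(pv, method = "BH")
    data.frame(component = cc, feature = rownames(x$values),
               log2_fold_change = lfc, p_value = pv, adj_p_value = adj,
               expressed_in_all_group_samples = in_all,
               passes = lfc > min_lfc & adj < alpha & in_all,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Features detected in every sample of a component
#'
#' Benchmark-style detection: a feature counts as detected in a component
#' only when its read count is non-zero in all of that component's
#' samples.
#'
#' @param x an [srna_set()] (any units; non-zero is scale-invariant).
#' @return Named list component -> character vector of detected features.
#' @export
detection_set <- function(x) {
  comp <- as.character(x$samples$component)
  sapply(unique(comp), function(cc) {
    all_pos <- apply(x$values[, comp == cc, drop = FALSE] > 0, 1, all)
    rownames(x$values)[all_pos]
  }, simplify = FALSE)
}

#' Correlation of whole-blood expression with blood counts
#'
#' Pearson correlation, across donors, of each feature's whole-blood RPM
#' value with each cell type's blood count. Pairs where either side has
#' zero variance are reported as `NA`.
#'
#' @param x an [srna_set()] in `RPM` units of whole-blood samples, one per
#'   donor.
#' @param blood_counts numeric matrix donors x cell types (cells/ul),
#'   row names donor ids.
#' @return Numeric matrix features x cell types of Pearson r.
#' @export
whole_blood_correlation <- function(x, blood_counts) {
  stopifnot_units(x, "RPM")
  donors <- as.character(x$samples$donor_id)
  shared <- intersect(donors, rownames(blood_counts))
  if (length(shared) < 3)
    stop("need at least 3 donors with both expression and blood counts")
  e <- x$values[, match(shared, donors), drop = FALSE]
  b <- blood_counts[shared, , drop = FALSE]
  r <- suppressWarnings(stats::cor(t(e), b, method = "pearson"))
  r[!is.finite(r)] <- NA_real_
  r
}

#' Per-component correlation of mean expression between two datasets
#'
#' For each component present in both sets, the mean log2(RPM+1)
#' expression of every shared feature is computed per dataset and the
#' Pearson correlation of the two mean vectors is returned.
#'
#' @param a,b [srna_set()] objects in `RPM` units.
#' @param shared_features optional character vector restricting the
#'   comparison; defaults to the intersection of feature labels.
#' @return Named numeric vector of Pearson r per shared component.
#' @export
mean_expression_correlation <- function(a, b, shared_features = NULL) {
  stopifnot_units(a, "RPM"); stopifnot_units(b, "RPM")
  if (is.null(shared_features))
    shared_features <- intersect(rownames(a$values), rownames(b$values))
  if (length(shared_features) < 3)
    stop("need at least 3 shared features")
  comps <- intersect(unique(a$samples$component),
                     unique(b$samples$component))
  vapply(comps, function(cc) {
    ma <- rowMeans(log2(a$values[shared_features,
             a$samples$component == cc, drop = FALSE] + 1))
    mb <- rowMeans(log2(b$values[shared_features,
             b$samples$component == cc, drop = FALSE] + 1))
    stats::cor(ma, mb)
  }, numeric(1))
}
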