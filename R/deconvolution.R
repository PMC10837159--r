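#' Small RNA content of a sorted cellular fraction
#'
#' The sRNA mass attributable to one blood cell type per microliter of
#' whole blood: eluted mass (concentration times elution volume) divided by
#' the number of sorted cells gives the mass per cell, which is scaled to
#' blood volume by the donor's blood count of that cell type.
#'
#' @param c_srna sRNA concentration of the eluate, pg/ul.
#' @param v_elution elution volume, ul.
#' @param n_blood_count donor blood count of the cell type, cells/ul blood.
#' @param n_sorted_count number of sorted cells in the fraction.
#' @return sRNA content in pg per ul blood:
#'   `c_srna * v_elution * n_blood_count / n_sorted_count`.
#' @export
srna_content_cell <- function(c_srna, v_elution, n_blood_count,
                              n_sorted_count) {
  if (any(n_sorted_count == 0, na.rm = TRUE))
    stop("`n_sorted_count` of zero: cannot compute per-cell mass")
  bad <- c(c_srna < 0, v_elution < 0, n_blood_count < 0, n_sorted_count < 0)
  if (any(bad, na.rm = TRUE)) stop("content inputs must be non-negative")
  c_srna * v_elution * n_blood_count / n_sorted_count
}

#' Small RNA content of the plasma fraction
#'
#' Eluted sRNA mass per microliter of plasma input, adjusted by the volume
#' fraction of plasma in whole blood.
#'
#' @param c_srna sRNA concentration of the eluate, pg/ul.
#' @param v_elution elution volume, ul.
#' @param v_input plasma volume used for RNA isolation, ul.
#' @param plasma_fraction assumed volume fraction of plasma in blood
#'   (default 0.5).
#' @return sRNA content in pg per ul blood:
#'   `(c_srna * v_elution / v_input) * plasma_fraction`.
#' @export
srna_content_plasma <- function(c_srna, v_elution, v_input,
                                plasma_fraction = 0.5) {
  if (any(v_input == 0, na.rm = TRUE)) stop("`v_input` of zero")
  if (any(plasma_fraction < 0 | plasma_fraction > 1))
    stop("`plasma_fraction` must be in [0, 1]")
  if (any(c(c_srna, v_elution, v_input) < 0, na.rm = TRUE))
    stop("content inputs must be non-negative")
  c_srna * v_elution / v_input * plasma_fraction
}

#' Per-sample sRNA content table
#'
#' Applies [srna_content_cell()] to cellular fractions and
#' [srna_content_plasma()] to plasma fractions, looking up each donor's
#' blood count for the sample's cell type. Samples with missing metrics
#' get `NA` content and are skipped downstream.
#'
#' @param sort_samples data frame with columns `sample_id`, `donor_id`,
#'   `component`, `sorted_count`, `purity_pct`, `elution_volume`,
#'   `srna_conc`, `plasma_input_volume`.
#' @param blood_counts numeric matrix donors x cell types (cells/ul), row
#'   names donor ids, column names matching component names.
#' @param plasma_fraction volume fraction of plasma in blood.
#' @param plasma_component name of the plasma component.
#' @return Data frame `sample_id`, `donor_id`, `component`, `alpha`
#'   (pg sRNA per ul blood, NA when metrics are missing).
#' @export
sample_contents <- function(sort_samples, blood_counts,
                            plasma_fraction = 0.5,
                            plasma_component = "plasma") {
  n <- nrow(sort_samples)
  alpha <- rep(NA_real_, n)
  is_plasma <- sort_samples$component == plasma_component
  for (i in seq_len(n)) {
    cs <- sort_samples$srna_conc[i]
    ve <- sort_samples$elution_volume[i]
    if (is.na(cs) || is.na(ve)) next
    if (is_plasma[i]) {
      vi <- sort_samples$plasma_input_volume[i]
      if (is.na(vi)) next
      alpha[i] <- srna_content_plasma(cs, ve, vi, plasma_fraction)
    } else {
      d <- as.character(sort_samples$donor_id[i])
      cc <- as.character(sort_samples$component[i])
      if (!d %in% rownames(blood_counts) || !cc %in% colnames(blood_counts))
        stop("missing blood count for donor ", d, ", component ", cc)
      nb <- blood_counts[d, cc]
      ns <- sort_samples$sorted_count[i]
      if (is.na(ns)) next
      alpha[i] <- srna_content_cell(cs, ve, nb, ns)
    }
  }
  data.frame(sample_id = as.character(sort_samples$sample_id),
             donor_id = as.character(sort_samples$donor_id),
             component = as.character(sort_samples$component),
             alpha = alpha, stringsAsFactors = FALSE)
}

#' Content-scaled mean expression per component
#'
#' For each blood component b and feature s, the mean over that
#' component's samples of the RPM value scaled by the sample's sRNA
#' content: `xbar[s, b] = (1/D_b) * sum_d x[s, d] * alpha[d]`. Samples
#' without an available content value are excluded from both the sum and
#' `D_b`.
#'
#' @param x an [srna_set()] in `RPM` units (component fractions only).
#' @param contents content table from [sample_contents()].
#' @return List: `xbar` (features x components), `D` (named vector of
#'   per-component sample counts used), `skipped` (sample ids without
#'   content).
#' @export
scaled_mean_expression <- function(x, contents) {
  stopifnot_units(x, "RPM")
  idx <- match(colnames(x$values), contents$sample_id)
  if (anyNA(idx))
    stop("sample(s) without content record: ",
         paste(colnames(x$values)[is.na(idx)], collapse = ", "))
  alpha <- contents$alpha[idx]
  comp <- as.character(contents$component[idx])
  usable <- !is.na(alpha)
  skipped <- colnames(x$values)[!usable]
  components <- unique(comp)
  dead <- setdiff(components, unique(comp[usable]))
  if (length(dead))
    stop("component(s) without any content-bearing sample: ",
         paste(dead, collapse = ", "))
  xbar <- matrix(NA_real_, nrow = nrow(x$values), ncol = length(components),
                 dimnames = list(rownames(x$values), components))
  for (cc in components) {
    j <- which(usable & comp == cc)
    xbar[, cc] <- rowMeans(sweep(x$values[, j, drop = FALSE], 2,
                                 alpha[j], "*"))
  }
  D <- vapply(components, function(cc) sum(usable & comp == cc), integer(1))
  list(xbar = xbar, D = D, skipped = skipped)
}

#' Proportional contributions from scaled mean expression
#'
#' Normalizes each feature's scaled mean expression across components to
#' sum to one. Features whose scaled means are zero in every component get
#' `NA` proportions (counted and warned about).
#'
#' @param xbar features x components matrix of content-scaled means.
#' @return Features x components matrix `P` with rows summing to 1 (or all
#'   NA for undefined features).
#' @export
contribution_proportions <- function(xbar) {
  if (any(xbar < 0)) stop("scaled mean expression must be non-negative")
  tot <- rowSums(xbar)
  P <- xbar / tot
  if (any(tot == 0)) {
    P[tot == 0, ] <- NA_real_
    warning(sum(tot == 0), " feature(s) with all-zero scaled means; ",
            "proportions undefined")
  }
  P
}

#' Deconvolution of whole-blood small RNA profiles by content weighting
#'
#' Fits the forward deconvolution model: each purified component's RPM
#' expression is scaled by its per-sample sRNA content (mass per ul blood),
#' averaged within components, and normalized per feature across
#' components. The resulting proportions estimate how much each blood
#' component contributes to the whole-blood signal of every small RNA.
#'
#' @param x an [srna_set()] of component fractions in `RPM` units
#'   (QC-passed; whole-blood samples are not valid inputs).
#' @param contents content table from [sample_contents()].
#' @return An object of class `blood_deconv` with components:
#'   \describe{
#'     \item{P}{features x components contribution proportions, rows sum
#'       to 1.}
#'     \item{xbar}{features x components content-scaled mean expression.}
#'     \item{mean_rpm}{features x components plain mean RPM (used by
#'       `predict`).}
#'     \item{D}{per-component number of samples used.}
#'     \item{skipped}{sample ids excluded for missing content.}
#'     \item{n_undefined}{features with all-zero scaled means.}
#'   }
#' @seealso [sample_contents()], [scaled_mean_expression()],
#'   [contribution_proportions()]
#' @export
blood_deconv <- function(x, contents) {
  stopifnot_units(x, "RPM")
  if (any(x$samples$is_whole_blood))
    stop("whole-blood samples are predicted by the model, not inputs; ",
         "remove them before fitting")
  sm <- scaled_mean_expression(x, contents)
  P <- withCallingHandlers(
    contribution_proportions(sm$xbar),
    warning = function(w) invokeRestart("muffleWarning"))
  comp <- as.character(contents$component[
    match(colnames(x$values), contents$sample_id)])
  mean_rpm <- sm$xbar
  for (cc in colnames(mean_rpm))
    mean_rpm[, cc] <- rowMeans(x$values[, comp == cc, drop = FALSE])
  structure(list(P = P, xbar = sm$xbar, mean_rpm = mean_rpm, D = sm$D,
                 skipped = sm$skipped,
                 n_undefined = sum(!stats::complete.cases(P)),
                 call = match.call()),
            class = "blood_deconv")
}

#' @export
print.blood_deconv <- function(x, ...) {
  cat("Blood component deconvolution (content-weighted)\n")
  cat(sprintf("  %d features, %d components\n", nrow(x$P), ncol(x$P)))
  cat("  samples used per component:\n")
  print(x$D)
  if (length(x$skipped))
    cat(sprintf("  %d sample(s) skipped (missing sRNA content)\n",
                length(x$skipped)))
  if (x$n_undefined)
    cat(sprintf("  %d feature(s) with undefined proportions\n",
                x$n_undefined))
  invisible(x)
}

#' @export
coef.blood_deconv <- function(object, ...) object$P

#' Summary of a blood deconvolution fit
#'
#' @param object a `blood_deconv` fit.
#' @param ... unused.
#' @return A `summary.blood_deconv` list with the per-component mean
#'   contribution (over defined features), sample counts, and bookkeeping.
#' @export
summary.blood_deconv <- function(object, ...) {
  ok <- stats::complete.cases(object$P)
  structure(list(
    mean_contribution = colMeans(object$P[ok, , drop = FALSE]),
    D = object$D,
    n_features = nrow(object$P),
    n_undefined = object$n_undefined,
    skipped = object$skipped),
    class = "summary.blood_deconv")
}

#' @export
print.summary.blood_deconv <- function(x, ...) {
  cat("Blood component deconvolution\n")
  cat(sprintf("features: %d (%d undefined), skipped samples: %d\n",
              x$n_features, x$n_undefined, length(x$skipped)))
  tab <- data.frame(mean_contribution = round(x$mean_contribution, 4),
                    samples_used = as.integer(x$D[names(x$mean_contribution)]))
  print(tab)
  invisible(x)
}

#' Predict a whole-blood profile from component contents
#'
#' Forms the content-weighted mixture of the fitted per-component mean RPM
#' profiles: the expected relative composition of a whole-blood sample
#' whose per-component sRNA contents (pg per ul blood) are `alpha`.
#'
#' @param object a `blood_deconv` fit.
#' @param alpha named numeric vector of sRNA contents, names covering the
#'   fitted components.
#' @param ... unused.
#' @return Named numeric vector over features, summing to 1.
#' @export
predict.blood_deconv <- function(object, alpha, ...) {
  comps <- colnames(object$mean_rpm)
  if (is.null(names(alpha)) || !all(comps %in% names(alpha)))
    stop("`alpha` must be named and cover all fitted components")
  w <- alpha[comps]
  mix <- as.vector(object$mean_rpm %*% w)
  names(mix) <- rownames(object$mean_rpm)
  mix / sum(mix)
}

#' Plot per-component contribution distributions
#'
#' Boxplots of the per-feature contribution proportions of every blood
#' component.
#'
#' @param x a `blood_deconv` fit.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.blood_deconv <- function(x, ...) {
  ok <- stats::complete.cases(x$P)
  graphics::boxplot(as.data.frame(x$P[ok, , drop = FALSE]),
                    las = 2, ylab = "contribution proportion", ...)
  invisible(x)
}
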