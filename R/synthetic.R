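#' Default blood components
#'
#' The eleven dominant components of human peripheral blood, in the order
#' used throughout the package.
#' @return Character vector of component names.
#' @export
blood_components <- function() {
  c("plasma", "erythrocytes", "thrombocytes", "monocytes", "neutrophils",
    "eosinophils", "basophils", "NK cells", "CD4 T cells", "CD8 T cells",
    "B cells")
}

# typical adult blood counts, cells per ul whole blood
default_blood_counts <- function() {
  c(erythrocytes = 5e6, thrombocytes = 2.5e5, monocytes = 500,
    neutrophils = 4000, eosinophils = 200, basophils = 50,
    "NK cells" = 300, "CD4 T cells" = 900, "CD8 T cells" = 500,
    "B cells" = 250)
}

# assumed sRNA mass per cell (pg); free parameters of the simulation
default_content_per_cell <- function() {
  c(erythrocytes = 0.002, thrombocytes = 0.01, monocytes = 0.10,
    neutrophils = 0.05, eosinophils = 0.08, basophils = 0.08,
    "NK cells" = 0.12, "CD4 T cells" = 0.10, "CD8 T cells" = 0.10,
    "B cells" = 0.10)
}

#' Configuration of a synthetic blood sRNA cohort
#'
#' Collects every knob of the cohort generator. Defaults emulate the
#' study cohort the analysis is designed for: 52 donors, the 11 blood
#' components, 300 features over 8 RNA classes, fraction dropout
#' concentrated on plasma/basophils/eosinophils/thrombocytes (539
#' fractions at n = 52), a 5% purity-failure rate among cellular
#' fractions, ~0.7% mislabeled samples, ~3% missing content metrics, and
#' a plasma volume fraction of 0.5.
#'
#' @param n_donors number of donors (>= 2).
#' @param components ordered character vector of component names; must
#'   contain `plasma_component` if plasma is simulated.
#' @param n_features_per_class named integer vector RNA class -> feature
#'   count.
#' @param marker_fraction fraction of features exclusive to one component.
#' @param library_size expected reads per sample.
#' @param noise_dispersion Dirichlet overdispersion of per-sample
#'   profiles; 0 gives pure multinomial sampling.
#' @param purity_fail_rate fraction of cellular fractions with purity
#'   <= 70%.
#' @param outlier_rate fraction of fractions given a wrong-component
#'   expression profile (mislabeled samples).
#' @param missing_content_rate fraction of QC-passing fractions whose
#'   sRNA concentration is unrecorded.
#' @param plasma_fraction assumed volume fraction of plasma in blood.
#' @param dropout_rates named vector of per-component donor-dropout
#'   rates (fractions of donors whose fraction is not obtained).
#' @param content_noise_sd lognormal sd of measured sRNA concentrations
#'   around their per-cell-content expectation (0 = exact metrics).
#' @param exact_counts if TRUE, counts equal their expectation (no
#'   multinomial sampling); used for noise-free closure checks.
#' @param blood_count_means,content_per_cell named per-component
#'   parameter vectors (cells/ul and pg/cell).
#' @param plasma_srna_per_ul sRNA mass per ul plasma (pg/ul).
#' @param seed integer RNG seed.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_donors = 52,
                       components = blood_components(),
                       n_features_per_class = c(
                         miRNA = 120, tRNA = 40, rRNA = 40, YRNA = 20,
                         snoRNA = 25, lncRNA = 20, snRNA = 15, piRNA = 20),
                       marker_fraction = 0.25,
                       library_size = 1e6,
                       noise_dispersion = 0,
                       purity_fail_rate = 0.05,
                       outlier_rate = 4 / 539,
                       missing_content_rate = 15 / 510,
                       plasma_fraction = 0.5,
                       dropout_rates = c(plasma = 13, basophils = 12,
                                         eosinophils = 5,
                                         thrombocytes = 3) / 52,
                       content_noise_sd = 0.2,
                       exact_counts = FALSE,
                       blood_count_means = default_blood_counts(),
                       content_per_cell = default_content_per_cell(),
                       plasma_srna_per_ul = 10,
                       seed = 1) {
  chk_rate <- function(v, nm) {
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      stop("invalid configuration field `", nm, "`: must be in [0, 1]")
  }
  if (!is.numeric(n_donors) || n_donors < 2)
    stop("invalid configuration field `n_donors`: must be >= 2")
  if (length(components) == 0 || anyDuplicated(components))
    stop("invalid configuration field `components`: ",
         "must be non-empty and unique")
  if (any(n_features_per_class < 1) || is.null(names(n_features_per_class)))
    stop("invalid configuration field `n_features_per_class`")
  bad_cls <- setdiff(names(n_features_per_class), rna_class_priority())
  if (length(bad_cls))
    stop("invalid configuration field `n_features_per_class`: ",
         "unknown class ", paste(bad_cls, collapse = ", "))
  if (library_size <= 0)
    stop("invalid configuration field `library_size`: must be > 0")
  chk_rate(marker_fraction, "marker_fraction")
  chk_rate(purity_fail_rate, "purity_fail_rate")
  chk_rate(outlier_rate, "outlier_rate")
  chk_rate(missing_content_rate, "missing_content_rate")
  chk_rate(plasma_fraction, "plasma_fraction")
  chk_rate(dropout_rates, "dropout_rates")
  if (noise_dispersion < 0)
    stop("invalid configuration field `noise_dispersion`: must be >= 0")
  if (content_noise_sd < 0)
    stop("invalid configuration field `content_noise_sd`: must be >= 0")
  if (length(seed) != 1 || !is.finite(seed) || seed != round(seed))
    stop("invalid configuration field `seed`: must be an integer")
  cellular <- setdiff(components, "plasma")
  missing_bc <- setdiff(cellular, names(blood_count_means))
  if (length(missing_bc))
    stop("invalid configuration field `blood_count_means`: no value for ",
         paste(missing_bc, collapse = ", "))
  missing_ct <- setdiff(cellular, names(content_per_cell))
  if (length(missing_ct))
    stop("invalid configuration field `content_per_cell`: no value for ",
         paste(missing_ct, collapse = ", "))
  structure(list(
    n_donors = as.integer(n_donors), components = components,
    n_features_per_class = n_features_per_class,
    marker_fraction = marker_fraction, library_size = library_size,
    noise_dispersion = noise_dispersion,
    purity_fail_rate = purity_fail_rate, outlier_rate = outlier_rate,
    missing_content_rate = missing_content_rate,
    plasma_fraction = plasma_fraction, dropout_rates = dropout_rates,
    content_noise_sd = content_noise_sd, exact_counts = exact_counts,
    blood_count_means = blood_count_means,
    content_per_cell = content_per_cell,
    plasma_srna_per_ul = plasma_srna_per_ul,
    seed = as.integer(seed)), class = "sim_config")
}

#' Convert a relative subpopulation frequency to an absolute count
#'
#' Absolute blood count of a subpopulation, given its relative frequency
#' within a parent population and the parent's absolute count.
#'
#' @param rel_freq fraction in [0, 1].
#' @param parent_abs absolute count of the parent population, cells/ul.
#' @return `rel_freq * parent_abs`, cells/ul.
#' @examples
#' absolute_subpopulation_counts(0.2, 1000)  # 200
#' @export
absolute_subpopulation_counts <- function(rel_freq, parent_abs) {
  if (any(rel_freq < 0 | rel_freq > 1))
    stop("`rel_freq` must be in [0, 1]")
  if (any(parent_abs < 0)) stop("`parent_abs` must be >= 0")
  rel_freq * parent_abs
}

# feature table: id, class, parent gene, start position, length
make_feature_table <- function(n_features_per_class) {
  rows <- lapply(names(n_features_per_class), function(cls) {
    n <- n_features_per_class[[cls]]
    i <- seq_len(n)
    if (cls %in% c("rRNA", "YRNA")) {
      parents <- if (cls == "rRNA")
        c("RNA18SN5", "RNA28SN1", "RNA45SN1", "RNA5-8SN1")
      else c("RNY1", "RNY3", "RNY4", "RNY5")
      parent <- parents[(i - 1) %% length(parents) + 1]
      bin <- (i - 1) %/% length(parents) + 1
      start <- 25 * (bin - 1) + 1 + (i * 7) %% 25
      data.frame(feature_id = bin_label(parent, start), rna_class = cls,
                 parent_gene = parent, start_pos = start,
                 length_nt = 25 + i %% 9, stringsAsFactors = FALSE)
    } else {
      id <- switch(cls,
        miRNA = sprintf("hsa-miR-9%03d-5p", i),
        tRNA = sprintf("tRF-Gly-GCC-%03d", i),
        snoRNA = sprintf("SNORD9%02d", i),
        lncRNA = sprintf("LINC9%04d", i),
        snRNA = sprintf("RNU6-9%02d", i),
        piRNA = sprintf("piR-9%04d", i))
      data.frame(feature_id = id, rna_class = cls, parent_gene = id,
                 start_pos = NA_real_, length_nt = 18 + i %% 15,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(out$feature_id))
  out
}

# component x feature relative-abundance matrix plus marker map
make_profiles <- function(config, features) {
  n_feat <- nrow(features)
  comps <- config$components
  n_markers <- round(config$marker_fraction * n_feat)
  marker_of <- rep(NA_character_, n_feat)
  if (n_markers > 0)
    marker_of[seq_len(n_markers)] <-
      rep_len(comps, n_markers)  # round-robin over components
  W <- matrix(stats::rlnorm(length(comps) * n_feat, meanlog = 0, sdlog = 1),
              nrow = length(comps), ncol = n_feat,
              dimnames = list(comps, features$feature_id))
  for (s in which(!is.na(marker_of))) {
    W[, s] <- 0
    W[marker_of[s], s] <- stats::rlnorm(1, meanlog = log(20), sdlog = 0.3)
  }
  profiles <- W / rowSums(W)
  names(marker_of) <- features$feature_id
  list(profiles = profiles, marker_map = marker_of)
}

#' Simulate a blood-fraction cohort with ground truth
#'
#' Generates donors (with blood counts), one sorted fraction per donor and
#' component minus configured dropout, sorting/extraction metrics
#' consistent with assumed per-cell sRNA contents, injected purity
#' failures, mislabeled (outlier) fractions, and missing content metrics.
#' All randomness is governed by `config$seed`.
#'
#' @param config a [sim_config()].
#' @return List with elements:
#'   \describe{
#'     \item{donors}{data frame `donor_id`, `group`, `age`, `sex`.}
#'     \item{blood_counts}{matrix donors x cellular components, cells/ul.}
#'     \item{sort_samples}{data frame of per-fraction metrics
#'       (`sample_id`, `donor_id`, `component`, `sorted_count`,
#'       `purity_pct`, `elution_volume`, `srna_conc`,
#'       `plasma_input_volume`).}
#'     \item{truth}{ground truth: `component_profiles`,
#'       `content_per_cell`, `alpha` (exact per-sample contents),
#'       `true_contributions`, `outlier_samples`, `profile_component`
#'       (the component whose profile each sample actually expresses),
#'       `marker_map`, `features`, `analysis_samples`.}
#'   }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  comps <- config$components
  cellular <- setdiff(comps, "plasma")
  n <- config$n_donors

  donor_id <- sprintf("D%03d", seq_len(n))
  group <- sample(rep_len(c(rep("healthy", 12), rep("lung_cancer", 19),
                            rep("non_malignant_lung_disease", 21)), n))
  age <- round(stats::rnorm(n, mean = 63, sd = 8))
  sex <- sample(c("female", "male"), n, replace = TRUE,
                prob = c(0.58, 0.42))
  donors <- data.frame(donor_id, group, age, sex, stringsAsFactors = FALSE)

  bc <- sapply(cellular, function(cc)
    config$blood_count_means[[cc]] *
      stats::rlnorm(n, meanlog = 0, sdlog = 0.2))
  if (is.null(dim(bc))) bc <- matrix(bc, nrow = n,
                                     dimnames = list(NULL, cellular))
  rownames(bc) <- donor_id

  # fraction dropout: per affected component, drop a donor subset
  grid <- expand.grid(donor_id = donor_id, component = comps,
                      stringsAsFactors = FALSE)
  drop_idx <- integer(0)
  for (cc in intersect(names(config$dropout_rates), comps)) {
    n_drop <- round(config$dropout_rates[[cc]] * n)
    if (n_drop > 0) {
      victims <- sample(donor_id, n_drop)
      drop_idx <- c(drop_idx,
                    which(grid$component == cc & grid$donor_id %in% victims))
    }
  }
  if (length(drop_idx)) grid <- grid[-drop_idx, , drop = FALSE]
  ns <- nrow(grid)
  sample_id <- sprintf("S_%s_%s", gsub("[^A-Za-z0-9]", "", grid$component),
                       grid$donor_id)
  is_plasma <- grid$component == "plasma"

  sorted_count <- ifelse(is_plasma, NA_real_,
                         round(stats::rlnorm(ns, meanlog = log(1e6),
                                             sdlog = 0.3)))
  plasma_input <- ifelse(is_plasma, 200, NA_real_)
  elution <- rep(14, ns)

  n_fail <- round(config$purity_fail_rate * sum(!is_plasma))
  fail_set <- if (n_fail > 0) sample(which(!is_plasma), n_fail) else integer(0)
  purity <- ifelse(is_plasma, NA_real_, stats::runif(ns, 85, 99.9))
  purity[fail_set] <- stats::runif(n_fail, 30, 70)

  # measured sRNA concentration consistent with assumed per-cell content
  noise <- exp(stats::rnorm(ns, 0, config$content_noise_sd))
  conc <- numeric(ns)
  for (i in seq_len(ns)) {
    if (is_plasma[i]) {
      conc[i] <- config$plasma_srna_per_ul * plasma_input[i] / elution[i] *
        noise[i]
    } else {
      conc[i] <- config$content_per_cell[[grid$component[i]]] *
        sorted_count[i] / elution[i] * noise[i]
    }
  }

  # exact per-sample content (Eqs. applied to the realized metrics)
  alpha <- ifelse(is_plasma,
                  conc * elution / plasma_input * config$plasma_fraction,
                  conc * elution *
                    bc[cbind(match(grid$donor_id, donor_id),
                             match(grid$component, cellular))] /
                    sorted_count)

  pass_purity <- is_plasma | purity > 70
  n_out <- round(config$outlier_rate * ns)
  out_set <- if (n_out > 0) sample(which(pass_purity), n_out) else integer(0)
  profile_component <- grid$component
  for (i in out_set) {
    alt <- setdiff(comps, grid$component[i])
    profile_component[i] <- alt[(match(grid$component[i], comps)) %%
                                  length(alt) + 1]
  }

  analysis <- pass_purity & !(seq_len(ns) %in% out_set)
  n_miss <- round(config$missing_content_rate * sum(analysis))
  miss_set <- if (n_miss > 0) sample(which(analysis), n_miss) else integer(0)
  conc_obs <- conc
  conc_obs[miss_set] <- NA_real_

  sort_samples <- data.frame(
    sample_id = sample_id, donor_id = grid$donor_id,
    component = grid$component, sorted_count = sorted_count,
    purity_pct = purity, elution_volume = elution, srna_conc = conc_obs,
    plasma_input_volume = plasma_input, stringsAsFactors = FALSE)

  pf <- make_feature_table(config$n_features_per_class)
  pr <- make_profiles(config, pf)

  # expected deconvolution output over the analysis set with content
  usable <- analysis & !is.na(conc_obs)
  abar <- vapply(comps, function(cc)
    mean(alpha[usable & grid$component == cc]), numeric(1))
  xbar_true <- t(pr$profiles * abar * 1e6)   # feature x component
  true_contributions <- xbar_true / rowSums(xbar_true)

  truth <- list(component_profiles = pr$profiles,
                content_per_cell = config$content_per_cell,
                plasma_srna_per_ul = config$plasma_srna_per_ul,
                alpha = data.frame(sample_id = sample_id,
                                   alpha = alpha,
                                   stringsAsFactors = FALSE),
                true_contributions = true_contributions,
                outlier_samples = sample_id[out_set],
                profile_component = stats::setNames(profile_component,
                                                    sample_id),
                marker_map = pr$marker_map,
                features = pf,
                analysis_samples = sample_id[usable])
  list(donors = donors, blood_counts = bc, sort_samples = sort_samples,
       truth = truth)
}

# per-sample sampling probabilities, optionally Dirichlet-perturbed
sample_probs <- function(profile, dispersion) {
  if (dispersion <= 0) return(profile)
  g <- stats::rgamma(length(profile), shape = profile / dispersion)
  if (sum(g) == 0) profile else g / sum(g)
}

#' Simulate sequence-level counts for a cohort
#'
#' Draws each fraction's read counts from its component's ground-truth
#' profile (outlier fractions use their injected wrong-component profile)
#' and wraps them as sequence-level records with candidate annotations, so
#' the annotation stage is exercised: some sequences carry an extra
#' lower-priority decoy candidate, and some features are split over two
#' sequence records that collapse back to one label.
#'
#' @param cohort output of [simulate_cohort()].
#' @param config the same [sim_config()].
#' @return A [seq_records()] object covering all fractions.
#' @export
simulate_counts <- function(cohort, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  truth <- cohort$truth
  ss <- cohort$sort_samples
  pf <- truth$features
  n_feat <- nrow(pf)
  pc <- truth$profile_component[ss$sample_id]
  missing_comp <- setdiff(unique(pc), rownames(truth$component_profiles))
  if (length(missing_comp))
    stop("component(s) absent from profiles: ",
         paste(missing_comp, collapse = ", "))

  counts <- matrix(0, nrow = n_feat, ncol = nrow(ss),
                   dimnames = list(pf$feature_id, ss$sample_id))
  for (j in seq_len(nrow(ss))) {
    p <- sample_probs(truth$component_profiles[pc[j], ],
                      config$noise_dispersion)
    counts[, j] <- if (config$exact_counts) p * config$library_size
                   else stats::rmultinom(1, config$library_size, p)
  }

  split_feat <- seq_len(n_feat) %% 11 == 5   # collapse exercise
  decoy_feat <- seq_len(n_feat) %% 7 == 3 & pf$rna_class != "piRNA"

  seq_id <- paste0("seq_", pf$feature_id)
  asn <- data.frame(seq_id = seq_id, length_nt = pf$length_nt,
                    rna_class = pf$rna_class, parent_gene = pf$parent_gene,
                    start_pos = pf$start_pos, stringsAsFactors = FALSE)
  if (any(decoy_feat)) {
    dec <- asn[decoy_feat, , drop = FALSE]
    dec$rna_class <- "piRNA"
    dec$parent_gene <- sprintf("piR-dec%04d", which(decoy_feat))
    dec$start_pos <- NA_real_
    asn <- rbind(asn, dec)
  }
  cmat <- counts
  rownames(cmat) <- seq_id
  if (any(split_feat)) {
    # second isoform record resolving to the same label
    for (i in which(split_feat)) {
      part <- if (config$exact_counts) 0.4 * cmat[i, ]
              else stats::rbinom(ncol(cmat), round(cmat[i, ]), 0.4)
      cmat[i, ] <- cmat[i, ] - part
      cmat <- rbind(cmat, matrix(part, nrow = 1,
                                 dimnames = list(paste0(seq_id[i], "_iso"),
                                                 colnames(cmat))))
      iso <- asn[asn$seq_id == seq_id[i], , drop = FALSE]
      iso$seq_id <- paste0(seq_id[i], "_iso")
      asn <- rbind(asn, iso)
    }
  }
  seq_records(asn, cmat)
}

#' Simulate whole-blood samples as content-weighted mixtures
#'
#' For each donor, the expected whole-blood composition of feature s is
#' `sum_b alpha_b * x_{b,s}` normalized, where `alpha_b` is the donor's
#' per-component sRNA content (per-cell content times blood count for
#' cellular components; plasma content times the plasma volume fraction)
#' and `x_{b,s}` the ground-truth component profile. Counts are sampled at
#' `library_size`.
#'
#' @param cohort output of [simulate_cohort()].
#' @param config the same [sim_config()].
#' @return An [srna_set()] in `reads` units, one whole-blood sample per
#'   donor, with `is_whole_blood = TRUE`.
#' @export
simulate_whole_blood <- function(cohort, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  truth <- cohort$truth
  comps <- config$components
  cellular <- setdiff(comps, "plasma")
  missing_bc <- setdiff(cellular, colnames(cohort$blood_counts))
  if (length(missing_bc))
    stop("missing blood count for component(s): ",
         paste(missing_bc, collapse = ", "))
  donors <- cohort$donors$donor_id
  profiles <- truth$component_profiles[comps, , drop = FALSE]
  counts <- sapply(donors, function(d) {
    w <- stats::setNames(numeric(length(comps)), comps)
    if ("plasma" %in% comps)
      w["plasma"] <- truth$plasma_srna_per_ul * config$plasma_fraction
    w[cellular] <- config$content_per_cell[cellular] *
      cohort$blood_counts[d, cellular]
    mix <- as.vector(t(profiles) %*% w)
    p <- mix / sum(mix)
    if (config$exact_counts) p * config$library_size
    else stats::rmultinom(1, config$library_size, p)
  })
  rownames(counts) <- colnames(profiles)
  colnames(counts) <- paste0("WB_", donors)
  smp <- data.frame(sample_id = colnames(counts), donor_id = donors,
                    component = "whole_blood", is_whole_blood = TRUE,
                    stringsAsFactors = FALSE)
  cls <- stats::setNames(truth$features$rna_class, truth$features$feature_id)
  srna_set(counts, smp, units = "reads", classes = cls)
}
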