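# shared fixtures and independent oracles

# a small srna_set built by hand
make_set <- function(values, components, units = "reads", classes = NULL,
                     donors = NULL) {
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%02d", seq_len(nrow(values)))
  if (is.null(donors)) donors <- sprintf("D%02d", seq_len(ncol(values)))
  srna_set(values,
           data.frame(sample_id = colnames(values), donor_id = donors,
                      component = components, stringsAsFactors = FALSE),
           units = units, classes = classes)
}

# a small clean cohort config: no dropout, no QC failures unless asked
quiet_config <- function(n_donors = 6, seed = 1, ...) {
  sim_config(n_donors = n_donors, purity_fail_rate = 0, outlier_rate = 0,
             missing_content_rate = 0, dropout_rates = numeric(0),
             seed = seed, ...)
}

# simulate -> collapse -> RPM in one step
cohort_rpm <- function(cfg) {
  co <- simulate_cohort(cfg)
  rec <- simulate_counts(co, cfg)
  smeta <- co$sort_samples[, c("sample_id", "donor_id", "component")]
  cm <- collapse_counts(prefilter_sequences(rec, smeta), smeta)
  list(cohort = co, counts = cm, rpm = rpm_normalize(cm))
}

# independent oracle for candidate resolution: enumerate (rank, label)
# pairs for every candidate and take the smallest under C collation
oracle_resolve <- function(candidates, bin_size = 25) {
  prio <- c("miRNA", "tRNA", "rRNA", "YRNA", "snoRNA", "lncRNA", "snRNA",
            "piRNA")
  lab <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    if (candidates$rna_class[i] %in% c("rRNA", "YRNA")) {
      k <- ceiling(candidates$start_pos[i] / bin_size)
      lab[i] <- paste0(candidates$parent_gene[i], "-bin", k)
    } else lab[i] <- candidates$parent_gene[i]
  }
  rank <- match(candidates$rna_class, prio)
  ord <- order(rank, lab, method = "radix")
  list(label = lab[ord[1]], rna_class = candidates$rna_class[ord[1]])
}

# exact two-sided permutation p-value for the rank-sum statistic
perm_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  obs <- sum(r[seq_along(x)])
  combs <- utils::combn(n, length(x))
  stats <- apply(combs, 2, function(idx) sum(r[idx]))
  p_le <- mean(stats <= obs)
  p_ge <- mean(stats >= obs)
  min(1, 2 * min(p_le, p_ge))
}

# marker recovery bookkeeping on a fitted marker table
marker_recovery <- function(markers, marker_map, features_present) {
  truthmk <- marker_map[!is.na(marker_map)]
  truthmk <- truthmk[names(truthmk) %in% features_present]
  key <- paste(markers$component, markers$feature)
  hit <- markers$passes[match(paste(truthmk, names(truthmk)), key)]
  wrong <- markers[markers$feature %in% names(truthmk) & markers$passes, ]
  n_wrong <- sum(wrong$component != truthmk[wrong$feature])
  list(sensitivity = mean(hit), wrong_calls = n_wrong,
       n_markers = length(truthmk))
}
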