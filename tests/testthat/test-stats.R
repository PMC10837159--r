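test_that("component profiles normalize mean RPM and pool sub-2% features as 'others'", {
  v <- matrix(c(0.5, 0.4, 0.06, 0.03, 0.01) * 1e6, ncol = 1)
  m <- make_set(v, "monocytes")
  m$units <- "RPM"
  pr <- component_profile(m)
  expect_equal(sum(pr$proportion), 1, tolerance = 1e-9)
  expect_equal(pr$proportion[pr$entry == "others"], 0.01)
  expect_setequal(setdiff(pr$entry, "others"),
                  c("f01", "f02", "f03", "f04"))

  single <- make_set(matrix(5e5, 1, 1), "a")
  single$units <- "RPM"
  ps <- component_profile(single)
  expect_equal(ps$proportion, 1)
  expect_false("others" %in% ps$entry)
})

test_that("class profiles sum within class per sample before averaging", {
  # unequal library compositions make sum-then-mean != mean-then-sum
  v <- rbind(c(800000, 100000), c(0, 100000), c(200000, 800000))
  m <- make_set(v, c("x", "x"),
                classes = c(f01 = "miRNA", f02 = "miRNA", f03 = "tRNA"))
  m$units <- "RPM"
  cp <- class_profile(m)
  expect_equal(cp$proportion[cp$entry == "miRNA"], 0.5)
  expect_equal(sum(cp$proportion), 1, tolerance = 1e-9)

  # all features one class
  one <- make_set(matrix(c(1, 2), 2, 1) * 1e5, "x",
                  classes = c(f01 = "miRNA", f02 = "miRNA"))
  one$units <- "RPM"
  expect_equal(class_profile(one)$proportion, 1)

  bad <- m; bad$classes <- NULL
  expect_error(class_profile(bad), "class")
})

test_that("constant two-class split yields the constant proportions", {
  v <- rbind(rep(8e5, 4), rep(2e5, 4))
  m <- make_set(v, rep("x", 4), classes = c(f01 = "miRNA", f02 = "tRNA"))
  m$units <- "RPM"
  cp <- class_profile(m)
  expect_equal(cp$proportion[cp$entry == "miRNA"], 0.8)
  expect_equal(cp$proportion[cp$entry == "tRNA"], 0.2)
})

test_that("one-vs-rest marker scan passes exclusive markers only in their component", {
  cfg <- quiet_config(n_donors = 10, seed = 5)
  fx <- cohort_rpm(cfg)
  mk <- overrepresented_srnas(log_transform(fx$rpm))
  rec <- marker_recovery(mk, fx$cohort$truth$marker_map,
                         rownames(fx$rpm$values))
  expect_gt(rec$n_markers, 50)
  expect_equal(rec$sensitivity, 1)
  expect_equal(rec$wrong_calls, 0)

  # invariant: passes <=> positive fold change, adj p < 0.05, expressed in all
  expect_equal(mk$passes,
               mk$log2_fold_change > 0 & mk$adj_p_value < 0.05 &
                 mk$expressed_in_all_group_samples)
  # BH adjustment is monotone in raw p within each component
  for (cc in unique(mk$component)) {
    sub <- mk[mk$component == cc, ]
    ord <- order(sub$p_value)
    expect_true(all(diff(sub$adj_p_value[ord]) >= -1e-12))
  }
})

test_that("constant features never pass and groups need two samples", {
  v <- rbind(rep(1e5, 6), c(9e5, 9e5, 9e5, 1e5, 1e5, 1e5))
  m <- make_set(v, rep(c("x", "y"), each = 3))
  m$units <- "RPM"
  mk <- overrepresented_srnas(log_transform(m))
  expect_false(any(mk$passes[mk$feature == "f01"]))
  expect_equal(mk$log2_fold_change[mk$feature == "f01"], c(0, 0))

  tiny <- make_set(matrix(1, 2, 3), c("x", "x", "y"))
  tiny$units <- "RPM"
  expect_error(overrepresented_srnas(log_transform(tiny)), "fewer than 2")
})

test_that("rank-sum p-values match an exact permutation oracle for small groups", {
  set.seed(77)
  for (rep_i in 1:20) {
    n1 <- sample(3:4, 1); n2 <- sample(3:8, 1)
    x <- rnorm(n1); y <- rnorm(n2, mean = sample(c(0, 2), 1))
    p_pkg <- suppressWarnings(wilcox.test(x, y)$p.value)
    expect_equal(p_pkg, perm_wilcox_p(x, y), tolerance = 1e-12)
  }
  # identical group and rest distributions: p near 1 under the oracle
  z <- c(1.3, 2.1, 3.2, 4.4, 1.3, 2.1, 3.2, 4.4)
  expect_gt(perm_wilcox_p(z[1:4], z[5:8]), 0.9)
})

test_that("detection requires non-zero counts in every sample of a component", {
  v <- rbind(c(1, 1, 1, 1), c(1, 0, 1, 1), c(0, 0, 2, 3))
  m <- make_set(v, rep(c("x", "y"), each = 2))
  ds <- detection_set(m)
  expect_setequal(ds$x, "f01")
  expect_setequal(ds$y, c("f01", "f02", "f03"))

  # brute-force oracle over all (feature, component) pairs
  for (cc in c("x", "y")) {
    brute <- rownames(m$values)[apply(
      m$values[, m$samples$component == cc, drop = FALSE], 1,
      function(z) all(z > 0))]
    expect_setequal(ds[[cc]], brute)
  }
})

test_that("whole-blood correlation is 1 for proportional pairs, NA for constants, null-centred for noise", {
  set.seed(3)
  n <- 12
  counts <- matrix(rlnorm(n * 3, log(1000)), ncol = 3,
                   dimnames = list(sprintf("D%02d", 1:n),
                                   c("monocytes", "NK cells", "B cells")))
  v <- rbind(5 * counts[, "monocytes"],        # exactly proportional
             rep(7, n),                        # constant
             rlnorm(n))                        # independent
  m <- make_set(v, rep("whole_blood", n), donors = rownames(counts))
  m$units <- "RPM"
  r <- whole_blood_correlation(m, counts)
  expect_equal(unname(r["f01", "monocytes"]), 1, tolerance = 1e-12)
  expect_true(all(is.na(r["f02", ])))

  # permutation null: mean |r| small over repeated permuted donors
  rs <- replicate(100, {
    mp <- m
    mp$values[3, ] <- sample(mp$values[3, ])
    whole_blood_correlation(mp, counts)["f03", "monocytes"]
  })
  expect_lt(mean(abs(rs)), 0.3)

  expect_error(whole_blood_correlation(
    subset_set(m, samples = 1:2), counts), "3 donors")
})

test_that("mean-expression correlation across datasets is affine-invariant Pearson", {
  set.seed(9)
  v <- matrix(rlnorm(30, log(100)), ncol = 3)
  a <- make_set(v, rep("monocytes", 3)); a$units <- "RPM"
  expect_equal(unname(mean_expression_correlation(a, a)["monocytes"]), 1)

  b <- a
  b$values <- 2 ^ (3 * log2(a$values + 1) + 1) - 1  # affine on log scale
  expect_equal(unname(mean_expression_correlation(a, b)["monocytes"]), 1,
               tolerance = 1e-12)

  # anti-ordered means on a three-feature toy: mirror on the log scale
  av <- matrix(c(1, 10, 100), ncol = 1,
               dimnames = list(c("f1", "f2", "f3"), "S1"))
  la <- log2(av + 1)
  bv <- 2 ^ (max(la) + min(la) - la) - 1
  aa <- srna_set(av, data.frame(sample_id = "S1", donor_id = "d",
                                component = "x"), units = "RPM")
  bb <- srna_set(bv, data.frame(sample_id = "S1", donor_id = "d",
                                component = "x"), units = "RPM")
  r <- mean_expression_correlation(aa, bb)
  expect_equal(unname(r["x"]), -1, tolerance = 1e-12)

  expect_error(mean_expression_correlation(
    subset_set(aa, features = 1:2), bb), "3 shared")
})
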