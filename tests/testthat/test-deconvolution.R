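test_that("cellular sRNA content follows concentration x elution x blood count / sorted cells", {
  expect_equal(srna_content_cell(1, 1, 1, 1), 1)
  expect_equal(srna_content_cell(50, 14, 2000, 1e6), 1.4)
  expect_equal(srna_content_cell(0, 14, 2000, 1e6), 0)
  expect_error(srna_content_cell(1, 1, 1, 0), "zero")
  expect_error(srna_content_cell(-1, 1, 1, 1), "non-negative")
})

test_that("plasma sRNA content is scaled by the plasma volume fraction", {
  expect_equal(srna_content_plasma(100, 14, 200, 0.5), 3.5)
  expect_equal(srna_content_plasma(10, 20, 200, plasma_fraction = 1), 1)
  expect_equal(srna_content_plasma(0, 14, 200), 0)
  expect_error(srna_content_plasma(1, 1, 0), "zero")
  expect_error(srna_content_plasma(1, 1, 1, 1.5), "0, 1")
})

test_that("sample_contents routes cellular and plasma fractions to their formulas", {
  ss <- data.frame(sample_id = c("c1", "p1", "m1"),
                   donor_id = c("d1", "d1", "d1"),
                   component = c("monocytes", "plasma", "monocytes"),
                   sorted_count = c(1e6, NA, 1e6),
                   purity_pct = c(95, NA, 95),
                   elution_volume = 14,
                   srna_conc = c(50, 100, NA),
                   plasma_input_volume = c(NA, 200, NA))
  bc <- matrix(2000, 1, 1, dimnames = list("d1", "monocytes"))
  ct <- sample_contents(ss, bc)
  expect_equal(ct$alpha, c(1.4, 3.5, NA_real_))
  expect_error(sample_contents(transform(ss, donor_id = "d9"), bc),
               "missing blood count")
})

test_that("scaled means average content-weighted RPM over content-bearing samples only", {
  v <- matrix(c(10, 20, 7), nrow = 1,
              dimnames = list("f1", c("A", "B", "C")))
  m <- make_set(v, rep("monocytes", 3))
  m$units <- "RPM"
  ct <- data.frame(sample_id = c("A", "B", "C"),
                   donor_id = c("d1", "d2", "d3"),
                   component = "monocytes", alpha = c(1, 2, NA))
  sm <- scaled_mean_expression(m, ct)
  expect_equal(unname(sm$xbar["f1", "monocytes"]), (10 * 1 + 20 * 2) / 2)
  expect_equal(unname(sm$D["monocytes"]), 2L)
  expect_equal(sm$skipped, "C")

  # one donor: the scaled mean is x * alpha; all alpha = 1: plain mean
  one <- scaled_mean_expression(subset_set(m, samples = 1),
                                ct[1, , drop = FALSE])
  expect_equal(unname(one$xbar["f1", 1]), 10)
  ct1 <- transform(ct, alpha = 1)
  expect_equal(unname(scaled_mean_expression(m, ct1)$xbar["f1", 1]),
               mean(v))

  ct_none <- transform(ct, alpha = NA_real_)
  expect_error(scaled_mean_expression(m, ct_none), "monocytes")
})

test_that("contribution proportions normalize features and flag all-zero rows", {
  xb <- rbind(c(3, 1), c(0, 5), c(0, 0))
  rownames(xb) <- c("f1", "f2", "f3"); colnames(xb) <- c("a", "b")
  expect_warning(P <- contribution_proportions(xb), "all-zero")
  expect_equal(P["f1", ], c(a = 0.75, b = 0.25))
  expect_equal(P["f2", ], c(a = 0, b = 1))
  expect_true(all(is.na(P["f3", ])))
  expect_equal(unname(rowSums(P[1:2, ])), c(1, 1), tolerance = 1e-9)
  expect_error(contribution_proportions(-xb), "non-negative")
})

test_that("blood_deconv fit carries proportions, bookkeeping, and S3 methods", {
  cfg <- quiet_config(n_donors = 5, seed = 11)
  fx <- cohort_rpm(cfg)
  ct <- sample_contents(fx$cohort$sort_samples, fx$cohort$blood_counts)
  fit <- blood_deconv(fx$rpm, ct)
  expect_s3_class(fit, "blood_deconv")
  expect_equal(unname(rowSums(coef(fit))), rep(1, nrow(fit$P)),
               tolerance = 1e-9)
  expect_equal(sort(names(fit$D)), sort(cfg$components))
  expect_output(print(fit), "deconvolution")
  s <- summary(fit)
  expect_equal(sum(s$mean_contribution), 1, tolerance = 1e-9)
  expect_output(print(s), "mean_contribution")

  # predict: content-weighted mixture of mean profiles sums to one and
  # tilts toward the up-weighted component's markers
  alpha <- setNames(rep(1, length(cfg$components)), cfg$components)
  pr <- predict(fit, alpha)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_error(predict(fit, unname(alpha)), "named")

  # whole-blood samples are refused as fit inputs
  wb <- simulate_whole_blood(fx$cohort, cfg)
  expect_error(blood_deconv(rpm_normalize(wb), ct), "whole-blood")
})

test_that("contributions are invariant to global content rescaling and monotone in one component's content", {
  cfg <- quiet_config(n_donors = 4, seed = 13)
  fx <- cohort_rpm(cfg)
  ct <- sample_contents(fx$cohort$sort_samples, fx$cohort$blood_counts)
  fit <- blood_deconv(fx$rpm, ct)
  ct2 <- transform(ct, alpha = alpha * 1000)
  expect_equal(coef(blood_deconv(fx$rpm, ct2)), coef(fit),
               tolerance = 1e-12)

  ct3 <- transform(ct, alpha = ifelse(component == "monocytes",
                                      alpha * 3, alpha))
  P3 <- coef(blood_deconv(fx$rpm, ct3))
  expect_true(all(P3[, "monocytes"] >= coef(fit)[, "monocytes"] - 1e-12))
})

test_that("deconvolution recovers the generator's ground truth (oracle closure)", {
  cfg <- quiet_config(n_donors = 6, exact_counts = TRUE, seed = 17)
  fx <- cohort_rpm(cfg)
  ct <- sample_contents(fx$cohort$sort_samples, fx$cohort$blood_counts)
  fit <- blood_deconv(fx$rpm, ct)
  tt <- fx$cohort$truth$true_contributions[rownames(fit$P),
                                           colnames(fit$P)]
  expect_lt(max(abs(coef(fit) - tt)), 1e-6)
})

test_that("a hand-built three-component mixture recovers contents 1:2:3 on disjoint markers", {
  # components with disjoint single markers and alphas (1, 2, 3):
  # the whole-blood expectation is (1/6, 2/6, 3/6)
  profiles <- diag(3)
  rownames(profiles) <- c("a", "b", "c")
  colnames(profiles) <- c("fa", "fb", "fc")
  alpha <- c(a = 1, b = 2, c = 3)
  mix <- (t(profiles) %*% alpha)[, 1]
  expect_equal(mix / sum(mix), c(fa = 1, fb = 2, fc = 3) / 6)
})
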