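test_that("kappa reproduces the published back-substitution and jackknife values", {
  expect_equal(round(cohen_kappa(confusion_table(96, 3, 0, 105)), 3), 0.971)
  expect_equal(round(cohen_kappa(confusion_table(95, 4, 1, 104)), 3), 0.951)
  expect_equal(cohen_kappa(confusion_table(50, 0, 0, 50)), 1)
})

test_that("kappa matches a cell-probability oracle on random tables", {
  set.seed(77)
  for (i in 1:1000) {
    cells <- as.integer(rmultinom(1, sample(20:300, 1),
                                  prob = runif(4, 0.05, 1)))
    # avoid degenerate marginals (chance agreement of 1)
    if ((cells[1] + cells[2] == 0) || (cells[3] + cells[4] == 0)) next
    tab <- confusion_table(cells[1], cells[2], cells[3], cells[4])
    k <- tryCatch(cohen_kappa(tab), error = function(e) NULL)
    if (is.null(k)) next
    expect_equal(k, oracle_kappa(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }
})

test_that("exact McNemar reproduces the published footnote values", {
  expect_equal(mcnemar_exact(3, 0), 0.250)
  expect_equal(mcnemar_exact(4, 1), 0.375)
  expect_equal(mcnemar_exact(0, 0), 1)
})

test_that("exact McNemar equals binomial enumeration for all b + c <= 25", {
  for (n in 0:25) {
    for (b in 0:n) {
      expect_equal(mcnemar_exact(b, n - b), oracle_mcnemar(b, n - b),
                   tolerance = 1e-12)
    }
  }
})

test_that("error discriminant proportions match the published percentages", {
  t3 <- confusion_table(96, 3, 0, 105)
  expect_equal(round(error_discriminant_proportion(t3, "positive"), 2), 3.03)
  expect_equal(error_discriminant_proportion(t3, "negative"), 0)
  t4 <- confusion_table(95, 4, 1, 104)
  expect_equal(round(error_discriminant_proportion(t4, "positive"), 2), 4.04)
  expect_equal(round(error_discriminant_proportion(t4, "negative"), 2), 0.95)
})

test_that("error and correct proportions always sum to one per class", {
  set.seed(19)
  for (i in 1:50) {
    cells <- 1 + as.integer(rmultinom(1, 100, runif(4)))
    tab <- confusion_table(cells[1], cells[2], cells[3], cells[4])
    sm <- summary_metrics(tab)
    expect_equal(sm$correct_prop_pos + sm$error_prop_pos, 1, tolerance = 1e-12)
    expect_equal(sm$correct_prop_neg + sm$error_prop_neg, 1, tolerance = 1e-12)
    expect_equal(sm$error_prop_pos * 100,
                 error_discriminant_proportion(tab, "positive"),
                 tolerance = 1e-12)
  }
})

test_that("swapping class roles swaps sensitivity/specificity, kappa unchanged", {
  tab <- confusion_table(80, 7, 12, 101)
  swapped <- confusion_table(101, 12, 7, 80)
  a <- summary_metrics(tab)
  b <- summary_metrics(swapped)
  expect_equal(a$sensitivity, b$specificity, tolerance = 1e-12)
  expect_equal(a$specificity, b$sensitivity, tolerance = 1e-12)
  expect_equal(a$kappa, b$kappa, tolerance = 1e-12)
})

test_that("summary metrics reproduce the published sensitivity and Youden index", {
  sm <- summary_metrics(confusion_table(96, 3, 0, 105))
  expect_equal(round(sm$sensitivity, 4), 0.9697)
  expect_equal(sm$specificity, 1)
  expect_equal(sm$youden, sm$sensitivity + sm$specificity - 1, tolerance = 1e-12)
  expect_equal(sm$mcnemar_p, 0.250)

  perfect <- summary_metrics(confusion_table(10, 0, 0, 10))
  expect_equal(perfect$youden, 1)
})

test_that("random assignment has a Youden index near zero", {
  set.seed(99)
  actual <- rep(c(1L, 2L), each = 200)
  predicted <- sample(c(1L, 2L), 400, replace = TRUE)
  tab <- confusion_table(
    sum(actual == 1 & predicted == 1), sum(actual == 1 & predicted == 2),
    sum(actual == 2 & predicted == 1), sum(actual == 2 & predicted == 2)
  )
  expect_lt(abs(summary_metrics(tab)$youden), 0.1)
})

test_that("back-substitution is error-free on separable data", {
  m <- generate_two_class(synthetic_spec(n_pos = 30, n_neg = 30,
                                         n_informative = 2, n_noise = 2,
                                         effect_size = 8, seed = 3))
  fit <- fit_fisher(m)
  tab <- back_substitution(fit, m)
  expect_equal(tab$fn, 0)
  expect_equal(tab$fp, 0)

  one <- m[1, , drop = FALSE]
  tab1 <- back_substitution(fit, one)
  expect_equal(unlist(tab1), c(tp = 1L, fn = 0L, fp = 0L, tn = 0L))
})

test_that("back-substitution accuracy tracks the Bayes rate on overlapping classes", {
  # one descriptor, class gap 2*qnorm(0.9): Bayes error 10%
  m <- generate_two_class(synthetic_spec(n_pos = 100, n_neg = 100,
                                         n_informative = 1, n_noise = 0,
                                         effect_size = 2 * qnorm(0.9),
                                         seed = 25))
  fit <- fit_fisher(m)
  acc <- summary_metrics(back_substitution(fit, m))$p0
  expect_gt(acc, 0.85)
  expect_lt(acc, 0.95)
})

test_that("the jackknife performs N refits and matches back-substitution when separable", {
  m4 <- generate_two_class(synthetic_spec(n_pos = 2, n_neg = 2,
                                          n_informative = 1, n_noise = 0,
                                          effect_size = 10, seed = 1))
  cv4 <- jackknife_loocv(m4)
  expect_equal(attr(cv4, "n_fits"), 4L)

  m <- generate_two_class(synthetic_spec(n_pos = 25, n_neg = 25,
                                         n_informative = 2, n_noise = 1,
                                         effect_size = 8, seed = 10))
  fit <- fit_fisher(m)
  bs <- back_substitution(fit, m)
  cv <- jackknife_loocv(m)
  expect_equal(attr(cv, "n_fits"), 50L)
  expect_equal(unlist(cv), unlist(bs))
})

test_that("leave-one-out accuracy is not optimistic beyond sampling slack", {
  diffs <- vapply(1:20, function(seed) {
    m <- generate_two_class(synthetic_spec(n_pos = 40, n_neg = 40,
                                           n_informative = 1, n_noise = 1,
                                           effect_size = 2 * qnorm(0.9),
                                           seed = seed))
    fit <- fit_fisher(m)
    bs <- summary_metrics(back_substitution(fit, m))$p0
    cv <- summary_metrics(jackknife_loocv(m))$p0
    cv - bs
  }, numeric(1))
  expect_true(all(diffs <= 0.05 + 1e-12))
})

test_that("reselection inside folds is exposed and deterministic", {
  m <- generate_two_class(synthetic_spec(n_pos = 15, n_neg = 15,
                                         n_informative = 2, n_noise = 3,
                                         effect_size = 3, seed = 18))
  a <- jackknife_loocv(m, reselect = TRUE)
  b <- jackknife_loocv(m, reselect = TRUE)
  expect_equal(unlist(a), unlist(b))
  expect_equal(attr(a, "n_fits"), 30L)
})

test_that("heat-map matrices are seeded, standardized, and class-contrasting", {
  m <- generate_two_class(synthetic_spec(n_pos = 30, n_neg = 30,
                                         n_informative = 3, n_noise = 3,
                                         effect_size = 2, seed = 5))
  fit <- fit_fisher(m, descriptors = c("inf_01", "inf_02", "noise_001"))
  h1 <- heatmap_matrix(m, fit, n_per_class = 10, seed = 17)
  h2 <- heatmap_matrix(m, fit, n_per_class = 10, seed = 17)
  expect_equal(as.data.frame(h1), as.data.frame(h2))
  expect_equal(nrow(h1), 20)

  for (col in fit$descriptors) {
    expect_equal(mean(h1[[col]]), 0, tolerance = 1e-10)
    expect_equal(sd(h1[[col]]), 1, tolerance = 1e-10)
  }
  # planted mean shift shows as opposite-signed class blocks
  z_pos <- mean(h1$inf_01[h1$label == 1])
  z_neg <- mean(h1$inf_01[h1$label == 2])
  expect_true(sign(z_pos) != sign(z_neg))

  p <- ggplot2::autoplot(h1)
  expect_s3_class(p, "ggplot")
})
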