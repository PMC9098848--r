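test_that("Wilks' lambda is 1 without between-group scatter and ~0 at separation", {
  # identical class means: mirrored values in both groups
  m <- make_matrix(matrix(c(1, 2, 3, 1, 2, 3), ncol = 1),
                   labels = c(1, 1, 1, 2, 2, 2))
  expect_equal(wilks_lambda(m), 1)

  # near-perfect separation with tiny within-variance
  set.seed(2)
  x <- c(rnorm(20, 0, 1e-4), rnorm(20, 10, 1e-4))
  m <- make_matrix(matrix(x, ncol = 1), labels = rep(c(1, 2), each = 20))
  expect_lt(wilks_lambda(m), 1e-6)
})

test_that("univariate lambda satisfies F = (n-2)(1-L)/L = t^2", {
  set.seed(31)
  for (i in 1:25) {
    n1 <- sample(4:20, 1)
    n2 <- sample(4:20, 1)
    x <- c(rnorm(n1, runif(1, -1, 1)), rnorm(n2))
    labels <- c(rep(1, n1), rep(2, n2))
    m <- make_matrix(matrix(x, ncol = 1), labels)
    lam <- wilks_lambda(m)
    expect_equal(lam, oracle_lambda1(x, labels), tolerance = 1e-12)
    f <- (n1 + n2 - 2) * (1 - lam) / lam
    t2 <- oracle_t_pooled(x[labels == 1], x[labels == 2])$t^2
    expect_equal(f, t2, tolerance = 1e-10)
  }
})

test_that("lambda is affine-invariant and never increases when adding descriptors", {
  set.seed(17)
  X <- matrix(rnorm(60 * 5), 60, 5)
  X[, 1] <- X[, 1] + rep(c(1, 0), each = 30)
  labels <- rep(c(1, 2), each = 30)
  m <- make_matrix(X, labels)
  desc <- descriptor_names(m)

  rescaled <- m
  rescaled$d02 <- 100 * rescaled$d02 - 7
  expect_equal(wilks_lambda(m, desc), wilks_lambda(rescaled, desc),
               tolerance = 1e-10)

  lams <- vapply(seq_along(desc), function(k) wilks_lambda(m, desc[1:k]),
                 numeric(1))
  expect_true(all(diff(lams) <= 1e-12))
})

test_that("first entry is the exhaustive single-descriptor minimum-lambda choice", {
  m <- generate_two_class(synthetic_spec(n_pos = 25, n_neg = 25,
                                         n_informative = 1, n_noise = 2,
                                         effect_size = 2, seed = 9))
  # informative column is the middle of a shuffled layout
  names(m)[names(m) == "inf_01"] <- "d2"
  names(m)[names(m) == "noise_001"] <- "d1"
  names(m)[names(m) == "noise_002"] <- "d3"
  tr <- stepwise_select(m, c("d1", "d2", "d3"))
  scan <- vapply(c("d1", "d2", "d3"), function(d) {
    oracle_lambda1(m[[d]], m$label)
  }, numeric(1))
  expect_equal(tr$steps$action[1], "enter")
  expect_equal(tr$steps$descriptor[1], names(which.min(scan)))
  expect_equal(tr$steps$descriptor[1], "d2")
})

test_that("no entry happens when the best candidate F stays below the threshold", {
  set.seed(23)
  m <- make_matrix(matrix(rnorm(40 * 3), 40, 3), labels = rep(c(1, 2), 20))
  best_f <- max(vapply(descriptor_names(m), function(d) {
    lam <- oracle_lambda1(m[[d]], m$label)
    (40 - 2) * (1 - lam) / lam
  }, numeric(1)))
  expect_lt(best_f, 3.84) # fixture sanity: pure noise below the default gate
  tr <- stepwise_select(m)
  expect_equal(nrow(tr$steps), 0)
  expect_equal(tr$selected, character(0))
  expect_equal(tr$wilks_lambda, 1)
})

test_that("a descriptor made redundant by later entries is removed", {
  set.seed(1)
  n <- 200
  labels <- rep(c(1, 2), each = n / 2)
  # B and C anticorrelate within class, so their sum A has small variance and
  # wins the univariate scan; jointly, B and C carry everything A has and more
  u <- rnorm(n)
  v <- rnorm(n)
  B <- u + ifelse(labels == 1, 0.4, -0.4)
  C <- -0.8 * u + 0.6 * v
  A <- B + C + rnorm(n, sd = 0.2) # A turns redundant once B and C are in
  m <- make_matrix(cbind(A, B, C), labels)
  names(m)[3:5] <- c("A", "B", "C")
  tr <- stepwise_select(m, c("A", "B", "C"))
  expect_equal(tr$steps$descriptor[1], "A")
  removed <- tr$steps$descriptor[tr$steps$action == "remove"]
  expect_true("A" %in% removed)
  expect_setequal(tr$selected, c("B", "C"))

  # brute-force check: {B, C} is the best two-descriptor subset by Wilks
  subsets <- list(c("A", "B"), c("A", "C"), c("B", "C"))
  lams <- vapply(subsets, function(s) {
    fit <- stats::manova(as.matrix(m[s]) ~ factor(m$label))
    summary(fit, test = "Wilks")$stats[1, "Wilks"]
  }, numeric(1))
  expect_equal(subsets[[which.min(lams)]], c("B", "C"))
  expect_equal(wilks_lambda(m, c("B", "C")), min(lams), tolerance = 1e-10)
})

test_that("entry and removal thresholds must not cycle", {
  m <- make_matrix(matrix(rnorm(20 * 2), 20, 2), labels = rep(c(1, 2), 10))
  expect_error(stepwise_select(m, f_enter = 2, f_remove = 2), "strictly below")
  expect_error(stepwise_select(m, f_enter = 2, f_remove = 3), "strictly below")
})

test_that("selection terminates within max_steps and respects it", {
  m <- generate_two_class(synthetic_spec(n_pos = 40, n_neg = 40,
                                         n_informative = 6, n_noise = 10,
                                         effect_size = 1.5, seed = 12))
  tr <- stepwise_select(m, max_steps = 4)
  expect_lte(nrow(tr$steps), 4)
  expect_equal(glance(tr)$n_selected, length(tr$selected))
  expect_equal(tidy(tr), tr$steps)
})

test_that("near-collinear candidates are skipped rather than inverted", {
  m <- generate_two_class(synthetic_spec(n_pos = 30, n_neg = 30,
                                         n_informative = 2, n_noise = 2,
                                         effect_size = 2, n_duplicate = 2,
                                         seed = 33))
  expect_message(tr <- stepwise_select(m), "collinear")
  # an informative column and its exact duplicate never coexist in the model
  expect_false(all(c("inf_01", "dup_inf_01") %in% tr$selected))
  expect_false(all(c("inf_02", "dup_inf_02") %in% tr$selected))
})

test_that("informative descriptors are recovered across seeded replicates", {
  hits <- vapply(1:50, function(seed) {
    m <- generate_two_class(synthetic_spec(n_pos = 100, n_neg = 100,
                                           n_informative = 3, n_noise = 20,
                                           effect_size = 2, seed = seed))
    tr <- stepwise_select(m)
    all(sprintf("inf_%02d", 1:3) %in% tr$selected)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
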