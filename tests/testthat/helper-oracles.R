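# Independent oracles used to cross-check the implementation. These are
# deliberately written from first principles (textbook formulas, direct
# enumeration) and share no code with the package internals.

# Pooled-variance two-sample t from the textbook formula.
oracle_t_pooled <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Single-descriptor Wilks' lambda from raw sums of squares.
oracle_lambda1 <- function(x, labels) {
  x1 <- x[labels == 1]
  x2 <- x[labels == 2]
  ssw <- sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)
  sst <- sum((x - mean(x))^2)
  ssw / sst
}

# Cohen's kappa from the 2x2 joint probabilities.
oracle_kappa <- function(tp, fn, fp, tn) {
  n <- tp + fn + fp + tn
  p <- matrix(c(tp, fn, fp, tn), 2, 2, byrow = TRUE) / n
  p0 <- sum(diag(p))
  pe <- sum(rowSums(p) * colSums(p))
  (p0 - pe) / (1 - pe)
}

# Exact two-sided McNemar p by enumerating every binomial outcome.
oracle_mcnemar <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  k <- min(b, c)
  probs <- choose(n, 0:n) / 2^n
  min(1, 2 * sum(probs[0:k + 1]))
}

# Pooled-covariance Gaussian Bayes decisions, computed from class means,
# the pooled covariance and priors by direct evaluation of the
# discriminant quadratic forms.
oracle_bayes_decide <- function(X, train_X, train_lab, priors = c(0.5, 0.5)) {
  X1 <- train_X[train_lab == 1, , drop = FALSE]
  X2 <- train_X[train_lab == 2, , drop = FALSE]
  m1 <- colMeans(X1)
  m2 <- colMeans(X2)
  S <- (crossprod(scale(X1, center = TRUE, scale = FALSE)) +
          crossprod(scale(X2, center = TRUE, scale = FALSE))) /
    (nrow(train_X) - 2)
  Sinv <- solve(S)
  score <- function(x, m, prior) {
    -0.5 * drop(t(x - m) %*% Sinv %*% (x - m)) + log(prior)
  }
  apply(X, 1, function(x) {
    if (score(x, m1, priors[1]) >= score(x, m2, priors[2])) 1L else 2L
  })
}

# Small helper: a plain descriptor matrix tibble from a numeric matrix.
make_matrix <- function(X, labels, prefix = "d") {
  colnames(X) <- sprintf("%s%02d", prefix, seq_len(ncol(X)))
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%03d", seq_len(nrow(X))),
                   label = as.integer(labels)),
    tibble::as_tibble(as.data.frame(X))
  )
}
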