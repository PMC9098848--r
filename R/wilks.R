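# Wilks' lambda and stepwise descriptor selection for two groups.

# Within-group (W) and total (T) scatter matrices over the descriptor
# columns; computed once and subset per candidate during stepwise search.
scatter_matrices <- function(data, descriptors, min_per_class = 2) {
  X <- as.matrix(data[descriptors])
  if (!is.numeric(X)) abort("Descriptor columns must be numeric.")
  lab <- data$label
  X1 <- X[lab == 1L, , drop = FALSE]
  X2 <- X[lab == 2L, , drop = FALSE]
  if (nrow(X1) < min_per_class || nrow(X2) < min_per_class) {
    abort(paste0("Both classes need at least ", min_per_class, " samples."))
  }
  C1 <- sweep(X1, 2, colMeans(X1))
  C2 <- sweep(X2, 2, colMeans(X2))
  CT <- sweep(X, 2, colMeans(X))
  list(W = crossprod(C1) + crossprod(C2), T = crossprod(CT),
       n = nrow(X), g = 2L, names = descriptors)
}

# log det via Cholesky; NA when not positive definite.
logdet_chol <- function(M) {
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) return(NA_real_)
  2 * sum(log(diag(R)))
}

lambda_from_scatter <- function(sc, idx) {
  lw <- logdet_chol(sc$W[idx, idx, drop = FALSE])
  lt <- logdet_chol(sc$T[idx, idx, drop = FALSE])
  if (is.na(lw) || is.na(lt)) return(NA_real_)
  min(exp(lw - lt), 1)
}

#' Wilks' lambda of a descriptor subset
#'
#' `Lambda = det(W) / det(T)`, the ratio of the within-group to the total
#' scatter determinant over the given descriptors; values near 0 indicate
#' strong group separation, 1 indicates none. For a single descriptor the
#' statistic satisfies `F = (n - 2) (1 - Lambda) / Lambda = t^2` with the
#' pooled two-sample t.
#'
#' @param data Descriptor matrix with a `label` column (1/2).
#' @param descriptors Character vector of descriptor columns to use
#'   (default: all).
#' @return Wilks' lambda in (0, 1].
#' @export
wilks_lambda <- function(data, descriptors = descriptor_names(data)) {
  check_descriptor_matrix(data)
  if (length(descriptors) == 0) abort("`descriptors` must be non-empty.")
  missing_cols <- setdiff(descriptors, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Unknown descriptors: ", paste(missing_cols, collapse = ", ")))
  }
  sc <- scatter_matrices(data, descriptors)
  lam <- lambda_from_scatter(sc, seq_along(descriptors))
  if (is.na(lam)) {
    abort(paste0("Singular scatter matrix over descriptors: ",
                 paste(descriptors, collapse = ", ")))
  }
  lam
}

condition_number <- function(M) {
  s <- svd(M, nu = 0, nv = 0)$d
  if (min(s) <= 0) return(Inf)
  max(s) / min(s)
}

#' Stepwise descriptor selection by the Wilks' lambda criterion
#'
#' Forward selection with backward removal, the classic stepwise
#' discriminant procedure. At each step the out-of-model descriptor that
#' minimizes the model's Wilks' lambda is entered if its partial
#' F-to-enter reaches `f_enter`; afterwards any in-model descriptor whose
#' partial F-to-remove falls below `f_remove` is removed (smallest F
#' first). For two groups with `p` descriptors in the model, the partial
#' F-to-enter of a candidate is
#' `(n - 2 - p) * (Lambda_with / Lambda_without - 1)^-1`-style ratio,
#' i.e. `(n - 2 - p) * (Lambda_p / Lambda_p+1 - 1)`, on 1 and `n - 2 - p`
#' degrees of freedom; the univariate case reduces to the squared pooled
#' t. Selection stops when no candidate qualifies, the candidate pool or
#' degrees of freedom are exhausted, or `max_steps` actions (entries plus
#' removals) have been recorded.
#'
#' Candidates whose entry would push the condition number of the
#' within-group scatter above `cond_tol` are skipped with a message:
#' screened descriptor pools routinely contain exact duplicates (e.g. two
#' ester-count descriptors that agree on every compound), which would make
#' the scatter singular.
#'
#' @param data Descriptor matrix with a `label` column (1/2).
#' @param descriptors Candidate descriptor columns (default: all).
#' @param f_enter Partial F threshold to enter (default 3.84).
#' @param f_remove Partial F threshold to remove (default 2.71); must be
#'   strictly below `f_enter` or entry/removal could cycle forever.
#' @param max_steps Maximum number of recorded actions (default 100).
#' @param cond_tol Condition-number guard for the within-group scatter
#'   (default 1e10).
#' @return A `stepwise_trace`: list with `steps` (tibble `step, action,
#'   descriptor, wilks_lambda, f, p_value`), `selected` (final ordered
#'   descriptor set) and the settings. `tidy()` returns the step tibble.
#' @export
stepwise_select <- function(data, descriptors = descriptor_names(data),
                            f_enter = 3.84, f_remove = 2.71,
                            max_steps = 100, cond_tol = 1e10) {
  check_descriptor_matrix(data)
  if (length(descriptors) < 2) abort("Need at least 2 candidate descriptors.")
  if (f_remove >= f_enter) {
    abort("`f_remove` must be strictly below `f_enter`.")
  }
  sc <- scatter_matrices(data, descriptors)
  n <- sc$n
  g <- sc$g
  p_all <- length(descriptors)

  model <- integer() # indices into `descriptors`
  lambda_cur <- 1
  steps <- list()
  skipped <- character()

  record <- function(action, idx, lambda, f, df2) {
    steps[[length(steps) + 1]] <<- tibble(
      step = length(steps) + 1L, action = action,
      descriptor = descriptors[idx],
      wilks_lambda = lambda, f = f,
      p_value = stats::pf(f, g - 1, df2, lower.tail = FALSE)
    )
  }

  repeat {
    if (length(steps) >= max_steps) break
    p <- length(model)
    df2_enter <- n - g - p
    if (df2_enter <= 0) break
    candidates <- setdiff(seq_len(p_all), model)
    if (length(candidates) == 0) break

    best_idx <- NA_integer_
    best_lambda <- Inf
    for (ci in candidates) {
      idx_new <- c(model, ci)
      if (condition_number(sc$W[idx_new, idx_new, drop = FALSE]) > cond_tol) {
        if (!descriptors[ci] %in% skipped) {
          skipped <- c(skipped, descriptors[ci])
          inform(paste0("Skipping near-collinear candidate: ", descriptors[ci]))
        }
        next
      }
      lam <- lambda_from_scatter(sc, idx_new)
      if (is.na(lam)) next
      better <- lam < best_lambda ||
        (lam == best_lambda && !is.na(best_idx) &&
           descriptors[ci] < descriptors[best_idx])
      if (better) {
        best_lambda <- lam
        best_idx <- ci
      }
    }
    if (is.na(best_idx)) break
    f_in <- if (best_lambda == 0) Inf else {
      df2_enter * (lambda_cur / best_lambda - 1)
    }
    if (f_in < f_enter) break
    model <- c(model, best_idx)
    lambda_cur <- best_lambda
    record("enter", best_idx, lambda_cur, f_in, df2_enter)

    # Backward phase: drop anything whose partial F fell below f_remove.
    repeat {
      if (length(steps) >= max_steps || length(model) < 2) break
      p <- length(model)
      df2_rem <- n - g - p + 1
      f_rem <- rep(NA_real_, p)
      lam_rem <- rep(NA_real_, p)
      for (k in seq_len(p)) {
        idx_wo <- model[-k]
        lam <- lambda_from_scatter(sc, idx_wo)
        if (is.na(lam)) next
        lam_rem[k] <- lam
        f_rem[k] <- df2_rem * (lam / lambda_cur - 1)
      }
      worst <- which.min(f_rem)
      if (length(worst) == 0 || is.na(f_rem[worst]) ||
          f_rem[worst] >= f_remove) break
      removed <- model[worst]
      model <- model[-worst]
      lambda_cur <- lam_rem[worst]
      record("remove", removed, lambda_cur, f_rem[worst], df2_rem)
    }
  }

  structure(
    list(
      steps = if (length(steps) > 0) dplyr::bind_rows(steps) else
        tibble(step = integer(), action = character(), descriptor = character(),
               wilks_lambda = numeric(), f = numeric(), p_value = numeric()),
      selected = descriptors[model],
      wilks_lambda = if (length(model) > 0) lambda_cur else 1,
      n = n, f_enter = f_enter, f_remove = f_remove,
      skipped = skipped
    ),
    class = "stepwise_trace"
  )
}

#' @export
print.stepwise_trace <- function(x, ...) {
  cat("Stepwise discriminant selection (Wilks' lambda criterion)\n")
  cat(sprintf("  %d action(s); %d descriptor(s) selected; final lambda = %.4g\n",
              nrow(x$steps), length(x$selected), x$wilks_lambda))
  if (nrow(x$steps) > 0) print(x$steps, n = 25)
  invisible(x)
}

#' @rdname stepwise_select
#' @param x A `stepwise_trace`.
#' @param ... Unused.
#' @export
tidy.stepwise_trace <- function(x, ...) x$steps

#' @rdname stepwise_select
#' @export
glance.stepwise_trace <- function(x, ...) {
  tibble(
    n_steps = nrow(x$steps),
    n_entered = sum(x$steps$action == "enter"),
    n_removed = sum(x$steps$action == "remove"),
    n_selected = length(x$selected),
    wilks_lambda = x$wilks_lambda,
    n = x$n
  )
}

#' @rdname stepwise_select
#' @param object A `stepwise_trace`.
#' @export
autoplot.stepwise_trace <- function(object, ...) {
  df <- object$steps
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$wilks_lambda)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$action), size = 2) +
    ggplot2::scale_shape_manual(values = c(enter = 16, remove = 4)) +
    ggplot2::labs(x = "Step", y = "Wilks' lambda", shape = NULL) +
    ggplot2::theme_minimal()
}
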