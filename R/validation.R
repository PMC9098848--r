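# Model validation: confusion tables, agreement statistics, LOOCV,
# exact McNemar, and the standardized heat-map matrix.

#' Build a 2x2 confusion table
#'
#' Cell convention: rows are the actual class, columns the predicted
#' class. `tp` actual-positive predicted-positive, `fn` actual-positive
#' predicted-negative, `fp` actual-negative predicted-positive, `tn`
#' actual-negative predicted-negative.
#'
#' @param tp,fn,fp,tn Non-negative counts.
#' @return A `confusion_table`.
#' @export
#' @examples
#' confusion_table(tp = 96, fn = 3, fp = 0, tn = 105)
confusion_table <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort("Confusion counts must be non-negative integers.")
  }
  structure(as.list(setNames(as.integer(counts), names(counts))),
            class = "confusion_table")
}

confusion_from_predictions <- function(actual, predicted) {
  confusion_table(
    tp = sum(actual == 1L & predicted == 1L),
    fn = sum(actual == 1L & predicted == 2L),
    fp = sum(actual == 2L & predicted == 1L),
    tn = sum(actual == 2L & predicted == 2L)
  )
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn, x$tp + x$fn, x$fp + x$tn),
              nrow = 3, byrow = TRUE,
              dimnames = list(
                c("Predicted positive", "Predicted negative", "Total"),
                c("Actual positive", "Actual negative")
              ))
  cat("Classification results (counts)\n")
  print(m)
  invisible(x)
}

#' @rdname confusion_table
#' @param x A `confusion_table`.
#' @param ... Unused.
#' @export
tidy.confusion_table <- function(x, ...) {
  tibble(
    actual = c(1L, 1L, 2L, 2L),
    predicted = c(1L, 2L, 1L, 2L),
    n = c(x$tp, x$fn, x$fp, x$tn)
  )
}

#' Back-substitution evaluation
#'
#' Classifies the very samples the model was fitted on and tallies the
#' 2x2 table; an optimistic but standard first check of a discriminant
#' model.
#'
#' @param model A `fisher_model`.
#' @param data Descriptor matrix with a `label` column covering the
#'   model's descriptors.
#' @return A `confusion_table`.
#' @export
back_substitution <- function(model, data) {
  check_descriptor_matrix(data)
  pred <- classify(model, data)
  confusion_from_predictions(data$label, pred$predicted_class)
}

#' Jackknife (leave-one-out) cross-validation
#'
#' Each sample in turn is held out, the classification functions are
#' refitted on the remaining `N - 1` samples, and the held-out sample is
#' classified; exactly `N` refits are performed (count available in the
#' `"n_fits"` attribute of the result). By default the descriptor set is
#' held fixed and only the coefficients are refitted per fold; with
#' `reselect = TRUE` the stepwise selection itself is re-run inside every
#' fold (much slower, and folds may select different descriptor sets).
#'
#' @param data Descriptor matrix with a `label` column; `N >= 4` with both
#'   classes kept in every fold.
#' @param descriptors Descriptor set to refit (default: all columns);
#'   ignored as the final set when `reselect = TRUE`, where it defines the
#'   candidate pool instead.
#' @param reselect Re-run [stepwise_select()] within each fold
#'   (default `FALSE`).
#' @param priors,f_enter,f_remove,max_steps Passed to [fit_fisher()] and,
#'   when reselecting, [stepwise_select()].
#' @return A `confusion_table` with attribute `n_fits`.
#' @export
jackknife_loocv <- function(data, descriptors = descriptor_names(data),
                            reselect = FALSE, priors = "equal",
                            f_enter = 3.84, f_remove = 2.71,
                            max_steps = 100) {
  check_descriptor_matrix(data)
  n <- nrow(data)
  if (n < 4) abort("LOOCV needs at least 4 samples.")
  if (sum(data$label == 1L) < 2 || sum(data$label == 2L) < 2) {
    abort("Each class needs at least 2 samples so every fold keeps both classes.")
  }
  predicted <- integer(n)
  n_fits <- 0L
  for (i in seq_len(n)) {
    train <- data[-i, , drop = FALSE]
    sel <- descriptors
    if (reselect) {
      sel <- stepwise_select(train, descriptors, f_enter = f_enter,
                             f_remove = f_remove, max_steps = max_steps)$selected
      if (length(sel) == 0) {
        # no descriptor qualifies: fall back to the prior-majority class
        predicted[i] <- if (sum(train$label == 1L) >= sum(train$label == 2L)) 1L else 2L
        n_fits <- n_fits + 1L
        next
      }
    }
    fit <- fit_fisher(train, sel, priors = priors)
    predicted[i] <- classify(fit, data[i, , drop = FALSE])$predicted_class
    n_fits <- n_fits + 1L
  }
  out <- confusion_from_predictions(data$label, predicted)
  attr(out, "n_fits") <- n_fits
  out
}

#' Error discriminant proportion
#'
#' The percentage of actual members of a class that the model predicts
#' into the other class: `fn / (tp + fn) * 100` for the positive class,
#' `fp / (fp + tn) * 100` for the negative class. Proportions below 10%
#' (or the laxer 20%) are the conventional bar for a satisfactory
#' discriminant model.
#'
#' @param table A `confusion_table`.
#' @param which_class `"positive"` or `"negative"`.
#' @return Percentage in `[0, 100]`.
#' @export
error_discriminant_proportion <- function(table,
                                          which_class = c("positive", "negative")) {
  which_class <- match.arg(which_class)
  if (which_class == "positive") {
    ap <- table$tp + table$fn
    if (ap == 0) abort("No actual positives in the table.")
    table$fn / ap * 100
  } else {
    an <- table$fp + table$tn
    if (an == 0) abort("No actual negatives in the table.")
    table$fp / an * 100
  }
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between predicted and actual classes:
#' `(P0 - Pe) / (1 - Pe)` with `P0` the observed agreement and `Pe` the
#' chance agreement from both row and column marginals.
#'
#' @param table A `confusion_table`.
#' @return Kappa (at most 1, full precision; the conventional display
#'   rounds to 3 decimals).
#' @export
#' @examples
#' cohen_kappa(confusion_table(96, 3, 0, 105)) # 0.9707...
cohen_kappa <- function(table) {
  n <- table$tp + table$fn + table$fp + table$tn
  if (n == 0) abort("Empty confusion table.")
  p0 <- (table$tp + table$tn) / n
  ap <- table$tp + table$fn   # actual positive
  an <- table$fp + table$tn   # actual negative
  pp <- table$tp + table$fp   # predicted positive
  pn <- table$fn + table$tn   # predicted negative
  pe <- (ap * pp + an * pn) / n^2
  if (pe >= 1) abort("Degenerate marginals: chance agreement is 1.")
  (p0 - pe) / (1 - pe)
}

#' Exact McNemar test
#'
#' Two-sided exact binomial test on the discordant pair counts `b` and
#' `c` (samples misclassified in one direction vs the other): under the
#' null the discordant outcomes are Binomial(b + c, 1/2), and
#' `p = min(1, 2 P(X <= min(b, c)))`. With no discordant pairs the
#' p-value is 1.
#'
#' @param b,c Non-negative discordant counts (for a confusion table
#'   against the truth, `b = fn` and `c = fp`).
#' @return Exact two-sided p-value in (0, 1].
#' @export
#' @examples
#' mcnemar_exact(3, 0) # 0.25
mcnemar_exact <- function(b, c) {
  if (b < 0 || c < 0 || b != round(b) || c != round(c)) {
    abort("`b` and `c` must be non-negative integers.")
  }
  n <- b + c
  if (n == 0) return(1)
  min(1, 2 * pbinom(min(b, c), n, 0.5))
}

#' Full validation metrics for a confusion table
#'
#' Derives every summary the validation protocol reports: per-class
#' correct and error discriminant proportions, observed and chance
#' agreement, Cohen's kappa, sensitivity, specificity, Youden index, and
#' the exact McNemar p-value on the discordant misclassification counts.
#'
#' @param table A `confusion_table` with both classes non-empty.
#' @return One-row tibble (a `glance()`-style report): `tp, fn, fp, tn,
#'   n, correct_prop_pos, correct_prop_neg, error_prop_pos,
#'   error_prop_neg` (fractions), `p0, pe, kappa, sensitivity,
#'   specificity, youden, mcnemar_p`.
#' @export
summary_metrics <- function(table) {
  ap <- table$tp + table$fn
  an <- table$fp + table$tn
  if (ap == 0 || an == 0) abort("Both classes must be non-empty.")
  n <- ap + an
  sens <- table$tp / ap
  spec <- table$tn / an
  tibble(
    tp = table$tp, fn = table$fn, fp = table$fp, tn = table$tn, n = n,
    correct_prop_pos = table$tp / ap,
    correct_prop_neg = table$tn / an,
    error_prop_pos = table$fn / ap,
    error_prop_neg = table$fp / an,
    p0 = (table$tp + table$tn) / n,
    pe = ((ap * (table$tp + table$fp)) + (an * (table$fn + table$tn))) / n^2,
    kappa = cohen_kappa(table),
    sensitivity = sens,
    specificity = spec,
    youden = sens + spec - 1,
    mcnemar_p = mcnemar_exact(table$fn, table$fp)
  )
}

#' Standardized descriptor sub-matrix for heat-map display
#'
#' Randomly draws `n_per_class` samples per class, restricts the matrix
#' to the model's descriptors and z-scores every descriptor over the
#' drawn samples, the standardization used for the qualitative heat-map
#' check of a discriminant model.
#'
#' @param data Descriptor matrix with a `label` column.
#' @param model A `fisher_model` defining the displayed descriptors.
#' @param n_per_class Samples drawn per class (default 10).
#' @param seed Integer seed; the selection is fully reproducible from it.
#' @return Tibble (class `dpph_heatmap`) with `sample_id`, `label` and the
#'   z-scored descriptor columns, positives first. `autoplot()` renders
#'   the classic green-to-red tile map.
#' @export
heatmap_matrix <- function(data, model, n_per_class = 10, seed = 1) {
  check_descriptor_matrix(data)
  missing_cols <- setdiff(model$descriptors, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing model descriptors: ",
                 paste(missing_cols, collapse = ", ")))
  }
  i1 <- which(data$label == 1L)
  i2 <- which(data$label == 2L)
  if (length(i1) < n_per_class || length(i2) < n_per_class) {
    abort("Each class needs at least `n_per_class` samples.")
  }
  pick <- withr::with_seed(seed, {
    c(sample(i1, n_per_class), sample(i2, n_per_class))
  })
  sub <- data[pick, c(intersect(.meta_cols, names(data)), model$descriptors)]
  for (col in model$descriptors) {
    x <- sub[[col]]
    s <- sd(x)
    sub[[col]] <- if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  class(sub) <- c("dpph_heatmap", class(sub))
  sub
}

#' @rdname heatmap_matrix
#' @param object A `dpph_heatmap`.
#' @param ... Unused.
#' @export
autoplot.dpph_heatmap <- function(object, ...) {
  df <- as_tibble(object)
  df$sample_id <- factor(df$sample_id, levels = rev(df$sample_id))
  long <- tidyr::pivot_longer(df, -dplyr::all_of(intersect(.meta_cols, names(df))),
                              names_to = "descriptor", values_to = "z")
  long$descriptor <- factor(long$descriptor,
                            levels = setdiff(names(df), .meta_cols))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$descriptor, y = .data$sample_id,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "green4", mid = "white",
                                  high = "red3", name = "z") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
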