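# Univariate two-sample t-test screening of descriptors.

#' Screen descriptors by two-sample t-test
#'
#' Tests each descriptor for a class-mean difference between positive
#' (label 1) and negative (label 2) samples. The statistic is signed as
#' `mean(positive) - mean(negative)` over its standard error, so a negative
#' t means the descriptor runs higher in the negative class. A descriptor
#' is retained when its two-sided p-value is below `alpha`; no
#' multiple-testing correction is applied by default (each descriptor is
#' screened at raw `p < alpha`), but `adjust` exposes [stats::p.adjust()]
#' methods.
#'
#' Columns with zero within-class variance in both classes have no defined
#' t: they are flagged `degenerate` and not retained (with `t = 0`,
#' `p = 1` when the class means also coincide).
#'
#' @param data Descriptor matrix with a `label` column (1/2), no missing
#'   cells, and at least two samples per class.
#' @param alpha Significance level (default 0.05).
#' @param variant `"pooled"` (Student, equal variances; default) or
#'   `"welch"`.
#' @param adjust Optional p-value adjustment method passed to
#'   [stats::p.adjust()]; default `"none"`.
#' @param catalog Optional descriptor catalog used to attach the category
#'   code per descriptor (default: the shipped panel; names absent from
#'   the catalog get `NA` category).
#' @return Tibble `descriptor, t, p_value, category, retained, degenerate`,
#'   one row per descriptor column in matrix order.
#' @export
ttest_screen <- function(data, alpha = 0.05,
                         variant = c("pooled", "welch"),
                         adjust = "none",
                         catalog = NULL) {
  variant <- match.arg(variant)
  check_descriptor_matrix(data)
  desc <- descriptor_names(data)
  if (length(desc) == 0) abort("`data` has no descriptor columns.")
  if (anyNA(data[desc])) {
    abort("`data` has missing cells; run `filter_semiconstant()` first.")
  }
  g1 <- data$label == 1L
  g2 <- data$label == 2L
  if (sum(g1) < 2 || sum(g2) < 2) {
    abort("Both classes need at least 2 samples.")
  }

  res <- purrr::map_dfr(desc, function(col) {
    x <- data[[col]][g1]
    y <- data[[col]][g2]
    if (var(x) == 0 && var(y) == 0) {
      same <- mean(x) == mean(y)
      return(tibble(descriptor = col,
                    t = if (same) 0 else NA_real_,
                    p_value = if (same) 1 else NA_real_,
                    degenerate = TRUE))
    }
    ht <- stats::t.test(x, y, var.equal = (variant == "pooled"))
    tibble(descriptor = col, t = unname(ht$statistic),
           p_value = ht$p.value, degenerate = FALSE)
  })
  res$p_value <- stats::p.adjust(res$p_value, method = adjust)
  res$retained <- !res$degenerate & !is.na(res$p_value) & res$p_value < alpha

  if (is.null(catalog)) {
    catalog <- tryCatch(descriptor_catalog(), error = function(e) NULL)
  }
  res$category <- if (!is.null(catalog)) {
    catalog$category[match(res$descriptor, catalog$name)]
  } else {
    NA_character_
  }
  res[, c("descriptor", "t", "p_value", "category", "retained", "degenerate")]
}

#' Count retained descriptors per category
#'
#' Summarizes a screen result into retained counts for the five descriptor
#' categories plus a total row.
#'
#' @param results Tibble from [ttest_screen()].
#' @return Tibble `category, n_retained` with one row per category code
#'   (`DF`, `P`, `T`, `C`, `E`) and a final `total` row.
#' @export
summarize_by_category <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    abort("`results` must be a non-empty screen result.")
  }
  codes <- c("DF", "P", "T", "C", "E")
  kept <- results[results$retained, , drop = FALSE]
  counts <- vapply(codes, function(cc) {
    sum(!is.na(kept$category) & kept$category == cc)
  }, integer(1))
  tibble(
    category = c(codes, "total"),
    n_retained = c(unname(counts), nrow(kept))
  )
}
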