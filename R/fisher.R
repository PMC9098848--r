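# Two-group Fisher classification functions.

#' Fit Fisher classification functions
#'
#' Fits one affine scoring function per class from the pooled within-group
#' covariance `S`: for class `g`, coefficients `S^-1 m_g` and constant
#' `-m_g' S^-1 m_g / 2 + log(prior_g)`, where `m_g` is the class mean
#' vector. A sample is assigned to the class with the larger function
#' value; with equal priors this is the pooled-covariance Gaussian Bayes
#' rule, and the softmax of the two scores is the corresponding posterior.
#'
#' @param data Descriptor matrix with a `label` column (1/2).
#' @param descriptors Descriptor columns to use (default: all), e.g. the
#'   `selected` set of a [stepwise_select()] trace.
#' @param priors Two prior probabilities (positive class first) summing to
#'   1; `"equal"` (default) or `"proportional"` (class frequencies), or a
#'   numeric pair.
#' @return A `fisher_model`: descriptor names, per-class coefficient
#'   vectors and constants, priors, and the descriptor backend version
#'   when known. Supports [classify()], [predict()][predict.fisher_model],
#'   `tidy()` and `glance()`.
#' @export
fit_fisher <- function(data, descriptors = descriptor_names(data),
                       priors = "equal") {
  check_descriptor_matrix(data)
  if (length(descriptors) == 0) abort("`descriptors` must be non-empty.")
  # a class may shrink to a single sample inside a leave-one-out fold; the
  # pooled covariance then rests on the other class's scatter
  sc <- scatter_matrices(data, descriptors, min_per_class = 1)
  n <- sc$n
  g <- sc$g
  priors <- resolve_priors(priors, data$label)

  S <- sc$W / (n - g)
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    abort("Pooled within-group covariance is singular over the selected descriptors.")
  }
  X <- as.matrix(data[descriptors])
  m1 <- colMeans(X[data$label == 1L, , drop = FALSE])
  m2 <- colMeans(X[data$label == 2L, , drop = FALSE])
  b1 <- backsolve(R, forwardsolve(t(R), m1))
  b2 <- backsolve(R, forwardsolve(t(R), m2))

  new_fisher_model(
    descriptors = descriptors,
    coef_pos = unname(b1), coef_neg = unname(b2),
    const_pos = unname(-0.5 * sum(m1 * b1) + log(priors[1])),
    const_neg = unname(-0.5 * sum(m2 * b2) + log(priors[2])),
    priors = priors,
    backend_version = attr(data, "backend_version")
  )
}

resolve_priors <- function(priors, labels = NULL) {
  if (is.character(priors)) {
    priors <- match.arg(priors, c("equal", "proportional"))
    if (priors == "equal") return(c(0.5, 0.5))
    tab <- c(sum(labels == 1L), sum(labels == 2L))
    return(tab / sum(tab))
  }
  if (!is.numeric(priors) || length(priors) != 2 || any(priors <= 0) ||
      abs(sum(priors) - 1) > 1e-8) {
    abort("`priors` must be two positive probabilities summing to 1.")
  }
  priors
}

new_fisher_model <- function(descriptors, coef_pos, coef_neg,
                             const_pos, const_neg, priors,
                             backend_version = NULL) {
  stopifnot(length(coef_pos) == length(descriptors),
            length(coef_neg) == length(descriptors))
  structure(
    list(descriptors = descriptors,
         coef_pos = coef_pos, coef_neg = coef_neg,
         const_pos = const_pos, const_neg = const_neg,
         priors = priors,
         backend_version = backend_version %||% "unknown"),
    class = "fisher_model"
  )
}

#' Classify samples with a Fisher model
#'
#' Evaluates both class functions and assigns each sample to the class
#' with the larger score; a tie (margin exactly 0) resolves to the
#' positive class. The posterior is the softmax of the two scores.
#'
#' @param model A `fisher_model`.
#' @param newdata Data frame containing the model's descriptor columns, or
#'   a named (or model-ordered) numeric vector for a single sample.
#' @return Tibble `score_pos, score_neg, margin, predicted_class,
#'   posterior_pos`, one row per sample; `margin = score_pos - score_neg`
#'   and `predicted_class` is 1 iff `margin >= 0`.
#' @export
classify <- function(model, newdata) {
  if (!inherits(model, "fisher_model")) abort("`model` must be a fisher_model.")
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    if (length(newdata) != length(model$descriptors)) {
      abort("Input vector length does not match the model's descriptor count.")
    }
    if (!is.null(names(newdata))) {
      if (!setequal(names(newdata), model$descriptors)) {
        abort("Input vector names do not match the model's descriptors.")
      }
      newdata <- newdata[model$descriptors]
    }
    X <- matrix(newdata, nrow = 1, dimnames = list(NULL, model$descriptors))
  } else {
    missing_cols <- setdiff(model$descriptors, colnames(newdata))
    if (length(missing_cols) > 0) {
      abort(paste0("Missing model descriptors: ",
                   paste(missing_cols, collapse = ", ")))
    }
    X <- as.matrix(as.data.frame(newdata)[model$descriptors])
  }
  if (any(!is.finite(X))) abort("Descriptor values must all be finite.")

  s1 <- drop(X %*% model$coef_pos) + model$const_pos
  s2 <- drop(X %*% model$coef_neg) + model$const_neg
  margin <- s1 - s2
  tibble(
    score_pos = s1, score_neg = s2, margin = margin,
    predicted_class = ifelse(margin >= 0, 1L, 2L),
    posterior_pos = 1 / (1 + exp(-margin))
  )
}

#' @rdname classify
#' @param object A `fisher_model`.
#' @param ... Unused.
#' @export
predict.fisher_model <- function(object, newdata, ...) {
  classify(object, newdata)
}

#' @export
print.fisher_model <- function(x, ...) {
  cat("Fisher classification functions (2 groups)\n")
  cat(sprintf("  %d descriptor(s); priors %.3f/%.3f; backend %s\n",
              length(x$descriptors), x$priors[1], x$priors[2],
              x$backend_version))
  print(tidy(x), n = length(x$descriptors) + 1)
  invisible(x)
}

#' @rdname fit_fisher
#' @param x,object A `fisher_model`.
#' @param ... Unused.
#' @export
tidy.fisher_model <- function(x, ...) {
  tibble(
    term = c("(constant)", x$descriptors),
    positive = c(x$const_pos, x$coef_pos),
    negative = c(x$const_neg, x$coef_neg)
  )
}

#' @rdname fit_fisher
#' @export
glance.fisher_model <- function(x, ...) {
  tibble(
    n_descriptors = length(x$descriptors),
    prior_positive = x$priors[1],
    prior_negative = x$priors[2],
    backend_version = x$backend_version
  )
}

#' Write / read a Fisher model as human-readable text
#'
#' Key-value text with one tab-separated coefficient row per descriptor.
#' Numbers are written with 17 significant digits, so a write/read round
#' trip is bit-exact.
#'
#' @param model A `fisher_model`.
#' @param path File path.
#' @return `write_fisher_model()`: `path` invisibly;
#'   `read_fisher_model()`: a `fisher_model`.
#' @export
write_fisher_model <- function(model, path) {
  fmt <- function(x) sprintf("%.17g", x)
  lines <- c(
    "format: fisher_model/1",
    "backend: rdkit",
    paste0("backend_version: ", model$backend_version),
    paste0("prior_positive: ", fmt(model$priors[1])),
    paste0("prior_negative: ", fmt(model$priors[2])),
    paste0("const_positive: ", fmt(model$const_pos)),
    paste0("const_negative: ", fmt(model$const_neg)),
    "coefficients:",
    paste(model$descriptors, fmt(model$coef_pos), fmt(model$coef_neg),
          sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fisher_model
#' @export
read_fisher_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  kv_end <- match("coefficients:", lines)
  if (is.na(kv_end)) abort("Model file has no `coefficients:` section.")
  kv <- strsplit(lines[seq_len(kv_end - 1)], ":\\s*")
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = ":"), character(1))
  get <- function(k) vals[match(k, keys)]

  rows <- strsplit(lines[(kv_end + 1):length(lines)], "\t", fixed = TRUE)
  new_fisher_model(
    descriptors = vapply(rows, `[[`, character(1), 1),
    coef_pos = vapply(rows, function(r) as.numeric(r[[2]]), numeric(1)),
    coef_neg = vapply(rows, function(r) as.numeric(r[[3]]), numeric(1)),
    const_pos = as.numeric(get("const_positive")),
    const_neg = as.numeric(get("const_negative")),
    priors = c(as.numeric(get("prior_positive")), as.numeric(get("prior_negative"))),
    backend_version = get("backend_version")
  )
}

#' The published 16-descriptor anti-DPPH classifier
#'
#' Loads the frozen two-group model fitted on the curated sets of 99
#' active and 105 inactive phenolic compounds: 16 descriptors, per-class
#' coefficients and constants -88.150 (positive) and -112.807 (negative),
#' equal priors. The descriptor toolkit version behind the published
#' coefficients is unknown; [screen_compounds()] records the backend
#' version in use alongside its scores.
#'
#' @return A `fisher_model`.
#' @export
#' @examples
#' mod <- load_published_model()
#' length(mod$descriptors) # 16
load_published_model <- function() {
  read_fisher_model(
    system.file("extdata", "published_model.txt", package = "dpphqsar")
  )
}

#' Descriptor names of the published model
#'
#' @return Character vector of the 16 descriptor names in model order.
#' @export
published_descriptors <- function() {
  load_published_model()$descriptors
}
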