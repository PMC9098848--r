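# Pinned descriptor panel and semi-constant filtering.

#' The pinned molecular descriptor catalog
#'
#' The 200-name descriptor panel used throughout the pipeline, with a
#' five-way category code per descriptor: `DF` (drug-likeness and molecular
#' fingerprint density), `P` (physicochemical), `T` (topological), `C`
#' (constitutional), `E` (electronic). The catalog, not the backend's
#' current default list, defines the contract: descriptor backends drift
#' across versions, so the panel is shipped as a file and validated against
#' the backend at compute time.
#'
#' @param path Optional path to a custom catalog CSV with columns
#'   `name, category`; defaults to the shipped 200-descriptor panel.
#' @return Tibble with columns `name` and `category`.
#' @export
#' @examples
#' cat200 <- descriptor_catalog()
#' table(cat200$category)
descriptor_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "descriptor_catalog.csv", package = "dpphqsar")
  }
  cat <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  if (!all(c("name", "category") %in% names(cat))) {
    abort("Catalog must have `name` and `category` columns.")
  }
  if (anyDuplicated(cat$name)) abort("Catalog names must be unique.")
  bad <- setdiff(unique(cat$category), c("DF", "P", "T", "C", "E"))
  if (length(bad) > 0) {
    abort(paste0("Unknown catalog categories: ", paste(bad, collapse = ", ")))
  }
  cat
}

#' Compute the descriptor matrix for a set of compounds
#'
#' Computes one column per catalog name, in catalog order, through the
#' RDKit backend. Compounds whose structure fails wholesale are dropped
#' with a warning; isolated failed cells are left missing (`NA`) and are
#' median-imputed by [filter_semiconstant()].
#'
#' @param compounds Compound tibble with `id` and `smiles` columns;
#'   an `activity_class` column, when present, becomes the matrix `label`.
#' @param catalog Descriptor catalog tibble (default: the shipped panel).
#'   May be restricted to a subset, e.g. the 16 descriptors of the
#'   published model via `descriptor_catalog()` filtered to
#'   `published_descriptors()`.
#' @return Descriptor matrix: tibble with `sample_id`, `label` and one
#'   numeric column per catalog name. The backend version is recorded in
#'   attribute `"backend_version"`.
#' @export
compute_descriptors <- function(compounds, catalog = descriptor_catalog()) {
  if (!is.data.frame(compounds) || nrow(compounds) == 0) {
    abort("`compounds` must be a non-empty data frame.")
  }
  if (!all(c("id", "smiles") %in% names(compounds))) {
    abort("`compounds` must have `id` and `smiles` columns.")
  }
  if (nrow(catalog) == 0) abort("`catalog` must be non-empty.")
  res <- rdkit_descriptors(compounds$id, compounds$smiles, catalog$name)
  failed <- res$ok != 1L | is.na(res$ok)
  if (any(failed)) {
    warn(paste0("Dropped ", sum(failed), " compound(s) with unparseable ",
                "structures: ", paste(res$id[failed], collapse = ", ")))
  }
  keep <- !failed
  out <- tibble(
    sample_id = res$id[keep],
    label = if ("activity_class" %in% names(compounds)) {
      as.integer(compounds$activity_class[keep])
    } else NA_integer_
  )
  out <- dplyr::bind_cols(out, res[keep, catalog$name, drop = FALSE])
  attr(out, "backend_version") <- rdkit_version()
  out
}

#' Exclude semi-constant descriptors
#'
#' A descriptor is semi-constant when the relative frequency of its modal
#' value is strictly greater than `threshold` (default 0.80): such columns
#' carry almost no information and inflate the later multivariate fits.
#' A column with exactly `threshold` modal frequency is retained.
#'
#' Columns with missing cells (isolated backend failures) are
#' median-imputed first, with a warning. Exclusions are recorded in the
#' `"excluded"` attribute of the result as a tibble
#' `descriptor, reason, modal_frequency`.
#'
#' @param data Descriptor matrix.
#' @param threshold Modal-frequency threshold in (0, 1] (default 0.80).
#' @return The matrix without the excluded columns, original column order
#'   preserved. Idempotent and never increases the column count.
#' @export
filter_semiconstant <- function(data, threshold = 0.80) {
  check_descriptor_matrix(data, require_label = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    abort("`threshold` must be a single number in (0, 1].")
  }
  desc <- descriptor_names(data)
  if (nrow(data) == 0 || length(desc) == 0) abort("`data` must be non-empty.")

  n_missing <- vapply(data[desc], function(x) sum(is.na(x)), integer(1))
  if (any(n_missing > 0)) {
    impute <- names(n_missing)[n_missing > 0]
    warn(paste0("Median-imputed missing cells in ", length(impute),
                " column(s): ", paste(impute, collapse = ", ")))
    for (col in impute) {
      x <- data[[col]]
      x[is.na(x)] <- median(x, na.rm = TRUE)
      data[[col]] <- x
    }
  }

  modal_freq <- vapply(data[desc], function(x) {
    max(table(x)) / length(x)
  }, numeric(1))
  drop <- modal_freq > threshold
  out <- data[, c(intersect(.meta_cols, names(data)), desc[!drop]), drop = FALSE]
  attr(out, "backend_version") <- attr(data, "backend_version")
  attr(out, "excluded") <- tibble(
    descriptor = desc[drop],
    reason = rep("semiconstant", sum(drop)),
    modal_frequency = unname(modal_freq[drop])
  )
  out
}

#' Descriptors excluded by the last filtering step
#'
#' @param data A descriptor matrix returned by [filter_semiconstant()].
#' @return Tibble `descriptor, reason, modal_frequency` (empty if nothing
#'   was excluded).
#' @export
excluded_descriptors <- function(data) {
  ex <- attr(data, "excluded")
  if (is.null(ex)) {
    tibble(descriptor = character(), reason = character(),
           modal_frequency = numeric())
  } else {
    ex
  }
}
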