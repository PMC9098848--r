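# Compound ingestion and activity-class assignment.

#' DPPH radical scavenging activity
#'
#' Percent scavenging from a paired absorbance read: `(a0 - a) / a0 * 100`,
#' where `a0` is the absorbance of the DPPH solution without antioxidant and
#' `a` with the antioxidant present. A value above 100 cannot occur for
#' non-negative `a`; a negative value (a pro-oxidant read, `a > a0`) is
#' returned as-is.
#'
#' @param a0 Absorbance without antioxidant (must be positive). Vectorized.
#' @param a Absorbance with antioxidant (non-negative). Vectorized.
#' @return Percent scavenging, same length as the inputs.
#' @export
#' @examples
#' dpph_scavenging(a0 = 1.0, a = 0.25) # 75
dpph_scavenging <- function(a0, a) {
  if (any(!is.finite(a0)) || any(a0 <= 0)) {
    abort("Invalid assay: `a0` must be positive and finite.")
  }
  if (any(!is.finite(a)) || any(a < 0)) {
    abort("Invalid assay: `a` must be non-negative and finite.")
  }
  (a0 - a) / a0 * 100
}

#' Assign binary activity classes from potency
#'
#' Compounds with IC50/EC50 at or below the cut point are labelled positive
#' (class 1); above it, negative (class 2). The default 300 uM cut point is
#' the conventional threshold beyond which a DPPH scavenger is not worth
#' pursuing as a lead; a potency of exactly 300 uM is classed positive.
#' Rows without a potency are labelled negative when an `inactive` logical
#' column flags them as curated inactives; otherwise they are an error.
#'
#' @param compounds Data frame with a `potency_um` column (positive reals,
#'   uM; `NA` allowed when an `inactive` flag column is present).
#' @param cut_point_um Potency cut point in uM (default 300).
#' @return The input as a tibble with an integer `activity_class` column
#'   (1 = positive, 2 = negative). Idempotent: depends only on
#'   `potency_um`, `inactive` and the cut point.
#' @export
#' @examples
#' assign_activity_class(data.frame(id = "x", potency_um = 250))
assign_activity_class <- function(compounds, cut_point_um = 300) {
  if (!is.data.frame(compounds)) abort("`compounds` must be a data frame.")
  if (!is.numeric(cut_point_um) || length(cut_point_um) != 1 || cut_point_um <= 0) {
    abort("`cut_point_um` must be a single positive number.")
  }
  compounds <- as_tibble(compounds)
  potency <- if ("potency_um" %in% names(compounds)) {
    compounds$potency_um
  } else {
    rep(NA_real_, nrow(compounds))
  }
  if (any(!is.na(potency) & potency <= 0)) {
    abort("`potency_um` must be positive where present.")
  }
  inactive <- if ("inactive" %in% names(compounds)) {
    isTRUE_vec(compounds$inactive)
  } else {
    rep(FALSE, nrow(compounds))
  }
  unlabelable <- is.na(potency) & !inactive
  if (any(unlabelable)) {
    abort(paste0(
      "Cannot label ", sum(unlabelable),
      " compound(s): no potency and no `inactive` flag."
    ))
  }
  cls <- ifelse(is.na(potency), 2L, ifelse(potency <= cut_point_um, 1L, 2L))
  compounds$activity_class <- as.integer(cls)
  compounds
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  !is.na(x) & tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Read compound records
#'
#' Reads compounds from a delimited table, an SDF (V2000), or a plain
#' SMILES list. SMILES are canonicalized on ingest; records whose structure
#' does not parse are skipped with a warning naming the offending records,
#' and duplicated canonical structures are collapsed to the first
#' occurrence.
#'
#' The delimited format is UTF-8 CSV with a header and columns
#' `id, smiles, potency_um, label, source` (`potency_um`, `label` and
#' `source` optional; `label` is `positive`/`negative`, and an optional
#' logical `inactive` column marks curated inactives without a potency).
#' A SMILES list has one structure per line with an optional tab-separated
#' identifier.
#'
#' @param path Input file path.
#' @param format One of `"delimited"`, `"sdf"`, `"smiles_list"`.
#' @param canonicalize Canonicalize SMILES through the descriptor backend
#'   (default `TRUE`; requires the Python backend).
#' @return Tibble with columns `id`, `smiles`, `potency_um`,
#'   `activity_class` (`NA` until assigned, unless a `label` column was
#'   present), `inactive`, `source`.
#' @export
read_compounds <- function(path,
                           format = c("delimited", "sdf", "smiles_list"),
                           canonicalize = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- switch(format,
    delimited = read_compounds_delimited(path),
    sdf = rdkit_sdf_to_smiles(path) |>
      dplyr::mutate(potency_um = NA_real_, label = NA_character_,
                    inactive = FALSE, source = NA_character_),
    smiles_list = read_compounds_smiles_list(path)
  )
  if (nrow(raw) == 0) abort("No records found in input.")

  if (canonicalize && format != "sdf") {
    raw$smiles <- rdkit_canonicalize(raw$smiles)
  }
  bad <- is.na(raw$smiles)
  if (any(bad)) {
    warn(paste0(
      "Skipped ", sum(bad), " record(s) with unparseable structures: ",
      paste(raw$id[bad], collapse = ", ")
    ))
    raw <- raw[!bad, , drop = FALSE]
  }
  if (nrow(raw) == 0) abort("No valid records after structure parsing.")

  dup <- duplicated(raw$smiles)
  if (any(dup)) {
    warn(paste0("Collapsed ", sum(dup),
                " duplicate structure(s); first occurrence kept."))
    raw <- raw[!dup, , drop = FALSE]
  }

  cls <- rep(NA_integer_, nrow(raw))
  if (any(!is.na(raw$label))) {
    lab <- tolower(raw$label)
    cls[lab %in% "positive"] <- 1L
    cls[lab %in% "negative"] <- 2L
  }
  tibble(
    id = as.character(raw$id),
    smiles = raw$smiles,
    potency_um = raw$potency_um,
    activity_class = cls,
    inactive = raw$inactive,
    source = raw$source
  )
}

read_compounds_delimited <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!all(c("id", "smiles") %in% names(df))) {
    abort("Delimited input must have `id` and `smiles` columns.")
  }
  tibble(
    id = df$id,
    smiles = df$smiles,
    potency_um = if ("potency_um" %in% names(df)) as.numeric(df$potency_um) else NA_real_,
    label = if ("label" %in% names(df)) df$label else NA_character_,
    inactive = if ("inactive" %in% names(df)) isTRUE_vec(df$inactive) else FALSE,
    source = if ("source" %in% names(df)) df$source else NA_character_
  )
}

read_compounds_smiles_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    smiles = vapply(parts, `[[`, character(1), 1),
    id = vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) > 1 && nzchar(parts[[i]][[2]])) parts[[i]][[2]]
      else paste0("record_", i)
    }, character(1)),
    potency_um = NA_real_, label = NA_character_,
    inactive = FALSE, source = NA_character_
  )
}

#' Write compound records to the delimited format
#'
#' Inverse of [read_compounds()] for the delimited format: `id`,
#' `potency_um` and assigned classes round-trip exactly.
#'
#' @param compounds Compound tibble (as returned by [read_compounds()] or
#'   [assign_activity_class()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_compounds <- function(compounds, path) {
  out <- tibble(
    id = as.character(compounds$id),
    smiles = compounds$smiles,
    potency_um = if ("potency_um" %in% names(compounds)) compounds$potency_um else NA_real_,
    label = if ("activity_class" %in% names(compounds)) {
      c("positive", "negative")[compounds$activity_class]
    } else NA_character_,
    inactive = if ("inactive" %in% names(compounds)) compounds$inactive else FALSE,
    source = if ("source" %in% names(compounds)) compounds$source else NA_character_
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}
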