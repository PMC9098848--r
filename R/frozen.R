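# In silico screening of new structures with the published classifier.

#' Screen compounds with the published anti-DPPH classifier
#'
#' For each compound, computes the published model's 16 descriptors,
#' evaluates both classification functions and reports the predicted
#' class and margin — the in silico pre-filter intended to run before in
#' vitro assays. Compounds whose structure fails the backend come back
#' flagged (`flagged = TRUE`) with no scores rather than being silently
#' dropped.
#'
#' The descriptor backend version in use is recorded in the result's
#' `"backend_version"` attribute; because the published coefficients were
#' fitted under an unspecified toolkit version, a one-time warning
#' signals that scores may drift across backend versions when the model
#' does not pin one.
#'
#' @param compounds Compound tibble with `id` and `smiles` columns
#'   (e.g. from [read_compounds()] or [toy_phenol_set()]).
#' @param model The classifier to apply (default: the published
#'   16-descriptor model).
#' @return Tibble with `id`, `smiles`, the 16 descriptor columns in model
#'   order, `score_pos`, `score_neg`, `predicted_class` (1/2, `NA` when
#'   flagged), `margin`, `flagged`.
#' @export
screen_compounds <- function(compounds, model = load_published_model()) {
  if (!is.data.frame(compounds) || nrow(compounds) == 0) {
    abort("`compounds` must be a non-empty data frame.")
  }
  if (!all(c("id", "smiles") %in% names(compounds))) {
    abort("`compounds` must have `id` and `smiles` columns.")
  }
  backend <- rdkit_version()
  if (!identical(model$backend_version, backend)) {
    warn(paste0(
      "Model descriptor backend (", model$backend_version, ") differs from ",
      "the one in use (", backend, "); scores may drift across versions."
    ), .frequency = "once", .frequency_id = "dpphqsar_backend_drift")
  }
  raw <- rdkit_descriptors(compounds$id, compounds$smiles, model$descriptors)
  ok <- raw$ok == 1L & !Reduce(`|`, lapply(raw[model$descriptors], is.na))

  out <- dplyr::bind_cols(
    tibble(id = as.character(compounds$id), smiles = compounds$smiles),
    raw[model$descriptors]
  )
  out$score_pos <- NA_real_
  out$score_neg <- NA_real_
  out$predicted_class <- NA_integer_
  out$margin <- NA_real_
  out$flagged <- !ok
  if (any(ok)) {
    pred <- classify(model, out[ok, model$descriptors, drop = FALSE])
    out$score_pos[ok] <- pred$score_pos
    out$score_neg[ok] <- pred$score_neg
    out$predicted_class[ok] <- pred$predicted_class
    out$margin[ok] <- pred$margin
  }
  attr(out, "backend_version") <- backend
  out
}
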