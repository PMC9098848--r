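# Synthetic two-class descriptor matrices and a toy phenolic compound set.

#' Specification of a synthetic two-class descriptor matrix
#'
#' Describes a matrix with the statistical structure the pipeline
#' assumes: a small informative descriptor subset with shifted class
#' means, pure-noise descriptors, optional within-class equicorrelation,
#' planted semi-constant columns and exact duplicate columns. The
#' defaults mirror the curated anti-DPPH study design: 99 positive and
#' 105 negative samples, 200 descriptors of which 16 carry a class-mean
#' gap of 1.5 pooled standard deviations.
#'
#' @param n_pos,n_neg Samples per class (default 99 / 105).
#' @param n_informative Descriptors with a class-mean gap (default 16).
#' @param n_noise Pure-noise descriptors (default 184).
#' @param effect_size Class-mean gap of informative descriptors in pooled
#'   SD units (default 1.5).
#' @param correlation Within-class equicorrelation among Gaussian
#'   descriptors, in `[0, 1)` (default 0).
#' @param n_semiconstant Planted near-constant columns, 85% zeros / 15%
#'   random positives (default 0).
#' @param n_duplicate Exact copies of the first informative columns
#'   (default 0).
#' @param n_poisson Noise columns drawn as Poisson counts (mean 3) rather
#'   than Gaussians, to emulate integer fragment-count descriptors
#'   (default 0, must be `<= n_noise`).
#' @param seed Integer seed (default 1); generation is fully reproducible
#'   from the spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_pos = 99, n_neg = 105, n_informative = 16,
                           n_noise = 184, effect_size = 1.5,
                           correlation = 0, n_semiconstant = 0,
                           n_duplicate = 0, n_poisson = 0, seed = 1) {
  counts <- c(n_pos, n_neg, n_informative, n_noise, n_semiconstant,
              n_duplicate, n_poisson)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("All counts must be non-negative integers.")
  }
  if (n_pos < 2 || n_neg < 2) abort("Need at least 2 samples per class.")
  if (effect_size < 0) abort("`effect_size` must be non-negative.")
  if (correlation < 0 || correlation >= 1) {
    abort("`correlation` must be in [0, 1).")
  }
  if (n_poisson > n_noise) abort("`n_poisson` cannot exceed `n_noise`.")
  if (n_duplicate > n_informative) {
    abort("`n_duplicate` cannot exceed `n_informative`.")
  }
  structure(
    list(n_pos = n_pos, n_neg = n_neg, n_informative = n_informative,
         n_noise = n_noise, effect_size = effect_size,
         correlation = correlation, n_semiconstant = n_semiconstant,
         n_duplicate = n_duplicate, n_poisson = n_poisson, seed = seed),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic two-class descriptor matrix
#'
#' Informative columns are unit-variance Gaussians whose class means sit
#' `effect_size` apart (symmetric around 0); noise columns have zero gap.
#' With `correlation > 0` the Gaussian columns share a per-sample common
#' factor so that every pair has the requested equicorrelation while the
#' marginal variance stays 1. Semi-constant columns are 85% exact zeros
#' (modal frequency > 0.8 by construction) and duplicates are bit-exact
#' copies of the leading informative columns.
#'
#' Column names record their role: `inf_*`, `noise_*`, `pois_*`,
#' `semiconst_*`, `dup_inf_*`.
#'
#' @param spec A [synthetic_spec()].
#' @return Descriptor matrix tibble (`sample_id`, `label`, descriptor
#'   columns), identical for identical specs.
#' @export
#' @examples
#' m <- generate_two_class(synthetic_spec(n_pos = 10, n_neg = 10,
#'                                        n_informative = 2, n_noise = 3))
generate_two_class <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    abort("`spec` must be a `synthetic_spec`.")
  }
  n <- spec$n_pos + spec$n_neg
  label <- c(rep(1L, spec$n_pos), rep(2L, spec$n_neg))

  withr::with_seed(spec$seed, {
    n_gauss_noise <- spec$n_noise - spec$n_poisson
    p_gauss <- spec$n_informative + n_gauss_noise
    X <- matrix(rnorm(n * p_gauss), n, p_gauss)
    if (spec$correlation > 0 && p_gauss > 1) {
      common <- rnorm(n)
      X <- sqrt(spec$correlation) * common +
        sqrt(1 - spec$correlation) * X
    }
    if (spec$n_informative > 0) {
      shift <- ifelse(label == 1L, spec$effect_size / 2, -spec$effect_size / 2)
      X[, seq_len(spec$n_informative)] <-
        X[, seq_len(spec$n_informative), drop = FALSE] + shift
    }
    cols <- list()
    nm <- character()
    if (spec$n_informative > 0) {
      nm <- c(nm, sprintf("inf_%02d", seq_len(spec$n_informative)))
    }
    if (n_gauss_noise > 0) {
      nm <- c(nm, sprintf("noise_%03d", seq_len(n_gauss_noise)))
    }
    out <- as.data.frame(X)
    names(out) <- nm
    if (spec$n_poisson > 0) {
      for (j in seq_len(spec$n_poisson)) {
        out[[sprintf("pois_%03d", j)]] <- rpois(n, 3)
      }
    }
    if (spec$n_semiconstant > 0) {
      n_nonzero <- n - floor(0.85 * n)
      for (j in seq_len(spec$n_semiconstant)) {
        x <- numeric(n)
        x[sample(n, n_nonzero)] <- runif(n_nonzero, 0.5, 2)
        out[[sprintf("semiconst_%02d", j)]] <- x
      }
    }
    if (spec$n_duplicate > 0) {
      for (j in seq_len(spec$n_duplicate)) {
        out[[sprintf("dup_inf_%02d", j)]] <- out[[sprintf("inf_%02d", j)]]
      }
    }
    dplyr::bind_cols(
      tibble(sample_id = sprintf("s%03d", seq_len(n)), label = label),
      as_tibble(out)
    )
  })
}

#' A fixed toy set of phenolic compounds
#'
#' Twenty-five valid structures — classic phenolic antioxidants (phenol,
#' catechol, pyrogallol, gallic and caffeic acids, flavonoids, ...) plus
#' non-phenolic decoys — with toy IC50 potencies spanning both sides of
#' the 300 uM cut point. A stand-in fixture for curated literature sets:
#' the potencies are invented and carry no experimental meaning.
#'
#' @return Compound tibble (`id`, `smiles`, `potency_um`, `source`)
#'   ready for [assign_activity_class()] and [compute_descriptors()].
#' @export
toy_phenol_set <- function() {
  tibble::tribble(
    ~id, ~smiles, ~potency_um,
    "phenol",            "c1ccccc1O",                         220,
    "catechol",          "c1ccc(O)c(O)c1",                     45,
    "resorcinol",        "c1cc(O)cc(O)c1",                    180,
    "hydroquinone",      "Oc1ccc(O)cc1",                       30,
    "pyrogallol",        "Oc1cccc(O)c1O",                      12,
    "gallic_acid",       "OC(=O)c1cc(O)c(O)c(O)c1",             8,
    "protocatechuic",    "OC(=O)c1ccc(O)c(O)c1",               25,
    "vanillic_acid",     "COc1cc(C(O)=O)ccc1O",               150,
    "syringic_acid",     "COc1cc(C(O)=O)cc(OC)c1O",           120,
    "caffeic_acid",      "OC(=O)/C=C/c1ccc(O)c(O)c1",          18,
    "ferulic_acid",      "COc1cc(/C=C/C(O)=O)ccc1O",           55,
    "p_coumaric_acid",   "OC(=O)/C=C/c1ccc(O)cc1",            290,
    "quercetin",         "O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12", 10,
    "kaempferol",        "O=c1c(O)c(-c2ccc(O)cc2)oc2cc(O)cc(O)c12",    22,
    "catechin",          "OC1Cc2c(O)cc(O)cc2OC1c1ccc(O)c(O)c1", 15,
    "resveratrol",       "Oc1ccc(/C=C/c2cc(O)cc(O)c2)cc1",     60,
    "tyrosol",           "OCCc1ccc(O)cc1",                    320,
    "eugenol",           "COc1cc(CC=C)ccc1O",                 260,
    "thymol",            "Cc1ccc(C(C)C)c(O)c1",               450,
    "carvacrol",         "Cc1ccc(C(C)C)cc1O",                 480,
    "anisole",           "COc1ccccc1",                       2000,
    "toluene",           "Cc1ccccc1",                        5000,
    "benzoic_acid",      "OC(=O)c1ccccc1",                   1500,
    "cyclohexanol",      "OC1CCCCC1",                        3000,
    "naphthalene",       "c1ccc2ccccc2c1",                   4000
  ) |>
    dplyr::mutate(source = "toy")
}
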