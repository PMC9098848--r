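# Bridge to the RDKit descriptor backend. RDKit has no R binding; the
# package shells out to a bundled Python helper over plain text files.

the <- new.env(parent = emptyenv())

#' Locate the Python interpreter used for the descriptor backend
#'
#' Resolution order: option `dpphqsar.python`, environment variable
#' `DPPHQSAR_PYTHON`, then `python` / `python3` on the PATH.
#'
#' @return Path to the interpreter.
#' @keywords internal
rdkit_python <- function() {
  opt <- getOption("dpphqsar.python", "")
  if (nzchar(opt)) return(opt)
  env <- Sys.getenv("DPPHQSAR_PYTHON", "")
  if (nzchar(env)) return(env)
  for (cand in c("python", "python3")) {
    path <- Sys.which(cand)
    if (nzchar(path)) return(unname(path))
  }
  abort("No Python interpreter found; set option `dpphqsar.python`.")
}

rdkit_script <- function() {
  path <- system.file("python", "rdkit_descriptors.py", package = "dpphqsar")
  if (!nzchar(path)) abort("Bundled descriptor helper script not found.")
  path
}

rdkit_call <- function(args) {
  out <- tempfile(fileext = ".out")
  err <- tempfile(fileext = ".err")
  on.exit(unlink(c(out, err)), add = TRUE)
  status <- suppressWarnings(
    system2(rdkit_python(), c(shQuote(rdkit_script()), args),
            stdout = out, stderr = err)
  )
  if (!identical(status, 0L)) {
    msg <- tryCatch(readLines(err, warn = FALSE), error = function(e) character())
    abort(c("Descriptor backend call failed.", paste(msg, collapse = "\n")))
  }
  readLines(out, warn = FALSE)
}

#' Version of the RDKit descriptor backend
#'
#' @return Version string of the Python rdkit package in use (memoized for
#'   the session).
#' @export
#' @examples
#' \dontrun{rdkit_version()}
rdkit_version <- function() {
  if (is.null(the$rdkit_version)) {
    the$rdkit_version <- rdkit_call("version")[[1]]
  }
  the$rdkit_version
}

#' Descriptor names known to the backend
#' @return Character vector of descriptor names the backend can compute.
#' @keywords internal
rdkit_descriptor_list <- function() {
  if (is.null(the$rdkit_names)) {
    the$rdkit_names <- rdkit_call("list")
  }
  the$rdkit_names
}

write_id_smiles <- function(ids, smiles) {
  path <- tempfile(fileext = ".tsv")
  writeLines(paste(ids, smiles, sep = "\t"), path, useBytes = TRUE)
  path
}

#' Canonicalize SMILES strings
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES; `NA` where a string does
#'   not parse to a molecule.
#' @export
#' @examples
#' \dontrun{rdkit_canonicalize(c("OC1=CC=CC=C1", "c1ccccc1O"))}
rdkit_canonicalize <- function(smiles) {
  if (length(smiles) == 0) return(character())
  inp <- write_id_smiles(seq_along(smiles), smiles)
  on.exit(unlink(inp), add = TRUE)
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(out), add = TRUE)
  rdkit_call(c("canonicalize", shQuote(inp), shQuote(out)))
  lines <- readLines(out, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  res <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else "", character(1))
  res[!nzchar(res)] <- NA_character_
  res[order(as.integer(vapply(parts, `[[`, character(1), 1)))]
}

# Raw descriptor computation: one row per input id, `ok` flag per molecule,
# NA cells where a single descriptor failed.
rdkit_descriptors <- function(ids, smiles, names) {
  stopifnot(length(ids) == length(smiles))
  unknown <- setdiff(names, rdkit_descriptor_list())
  if (length(unknown) > 0) {
    abort(paste0("Descriptors unknown to the backend: ",
                 paste(unknown, collapse = ", ")))
  }
  inp <- write_id_smiles(ids, smiles)
  names_path <- tempfile(fileext = ".txt")
  writeLines(names, names_path)
  out <- tempfile(fileext = ".csv")
  on.exit(unlink(c(inp, names_path, out)), add = TRUE)
  rdkit_call(c("descriptors", shQuote(inp), shQuote(names_path), shQuote(out)))
  res <- readr::read_csv(out, col_types = readr::cols(
    id = readr::col_character(),
    ok = readr::col_integer(),
    .default = readr::col_double()
  ), progress = FALSE)
  res[match(as.character(ids), res$id), , drop = FALSE]
}

rdkit_sdf_to_smiles <- function(path) {
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(out), add = TRUE)
  rdkit_call(c("sdf2smi", shQuote(path), shQuote(out)))
  lines <- readLines(out, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    id = vapply(parts, `[[`, character(1), 1),
    smiles = vapply(parts, function(p) if (length(p) > 1 && nzchar(p[[2]])) p[[2]] else NA_character_, character(1))
  )
}
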