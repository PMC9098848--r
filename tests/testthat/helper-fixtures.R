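# Small plain-text chemistry fixtures, built in code at test time.

write_compound_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("id,smiles,potency_um,label,source", rows), path)
  path
}

phenol_molblock <- function() {
  paste(
    "phenol",
    "     RDKit          2D",
    "",
    "  7  7  0  0  0  0  0  0  0  0999 V2000",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.7500   -1.2990    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.7500   -1.2990    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.7500    1.2990    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.7500    1.2990    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    2.5981    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  2  0",
    "  2  3  1  0",
    "  3  4  2  0",
    "  4  5  1  0",
    "  5  6  2  0",
    "  6  7  1  0",
    "  6  1  1  0",
    "M  END",
    "$$$$",
    sep = "\n"
  )
}
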