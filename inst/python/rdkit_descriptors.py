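"""Descriptor backend bridge: thin command-line wrapper around RDKit.

Invoked by the R package through subprocess; all I/O is via plain text
files so that no Python<->R binding is needed.

Modes:
    version                         print rdkit version
    list                            print one available descriptor name per line
    canonicalize IN OUT             IN: tsv id<TAB>smiles; OUT: tsv id, canonical
                                    smiles (empty field if unparseable)
    sdf2smi IN OUT                  IN: SDF (V2000); OUT: tsv id, canonical smiles
    descriptors IN NAMES OUT        IN: tsv id<TAB>smiles; NAMES: one descriptor
                                    name per line; OUT: csv id,ok,<names...>
                                    (ok=0 and empty values if the molecule fails)
"""

import sys
import csv

from rdkit import Chem, rdBase
from rdkit.Chem import Descriptors
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")

DESC_FUNS = dict(Descriptors.descList)


def read_tsv(path):
    rows = []
    with open(path, encoding="utf-8") as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            parts = line.split("\t")
            rows.append((parts[0], parts[1] if len(parts) > 1 else ""))
    return rows


def canonical(smiles):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return None
    return Chem.MolToSmiles(mol)


def cmd_canonicalize(inp, out):
    with open(out, "w", encoding="utf-8") as fh:
        for ident, smi in read_tsv(inp):
            can = canonical(smi)
            fh.write("%s\t%s\n" % (ident, "" if can is None else can))


def cmd_sdf2smi(inp, out):
    supplier = Chem.SDMolSupplier(inp, sanitize=True)
    with open(out, "w", encoding="utf-8") as fh:
        for i, mol in enumerate(supplier):
            if mol is None:
                fh.write("record_%d\t\n" % (i + 1))
                continue
            name = mol.GetProp("_Name") if mol.HasProp("_Name") else ""
            if not name.strip():
                name = "record_%d" % (i + 1)
            fh.write("%s\t%s\n" % (name.strip(), Chem.MolToSmiles(mol)))


def cmd_descriptors(inp, names_path, out):
    with open(names_path, encoding="utf-8") as fh:
        names = [ln.strip() for ln in fh if ln.strip()]
    unknown = [n for n in names if n not in DESC_FUNS]
    if unknown:
        sys.stderr.write("unknown descriptors: %s\n" % ",".join(unknown))
        sys.exit(3)
    with open(out, "w", newline="", encoding="utf-8") as fh:
        writer = csv.writer(fh)
        writer.writerow(["id", "ok"] + names)
        for ident, smi in read_tsv(inp):
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                writer.writerow([ident, 0] + [""] * len(names))
                continue
            values = []
            for n in names:
                try:
                    v = DESC_FUNS[n](mol)
                    values.append(repr(float(v)))
                except Exception:
                    values.append("")
            writer.writerow([ident, 1] + values)


def main(argv):
    mode = argv[1]
    if mode == "version":
        print(rdBase.rdkitVersion)
    elif mode == "list":
        for n in DESC_FUNS:
            print(n)
    elif mode == "canonicalize":
        cmd_canonicalize(argv[2], argv[3])
    elif mode == "sdf2smi":
        cmd_sdf2smi(argv[2], argv[3])
    elif mode == "descriptors":
        cmd_descriptors(argv[2], argv[3], argv[4])
    else:
        sys.stderr.write("unknown mode: %s\n" % mode)
        sys.exit(2)


if __name__ == "__main__":
    main(sys.argv)
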