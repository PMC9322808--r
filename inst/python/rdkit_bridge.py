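"""Fingerprint bridge: parse compound files with RDKit, emit canonical SMILES
and Morgan fingerprint on-bits as TSV on stdout.

Output columns: record_index, compound_id, status (ok|invalid),
canonical_smiles, comma-joined on-bit indices (0-based).

Formats:
  smi -- one record per line, "SMILES<whitespace>identifier"; '#' comments and
         blank lines are skipped (they do not consume a record index).
  tsv -- "SMILES<TAB>identifier" with no comment handling (internal use: the
         SMILES field may be empty, which is reported as invalid).
  sdf -- MDL SD file; identifier from --id-property, else the title line.
"""

import argparse
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")


def emit(idx, cid, mol, gen):
    if mol is None:
        return f"{idx}\t{cid}\tinvalid\t\t"
    smi = Chem.MolToSmiles(mol)
    bits = ",".join(str(b) for b in gen.GetFingerprint(mol).GetOnBits())
    return f"{idx}\t{cid}\tok\t{smi}\t{bits}"


def iter_smi(path, strict_tab):
    idx = 0
    with open(path) as fh:
        for lineno, line in enumerate(fh, start=1):
            line = line.rstrip("\n")
            if strict_tab:
                parts = line.split("\t")
                smi = parts[0] if parts else ""
                cid = parts[1] if len(parts) > 1 and parts[1] else f"C{lineno:06d}"
            else:
                if not line.strip() or line.lstrip().startswith("#"):
                    continue
                parts = line.split(None, 1)
                smi = parts[0]
                cid = parts[1].strip() if len(parts) > 1 else f"C{lineno:06d}"
            idx += 1
            mol = Chem.MolFromSmiles(smi) if smi else None
            yield idx, lineno, cid, mol


def iter_sdf(path, id_property):
    supplier = Chem.SDMolSupplier(path, sanitize=True)
    for idx, mol in enumerate(supplier, start=1):
        if mol is None:
            yield idx, idx, f"C{idx:06d}", None
            continue
        cid = None
        if id_property and mol.HasProp(id_property):
            cid = mol.GetProp(id_property).strip()
        if not cid and mol.HasProp("_Name"):
            cid = mol.GetProp("_Name").strip()
        yield idx, idx, cid or f"C{idx:06d}", mol


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--input", required=True)
    ap.add_argument("--format", choices=["smi", "sdf", "tsv"], required=True)
    ap.add_argument("--radius", type=int, default=2)
    ap.add_argument("--n-bits", type=int, default=2048)
    ap.add_argument("--id-property", default=None)
    args = ap.parse_args()

    gen = rdFingerprintGenerator.GetMorganGenerator(
        radius=args.radius, fpSize=args.n_bits
    )
    if args.format == "sdf":
        records = iter_sdf(args.input, args.id_property)
    else:
        records = iter_smi(args.input, strict_tab=(args.format == "tsv"))
    out = sys.stdout
    for idx, lineno, cid, mol in records:
        print(emit(lineno, cid, mol, gen), file=out)


if __name__ == "__main__":
    main()
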