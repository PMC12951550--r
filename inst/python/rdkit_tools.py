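"""Batch SMILES utilities backed by RDKit.

Called by the R package as:  python rdkit_tools.py <in.json> <out.json>
Input : {"smiles": [...], "radius": int, "n_bits": int, "want_fp": 0/1}
Output: list of records, one per input SMILES, in order:
  {"ok": bool, "canonical": str|None, "n_frags": int, "bits": [int, ...]}
`bits` are the on-bit indices (0-based) of the Morgan/ECFP fingerprint.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")


def main(path_in, path_out):
    with open(path_in) as fh:
        req = json.load(fh)
    if isinstance(req["smiles"], str):  # guard against unboxed scalars
        req["smiles"] = [req["smiles"]]
    radius = int(req.get("radius", 2))
    n_bits = int(req.get("n_bits", 2048))
    want_fp = bool(req.get("want_fp", 1))
    gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius,
                                                    fpSize=n_bits)
    out = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"ok": False, "canonical": None, "n_frags": 0,
                        "bits": []})
            continue
        rec = {"ok": True,
               "canonical": Chem.MolToSmiles(mol),
               "n_frags": len(Chem.GetMolFrags(mol)),
               "bits": []}
        if want_fp:
            rec["bits"] = sorted(gen.GetFingerprint(mol).GetOnBits())
        out.append(rec)
    with open(path_out, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
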