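"""Structure parsing + fingerprint bridge.

Reads a CSV of (id, smiles), canonicalizes each structure and computes the
requested binary fingerprints; emits one JSON document on --output. All
chemistry is delegated to RDKit; everything downstream of the bit sets lives
in R. Deterministic: same input + params always yields identical bits.
"""
import argparse
import csv
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, MACCSkeys, rdMolDescriptors
from rdkit.Chem.Pharm2D import Generate, Gobbi_Pharm2D
from rdkit.Chem.Pharm2D.SigFactory import SigFactory

RDLogger.DisableLog("rdApp.*")

DEFAULT_PARAMS = {
    "topological_path": {"max_path": 7, "n_bits": 2048},
    "morgan": {"radius": 2, "n_bits": 2048},
    "maccs_keys": {"n_bits": 167},
    "atom_pair": {"n_bits": 2048},
    "pharmacophore": {"n_points": 2, "n_bits": 2048},
}

_PHARM_FACTORY = {}


def pharm_factory(n_points):
    if n_points not in _PHARM_FACTORY:
        fac = SigFactory(Gobbi_Pharm2D.factory.featFactory,
                         minPointCount=n_points, maxPointCount=n_points)
        fac.SetBins([(0, 2), (2, 5), (5, 8)])
        fac.Init()
        _PHARM_FACTORY[n_points] = fac
    return _PHARM_FACTORY[n_points]


def fold(bits, n_bits):
    return sorted({b % n_bits for b in bits})


def compute_fp(mol, kind, p):
    if kind == "topological_path":
        bv = Chem.RDKFingerprint(mol, maxPath=int(p["max_path"]),
                                 fpSize=int(p["n_bits"]))
        return list(bv.GetOnBits()), int(p["n_bits"])
    if kind == "morgan":
        bv = AllChem.GetMorganFingerprintAsBitVect(
            mol, int(p["radius"]), nBits=int(p["n_bits"]))
        return list(bv.GetOnBits()), int(p["n_bits"])
    if kind == "maccs_keys":
        bv = MACCSkeys.GenMACCSKeys(mol)  # 167 bits, bit 0 unused
        return list(bv.GetOnBits()), 167
    if kind == "atom_pair":
        bv = rdMolDescriptors.GetHashedAtomPairFingerprintAsBitVect(
            mol, nBits=int(p["n_bits"]))
        return list(bv.GetOnBits()), int(p["n_bits"])
    if kind == "pharmacophore":
        sig = Generate.Gen2DFingerprint(mol, pharm_factory(int(p["n_points"])))
        return fold(sig.GetOnBits(), int(p["n_bits"])), int(p["n_bits"])
    raise ValueError(f"unknown fingerprint kind: {kind}")


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--input", required=True, help="CSV with id,smiles columns")
    ap.add_argument("--kinds", default="", help="comma-separated kinds ('' = parse only)")
    ap.add_argument("--params", default="{}", help="JSON per-kind parameter overrides")
    ap.add_argument("--output", required=True)
    args = ap.parse_args()

    params = dict(DEFAULT_PARAMS)
    for k, v in json.loads(args.params).items():
        params[k] = {**params.get(k, {}), **v}
    kinds = [k for k in args.kinds.split(",") if k]

    out = []
    with open(args.input, newline="") as fh:
        for row in csv.DictReader(fh):
            rec = {"id": row["id"], "input_smiles": row["smiles"],
                   "valid": False, "canonical_smiles": None, "fps": {}}
            mol = Chem.MolFromSmiles(row["smiles"])
            if mol is None:
                rec["error"] = "unparseable SMILES"
            else:
                rec["valid"] = True
                rec["canonical_smiles"] = Chem.MolToSmiles(mol)
                for kind in kinds:
                    bits, n_bits = compute_fp(mol, kind, params[kind])
                    rec["fps"][kind] = {"length": n_bits,
                                        "bits": [int(b) for b in bits]}
            out.append(rec)

    with open(args.output, "w") as fh:
        json.dump({"molecules": out}, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main())
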