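"""Batch chemistry backend for the APNet R package.

Reads a JSON request {smiles: [...], graphs: bool, fingerprints: [...],
patterns: [...]} and writes a JSON response. All heavy RDKit work is done in
one process invocation so the R side can batch whole libraries.

Feature vocabularies (categorical indices, 0-based):
  atom:  atomic number (1..118), chirality tag (RDKit ChiralType 0..3)
  bond:  bond type {SINGLE:0, DOUBLE:1, TRIPLE:2, AROMATIC:3, other:0},
         bond direction {NONE:0, ENDUPRIGHT:1, ENDDOWNRIGHT:2, other:0}
Fingerprints are returned as 0-based on-bit index lists (sparse).
"""

import argparse
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors, MACCSkeys, rdMolDescriptors
from rdkit.Avalon import pyAvalonTools

RDLogger.DisableLog("rdApp.*")

BOND_TYPE = {
    Chem.BondType.SINGLE: 0,
    Chem.BondType.DOUBLE: 1,
    Chem.BondType.TRIPLE: 2,
    Chem.BondType.AROMATIC: 3,
}
BOND_DIR = {
    Chem.BondDir.NONE: 0,
    Chem.BondDir.ENDUPRIGHT: 1,
    Chem.BondDir.ENDDOWNRIGHT: 2,
}

# 2D physicochemical descriptor panel for the optional 'rdkDes' attribute.
RDKDES_FUNS = [
    Descriptors.MolWt, Descriptors.MolLogP, Descriptors.MolMR,
    Descriptors.TPSA, Descriptors.NumHAcceptors, Descriptors.NumHDonors,
    Descriptors.NumRotatableBonds, Descriptors.NumAromaticRings,
    Descriptors.NumAliphaticRings, Descriptors.NumSaturatedRings,
    Descriptors.FractionCSP3, Descriptors.HeavyAtomCount,
    Descriptors.RingCount, Descriptors.NHOHCount, Descriptors.NOCount,
    Descriptors.qed, Descriptors.BertzCT, Descriptors.BalabanJ,
    Descriptors.Chi0, Descriptors.Chi1,
]


def fingerprint_bits(mol, kind):
    if kind.startswith("ECFP") or kind.startswith("FCFP"):
        radius = int(kind[4:]) // 2
        fp = AllChem.GetMorganFingerprintAsBitVect(
            mol, radius, nBits=1024, useFeatures=kind.startswith("FCFP"))
    elif kind in ("RDK5", "RDK6", "RDK7"):
        fp = Chem.RDKFingerprint(mol, maxPath=int(kind[3]), fpSize=1024)
    elif kind == "HashAP":
        fp = rdMolDescriptors.GetHashedAtomPairFingerprintAsBitVect(
            mol, nBits=1024)
    elif kind == "HashTT":
        fp = rdMolDescriptors.GetHashedTopologicalTorsionFingerprintAsBitVect(
            mol, nBits=1024)
    elif kind == "MACCS":
        fp = MACCSkeys.GenMACCSKeys(mol)
    elif kind == "Avalon":
        fp = pyAvalonTools.GetAvalonFP(mol, nBits=1024)
    else:
        raise ValueError("unknown fingerprint kind: %s" % kind)
    return list(fp.GetOnBits())


def graph_of(mol):
    z, chir = [], []
    for atom in mol.GetAtoms():
        z.append(atom.GetAtomicNum())
        chir.append(int(atom.GetChiralTag()))
    src, dst, bt, bd = [], [], [], []
    for bond in mol.GetBonds():
        u = bond.GetBeginAtomIdx() + 1
        v = bond.GetEndAtomIdx() + 1
        t = BOND_TYPE.get(bond.GetBondType(), 0)
        d = BOND_DIR.get(bond.GetBondDir(), 0)
        src += [u, v]
        dst += [v, u]
        bt += [t, t]
        bd += [d, d]
    return {"z": z, "chir": chir, "src": src, "dst": dst, "bt": bt, "bd": bd}


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--infile", required=True)
    ap.add_argument("--outfile", required=True)
    args = ap.parse_args()

    with open(args.infile) as fh:
        req = json.load(fh)

    smiles = req["smiles"]
    want_graphs = bool(req.get("graphs", False))
    fp_kinds = req.get("fingerprints", []) or []
    patterns = req.get("patterns", []) or []

    mols, ok, canonical = [], [], []
    for smi in smiles:
        mol = Chem.MolFromSmiles(smi)
        mols.append(mol)
        ok.append(mol is not None)
        canonical.append(Chem.MolToSmiles(mol) if mol is not None else None)

    out = {"ok": ok, "canonical": canonical}

    if want_graphs:
        out["graphs"] = [graph_of(m) if m is not None else None for m in mols]

    if fp_kinds:
        fps = {}
        for kind in fp_kinds:
            if kind == "rdkDes":
                fps[kind] = [
                    [float(f(m)) for f in RDKDES_FUNS] if m is not None
                    else None for m in mols]
            else:
                fps[kind] = [
                    fingerprint_bits(m, kind) if m is not None else None
                    for m in mols]
        out["fingerprints"] = fps

    if patterns:
        qmols = []
        for p in patterns:
            q = Chem.MolFromSmarts(p)
            if q is None:
                sys.stderr.write("bad SMARTS pattern: %s\n" % p)
                sys.exit(2)
            qmols.append(q)
        out["matches"] = [
            [bool(m.HasSubstructMatch(q)) for q in qmols] if m is not None
            else None for m in mols]

    with open(args.outfile, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
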