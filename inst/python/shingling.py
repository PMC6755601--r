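"""Molecular shingling backend.

Reads one JSON request from stdin and writes one JSON response to stdout.
Requests:
  {"op": "shingling", "smiles": [...], "radius": 3, "rings": true,
   "min_radius": 1, "isomeric": false}
  {"op": "atom_env", "smiles": "...", "atom": 0, "radius": 1,
   "isomeric": false}
  {"op": "rings", "smiles": [...]}
  {"op": "canonical", "smiles": [...]}
  {"op": "ecfp_hashes", "smiles": [...], "radius": 2}

Per-molecule failures are reported in-band as {"error": "..."} entries so a
single bad record does not abort a batch. All substructure SMILES are
canonical and kekulized; stereochemistry is stripped unless isomeric is set.
"""

import json
import sys

from rdkit import Chem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def _parse(smiles, isomeric):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        raise ValueError("SMILES parse error: %r" % smiles)
    if mol.GetNumHeavyAtoms() < 1:
        raise ValueError("no heavy atoms: %r" % smiles)
    if not isomeric:
        Chem.RemoveStereochemistry(mol)
    try:
        Chem.Kekulize(mol, clearAromaticFlags=True)
    except Exception:
        raise ValueError("kekulization failed: %r" % smiles)
    return mol


def _atom_env_smiles(mol, idx, radius, isomeric):
    """Rooted canonical SMILES of all bonds within `radius` of atom `idx`;
    empty string when the environment holds no bonds."""
    env = Chem.FindAtomEnvironmentOfRadiusN(mol, radius, idx)
    if not env:
        return ""
    amap = {}
    sub = Chem.PathToSubmol(mol, env, atomMap=amap)
    if idx not in amap:
        return ""
    return Chem.MolToSmiles(
        sub, rootedAtAtom=amap[idx], canonical=True, isomericSmiles=isomeric
    )


def _ring_smiles(mol, isomeric):
    """Unrooted canonical SMILES, one per ring of the symmetrized SSSR."""
    out = []
    for ring in Chem.GetSymmSSSR(mol):
        ring = list(ring)
        bonds = []
        for i in range(len(ring)):
            for j in range(i + 1, len(ring)):
                bond = mol.GetBondBetweenAtoms(ring[i], ring[j])
                if bond is not None:
                    bonds.append(bond.GetIdx())
        smi = Chem.MolToSmiles(
            Chem.PathToSubmol(mol, bonds), isomericSmiles=isomeric
        )
        if smi:
            out.append(smi)
    return out


def _shingling(mol, radius, rings, min_radius, isomeric):
    shingles = set()
    if min_radius <= 0:
        for atom in mol.GetAtoms():
            smi = Chem.MolFragmentToSmiles(mol, atomsToUse=[atom.GetIdx()])
            if smi:
                shingles.add(smi)
    lo = max(1, min_radius)
    for atom in mol.GetAtoms():
        idx = atom.GetIdx()
        for r in range(lo, radius + 1):
            smi = _atom_env_smiles(mol, idx, r, isomeric)
            if smi:
                shingles.add(smi)
    if rings:
        shingles.update(_ring_smiles(mol, isomeric))
    return sorted(shingles)


def _mol_stats(mol):
    return {
        "heavy_atoms": mol.GetNumHeavyAtoms(),
        "n_rings": len(Chem.GetSymmSSSR(mol)),
    }


def main():
    req = json.load(sys.stdin)
    op = req["op"]
    isomeric = bool(req.get("isomeric", False))
    res = []

    if op == "shingling":
        radius = int(req.get("radius", 3))
        rings = bool(req.get("rings", True))
        min_radius = int(req.get("min_radius", 1))
        for smi in req["smiles"]:
            try:
                mol = _parse(smi, isomeric)
                entry = _mol_stats(mol)
                entry["shingles"] = _shingling(
                    mol, radius, rings, min_radius, isomeric
                )
                res.append(entry)
            except ValueError as exc:
                res.append({"error": str(exc)})
    elif op == "atom_env":
        try:
            mol = _parse(req["smiles"], isomeric)
            idx = int(req["atom"])
            if idx < 0 or idx >= mol.GetNumHeavyAtoms():
                raise ValueError(
                    "atom index %d out of range for %r" % (idx, req["smiles"])
                )
            res = {"smiles": _atom_env_smiles(mol, idx, int(req["radius"]), isomeric)}
        except ValueError as exc:
            res = {"error": str(exc)}
    elif op == "rings":
        for smi in req["smiles"]:
            try:
                mol = _parse(smi, isomeric)
                res.append({"rings": _ring_smiles(mol, isomeric)})
            except ValueError as exc:
                res.append({"error": str(exc)})
    elif op == "canonical":
        for smi in req["smiles"]:
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                res.append({"error": "SMILES parse error: %r" % smi})
            else:
                if not isomeric:
                    Chem.RemoveStereochemistry(mol)
                res.append({"smiles": Chem.MolToSmiles(mol)})
    elif op == "ecfp_hashes":
        # Unfolded circular-fingerprint identifiers (Morgan), reduced mod
        # 2^32; used as the input to the MHECFP control fingerprint.
        from rdkit.Chem import rdFingerprintGenerator

        radius = int(req.get("radius", 2))
        gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius)
        for smi in req["smiles"]:
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                res.append({"error": "SMILES parse error: %r" % smi})
            else:
                sfp = gen.GetSparseCountFingerprint(mol)
                hashes = sorted(set(h % (2 ** 32) for h in sfp.GetNonzeroElements()))
                res.append({"hashes": hashes})
    else:
        raise SystemExit("unknown op: %r" % op)

    json.dump(res, sys.stdout)


if __name__ == "__main__":
    main()
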