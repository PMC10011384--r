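"""Molecule preparation helper.

Reads a JSON request on stdin, emits a JSON response on stdout. All
cheminformatics perception (parsing, hydrogen addition, fixed-seed 3D
embedding, MMFF94 minimisation, hybridisation/ring perception, 2D layout)
happens here through RDKit; everything downstream of the perceived atom
records is computed by the R package.

Request schema:
{
  "molecules": [{"id": str, "smiles": str} | {"id": str, "molblock": str}],
  "seed": int,            # embedding seed (ETKDG randomSeed)
  "embed": bool,          # embed a 3D conformer (ignored for 3D molblocks
                          # when "preserve" is true)
  "minimise": bool,       # MMFF94-minimise the conformer
  "preserve": bool,       # keep molblock coordinates, only add hydrogens
  "layout2d": bool        # also return 2D depiction coordinates
}

Response: {"molecules": [{"ok": bool, "id": ..., "error": null|str, ...}]}
Per-molecule failures are reported, never fatal.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")

HYB_MAP = {
    Chem.HybridizationType.SP: "sp1",
    Chem.HybridizationType.SP2: "sp2",
    Chem.HybridizationType.SP3: "sp3",
}


def perceive(mol):
    """Per-atom feature records and bond list (0-based indices)."""
    atoms = []
    for atom in mol.GetAtoms():
        if atom.GetAtomicNum() == 1:
            hyb = "h"
        elif atom.GetIsAromatic():
            hyb = "sp2"
        else:
            hyb = HYB_MAP.get(atom.GetHybridization(), "other")
        nbrs = atom.GetNeighbors()
        n_h = sum(1 for n in nbrs if n.GetAtomicNum() == 1)
        atoms.append({
            "element": atom.GetSymbol(),
            "fc": atom.GetFormalCharge(),
            "hyb": hyb,
            "aromatic": bool(atom.GetIsAromatic()),
            "in_ring": bool(atom.IsInRing()),
            "n_H": n_h,
            "n_l": len(nbrs) - n_h,
            "valence": int(atom.GetTotalValence()),
        })
    bonds = []
    for bond in mol.GetBonds():
        order = 1.5 if bond.GetIsAromatic() else bond.GetBondTypeAsDouble()
        bonds.append([bond.GetBeginAtomIdx(), bond.GetEndAtomIdx(), order])
    return atoms, bonds


def process(entry, opts):
    mid = entry.get("id")
    out = {"ok": False, "id": mid, "error": None}
    try:
        if "smiles" in entry:
            mol = Chem.MolFromSmiles(entry["smiles"])
            if mol is None:
                out["error"] = "unparseable SMILES: %r" % entry["smiles"]
                return out
            has3d = False
        else:
            mol = Chem.MolFromMolBlock(entry["molblock"], removeHs=False)
            if mol is None:
                out["error"] = "unparseable molblock"
                return out
            has3d = mol.GetNumConformers() > 0
        mol = Chem.AddHs(mol, addCoords=has3d)

        if has3d and opts["preserve"]:
            pass  # deposited conformation kept as-is, hydrogens added above
        elif opts["embed"]:
            params = AllChem.ETKDGv3()
            params.randomSeed = int(opts["seed"])
            if AllChem.EmbedMolecule(mol, params) != 0:
                out["error"] = "3D embedding failed"
                return out
            if opts["minimise"]:
                if not AllChem.MMFFHasAllMoleculeParams(mol):
                    out["error"] = "mmff-parameter-gap"
                    return out
                props = AllChem.MMFFGetMoleculeProperties(mol)
                ff = AllChem.MMFFGetMoleculeForceField(mol, props)
                ff.Minimize(maxIts=5000, forceTol=1e-6, energyTol=1e-10)

        atoms, bonds = perceive(mol)
        out["atoms"] = atoms
        out["bonds"] = bonds
        out["smiles"] = Chem.MolToSmiles(Chem.RemoveHs(Chem.Mol(mol)))
        out["n_sssr"] = int(len(Chem.GetSSSR(mol)))
        out["total_charge"] = int(Chem.GetFormalCharge(mol))
        if mol.GetNumConformers() > 0:
            conf = mol.GetConformer()
            out["coords"] = [list(conf.GetAtomPosition(i))
                             for i in range(mol.GetNumAtoms())]
        if opts["layout2d"]:
            flat = Chem.Mol(mol)
            AllChem.Compute2DCoords(flat)
            conf = flat.GetConformer()
            out["coords2d"] = [list(conf.GetAtomPosition(i))[:2]
                               for i in range(flat.GetNumAtoms())]
        out["ok"] = True
    except Exception as exc:  # pragma: no cover - defensive
        out["error"] = "%s: %s" % (type(exc).__name__, exc)
    return out


def main():
    req = json.load(sys.stdin)
    opts = {
        "seed": req.get("seed", 1),
        "embed": req.get("embed", True),
        "minimise": req.get("minimise", True),
        "preserve": req.get("preserve", False),
        "layout2d": req.get("layout2d", False),
    }
    res = [process(entry, opts) for entry in req["molecules"]]
    json.dump({"molecules": res}, sys.stdout)


if __name__ == "__main__":
    main()
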