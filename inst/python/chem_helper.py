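"""Chemistry perception backend (RDKit).

Reads a JSON request on stdin, writes a JSON response on stdout. Two modes:

  perceive   -- parse/clean SMILES and return atom, bond, ring tables plus
                per-atom H-bond donor/acceptor SMARTS matches
  fragments  -- extract node substructures as canonical SMILES with "*"
                wildcard atoms at the attachment points

Atom indices in all tables are 0-based and refer to the RDKit atom order of
the molecule parsed from the *cleaned* canonical SMILES, which is stable:
re-parsing a SMILES string always yields atoms in SMILES order.
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdmolops

RDLogger.DisableLog("rdApp.*")

# O'Boyle neutralisation: atoms with a formal charge not balanced by an
# adjacent opposite charge get protonated/deprotonated to the neutral form.
_NEUTRALISE = Chem.MolFromSmarts(
    "[+1!h0!$([*]~[-1,-2,-3,-4]),-1!$([*]~[+1,+2,+3,+4])]"
)


def neutralise(mol):
    matches = mol.GetSubstructMatches(_NEUTRALISE)
    if not matches:
        return mol
    mol = Chem.RWMol(mol)
    for (idx,) in matches:
        atom = mol.GetAtomWithIdx(idx)
        chg = atom.GetFormalCharge()
        hcount = atom.GetTotalNumHs()
        atom.SetFormalCharge(0)
        atom.SetNumExplicitHs(hcount - chg)
        atom.UpdatePropertyCache()
    Chem.SanitizeMol(mol)
    return mol.GetMol()


def largest_fragment(mol):
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=True)
    if len(frags) == 1:
        return mol
    return max(frags, key=lambda f: f.GetNumHeavyAtoms())


def clean_smiles(smi):
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return None, "unparseable SMILES"
    try:
        mol = largest_fragment(mol)
        mol = neutralise(mol)
    except Exception as exc:  # pragma: no cover - rare sanitisation failures
        return None, "standardisation failed: %s" % exc
    return Chem.MolToSmiles(mol), None


def perceive_one(can_smi, hba, hbd):
    mol = Chem.MolFromSmiles(can_smi)
    ring_info = mol.GetRingInfo()
    hba_atoms = sorted({m[0] for m in mol.GetSubstructMatches(hba)})
    hbd_atoms = sorted({m[0] for m in mol.GetSubstructMatches(hbd)})
    atoms = []
    for a in mol.GetAtoms():
        atoms.append(
            {
                "idx": a.GetIdx(),
                "symbol": a.GetSymbol(),
                "atomic_num": a.GetAtomicNum(),
                "aromatic": a.GetIsAromatic(),
                "in_ring": a.IsInRing(),
                "charge": a.GetFormalCharge(),
                "degree": a.GetDegree(),
                "num_h": a.GetTotalNumHs(),
            }
        )
    bonds = []
    for b in mol.GetBonds():
        bonds.append(
            {
                "a": b.GetBeginAtomIdx(),
                "b": b.GetEndAtomIdx(),
                "order": b.GetBondTypeAsDouble(),
                "aromatic": b.GetIsAromatic(),
                "in_ring": b.IsInRing(),
            }
        )
    rings = []
    bond_rings = ring_info.BondRings()
    for atom_ring, bond_ring in zip(ring_info.AtomRings(), bond_rings):
        aromatic = all(mol.GetBondWithIdx(i).GetIsAromatic() for i in bond_ring)
        rings.append({"atoms": sorted(atom_ring), "aromatic": aromatic})
    return {
        "smiles": can_smi,
        "n_atoms": mol.GetNumAtoms(),
        "atoms": atoms,
        "bonds": bonds,
        "rings": rings,
        "hba_atoms": hba_atoms,
        "hbd_atoms": hbd_atoms,
    }


def mode_perceive(req):
    hba = Chem.MolFromSmarts(req["hba_smarts"])
    hbd = Chem.MolFromSmarts(req["hbd_smarts"])
    if hba is None:
        return {"error": "invalid HBA SMARTS: %s" % req["hba_smarts"]}
    if hbd is None:
        return {"error": "invalid HBD SMARTS: %s" % req["hbd_smarts"]}
    out = []
    for smi in req["smiles"]:
        can, err = clean_smiles(smi)
        if can is None:
            out.append({"error": err, "input": smi})
            continue
        rec = perceive_one(can, hba, hbd)
        rec["input"] = smi
        out.append(rec)
    return {"molecules": out}


def extract_fragment(mol, atom_ids):
    """Canonical SMILES of the substructure over atom_ids with one "*" per
    bond leaving the atom set."""
    keep = set(atom_ids)
    em = Chem.RWMol(mol)
    dummies = []
    for bond in mol.GetBonds():
        a, b = bond.GetBeginAtomIdx(), bond.GetEndAtomIdx()
        inside = None
        if a in keep and b not in keep:
            inside, outside = a, b
        elif b in keep and a not in keep:
            inside, outside = b, a
        if inside is None:
            continue
        d = em.AddAtom(Chem.Atom(0))
        btype = bond.GetBondType()
        if btype == Chem.BondType.AROMATIC:
            btype = Chem.BondType.SINGLE
        em.AddBond(inside, d, btype)
        dummies.append(d)
    keep_all = keep | set(dummies)
    for idx in sorted(range(mol.GetNumAtoms()), reverse=True):
        if idx not in keep_all:
            em.RemoveAtom(idx)
    frag = em.GetMol()
    try:
        Chem.SanitizeMol(frag)
    except Exception:
        # partial ring extraction can break kekulisation; the string is still
        # a deterministic identity key
        try:
            Chem.SanitizeMol(
                frag,
                Chem.SanitizeFlags.SANITIZE_ALL
                ^ Chem.SanitizeFlags.SANITIZE_KEKULIZE,
            )
        except Exception:
            pass
    return Chem.MolToSmiles(frag)


def mode_fragments(req):
    out = []
    for entry in req["molecules"]:
        mol = Chem.MolFromSmiles(entry["smiles"])
        frags = [extract_fragment(mol, r["atoms"]) for r in entry["requests"]]
        out.append({"fragments": frags})
    return {"molecules": out}


def mode_randomize(req):
    """Equivalent SMILES with permuted atom numbering (for determinism tests)."""
    import random

    rnd = random.Random(int(req.get("seed", 0)))
    out = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        variants = []
        for _ in range(int(req.get("n", 3))):
            perm = list(range(mol.GetNumAtoms()))
            rnd.shuffle(perm)
            variants.append(
                Chem.MolToSmiles(Chem.RenumberAtoms(mol, perm), canonical=False)
            )
        out.append(variants)
    return {"variants": out}


def main():
    mode = sys.argv[1]
    req = json.load(sys.stdin)
    if mode == "perceive":
        res = mode_perceive(req)
    elif mode == "fragments":
        res = mode_fragments(req)
    elif mode == "randomize":
        res = mode_randomize(req)
    else:
        raise SystemExit("unknown mode: %s" % mode)
    json.dump(res, sys.stdout)


if __name__ == "__main__":
    main()
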