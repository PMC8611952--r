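"""Independent cheminformatics oracle used by the test suite.

Modes (first argv): a JSON file path is passed as second argv and a JSON
document is printed to stdout.

  murcko     {"smiles": [...]}            -> list of Murcko scaffold SMILES
  substruct  {"sub": [...], "mol": [...]} -> list of bools; graph-level
              (element + connectivity, bond-order/aromaticity agnostic)
              substructure containment of sub[i] in mol[i]
  rings      {"smiles": [...]}            -> SSSR ring counts
"""
import json
import sys

from rdkit import Chem
from rdkit.Chem.Scaffolds import MurckoScaffold


def generic_bond_smarts(mol):
    smarts = Chem.MolToSmarts(mol)
    out = []
    depth = 0
    for ch in smarts:
        if ch == "[":
            depth += 1
        elif ch == "]":
            depth -= 1
        if depth == 0 and ch in "-=#:/\\":
            out.append("~")
        else:
            out.append(ch)
    return "".join(out)


def main():
    mode = sys.argv[1]
    with open(sys.argv[2]) as fh:
        data = json.load(fh)
    if mode == "murcko":
        res = []
        for s in data["smiles"]:
            m = Chem.MolFromSmiles(s)
            res.append(Chem.MolToSmiles(MurckoScaffold.GetScaffoldForMol(m)))
    elif mode == "substruct":
        res = []
        for s, m in zip(data["sub"], data["mol"]):
            query = Chem.MolFromSmarts(generic_bond_smarts(Chem.MolFromSmiles(s)))
            target = Chem.MolFromSmiles(m)
            res.append(bool(target.HasSubstructMatch(query)))
    elif mode == "rings":
        res = []
        for s in data["smiles"]:
            r = Chem.GetSSSR(Chem.MolFromSmiles(s))
            res.append(r if isinstance(r, int) else len(r))
    else:
        raise SystemExit("unknown mode " + mode)
    print(json.dumps(res))


if __name__ == "__main__":
    main()
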