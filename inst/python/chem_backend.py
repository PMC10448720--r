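"""Structure backend: SMILES -> canonical form, Morgan fingerprint
on-bits, and Lipinski-type descriptors, emitted as JSON.

Usage: python chem_backend.py <input.tsv> <radius> <n_bits>
  input.tsv: chem_id <TAB> smiles, no header
Output (stdout): JSON array, one object per input row.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Crippen, Descriptors, Lipinski, rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")


def main():
    path, radius, n_bits = sys.argv[1], int(sys.argv[2]), int(sys.argv[3])
    gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius,
                                                    fpSize=n_bits)
    out = []
    with open(path) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            chem_id, smiles = line.split("\t", 1)
            mol = Chem.MolFromSmiles(smiles)
            if mol is None:
                out.append({"chem_id": chem_id, "ok": False,
                            "error": "unparseable SMILES"})
                continue
            fp = gen.GetFingerprint(mol)
            out.append({
                "chem_id": chem_id,
                "ok": True,
                "canonical": Chem.MolToSmiles(mol),
                "bits": sorted(int(b) + 1 for b in fp.GetOnBits()),
                "mw": Descriptors.MolWt(mol),
                "logp": Crippen.MolLogP(mol),
                "hbd": Lipinski.NumHDonors(mol),
                "hba": Lipinski.NumHAcceptors(mol),
                "rotatable_bonds": Lipinski.NumRotatableBonds(mol),
                "rings": Descriptors.RingCount(mol),
                "heavy_atoms": mol.GetNumHeavyAtoms(),
            })
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
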