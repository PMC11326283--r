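"""Batch SMILES utilities backing the R chem module.

Usage: python chem_tool.py MODE INFILE OUTFILE
  MODE = canon    : one SMILES per input line -> canonical SMILES, or an
                    empty line where parsing failed
  MODE = sequence : one one-letter peptide sequence per line -> canonical
                    SMILES of the linear peptide (independent oracle for
                    the R-side peptide assembler)
  MODE = descriptors : one SMILES per line -> four tab-separated numbers:
                    residue count (N-CA-C=O backbone motifs), N-methylated
                    backbone amide count, PEG attachment flag, macrocycle
                    flag
"""
import sys

from rdkit import Chem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")

RESIDUE_PAT = Chem.MolFromSmarts("[NX3][CX4][CX3](=O)")
NMETHYL_PAT = Chem.MolFromSmarts("[CH3][NX3]([CX4])[CX3]=O")
PEG_PAT = Chem.MolFromSmarts("[NX3][CH2][CH2][OX2]")


def canon(line):
    mol = Chem.MolFromSmiles(line)
    return Chem.MolToSmiles(mol) if mol is not None else ""


def sequence(line):
    mol = Chem.MolFromSequence(line)
    return Chem.MolToSmiles(mol) if mol is not None else ""


def descriptors(line):
    mol = Chem.MolFromSmiles(line)
    if mol is None:
        return ""
    n_res = len(mol.GetSubstructMatches(RESIDUE_PAT))
    n_me = len(mol.GetSubstructMatches(NMETHYL_PAT))
    peg = 1 if mol.HasSubstructMatch(PEG_PAT) else 0
    cyclic = 0
    for ring in mol.GetRingInfo().AtomRings():
        if len(ring) >= 7:
            cyclic = 1
            break
        if len(ring) == 6:
            n_in_ring = sum(1 for a in ring
                            if mol.GetAtomWithIdx(a).GetSymbol() == "N"
                            and not mol.GetAtomWithIdx(a).GetIsAromatic())
            if n_in_ring >= 2:  # diketopiperazine-sized backbone macrocycle
                cyclic = 1
                break
    return "%d\t%d\t%d\t%d" % (n_res, n_me, peg, cyclic)


def main():
    mode, infile, outfile = sys.argv[1:4]
    fn = {"canon": canon, "sequence": sequence, "descriptors": descriptors}[mode]
    with open(infile) as fin, open(outfile, "w") as fout:
        for line in fin:
            line = line.rstrip("\n")
            fout.write((fn(line) if line else "") + "\n")


if __name__ == "__main__":
    main()
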