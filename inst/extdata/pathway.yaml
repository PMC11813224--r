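# Two-branch processive proteolysis of APP C99 by gamma-secretase.
# Each step releases one coproduct; trimming coproducts carry their
# literal peptide sequence.  AICDs are named by C99 residue span.
branches:
  Ab40:
    - {precursor: C99,  product: Ab49, coproduct: AICD50-99}
    - {precursor: Ab49, product: Ab46, coproduct: ITL, sequence: ITL}
    - {precursor: Ab46, product: Ab43, coproduct: VIV, sequence: VIV}
    - {precursor: Ab43, product: Ab40, coproduct: IAT, sequence: IAT}
  Ab42:
    - {precursor: C99,  product: Ab48, coproduct: AICD49-99}
    - {precursor: Ab48, product: Ab45, coproduct: VIT, sequence: VIT}
    - {precursor: Ab45, product: Ab42, coproduct: TVI, sequence: TVI}
    - {precursor: Ab42, product: Ab38, coproduct: VVIA, sequence: VVIA}
peptides:
  ITL: ITL
  VIV: VIV
  IAT: IAT
  VIT: VIT
  TVI: TVI
  VVIA: VVIA
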