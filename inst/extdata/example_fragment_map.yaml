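# Fragment map for a thiolate ligand of residue name LIG:
# inner = hydrophobic alkyl block, central = amide/urea moiety,
# outer = oligo-ethylene-glycol terminus.  Atom-name based; an
# equivalent positional form uses inner_pos / central_pos / outer_pos.
species:
  - resname: LIG
    inner: [C1, C2, C3, C4]
    central: [N1, C5, O1]
    outer: [C6, O2, C7, O3, C8]
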