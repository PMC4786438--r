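# SYNTHETIC 27-position scan world built around the printed CLS segment.
# The published scan covered 27 positions (540 = 27 x 20 variants) but only
# 23 residues of the construct are printed; two invented juxtamembrane
# residues are added on each side (cytoplasmic K,R obeying the
# positive-inside rule; periplasmic S,Q polar). Positions 295-317 are the
# printed CLS residues; 293, 294, 318, 319 are synthetic.
name: cls27
dna: AAACGTCCGCTGTTCATCCCGGTTGCAGTTATGGTTACCGCTTTTAGTGGATTGGCGTTTATCATCTGGCTGGCTTCTCAG
protein: KRPLFIPVAVMVTAFSGLAFIIWLASQ
numbering_offset: 292
span_start: 293
span_end: 319
upstream_flank: CTTGGGGAATCGACTCGAG
downstream_flank: CCAAGCCAATCCAGCTTTAAAC
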