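# ErbB2 (HER2) transmembrane homodimer segment, as printed.
# Numbering approximate (first printed residue set to 652).
name: erbb2
dna: CTGACGTCTATCATCTCTGCGGTGGTTGGCATTCTGCTGGTCGTGGTCTTGGGCGTGGTCTTTGGCATCCTGATC
protein: LTSIISAVVGILLVVVLGVVFGILI
numbering_offset: 651
span_start: 652
span_end: 676
upstream_flank: CTTGGGGAATCGACTCGAG
downstream_flank: CCAAGCCAATCCAGCTTTAAAC
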