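# Glycophorin A transmembrane homodimer segment, as printed.
# Numbered 75-90 so that the GxxxG motif is Gly79/Gly83 and Ala82 sits at
# the membrane centre.
name: gpa
dna: CTCATTATTTTTGGGGTGATGGCTGGTGTTATTGGAACGATCCTGATC
protein: LIIFGVMAGVIGTILI
numbering_offset: 74
span_start: 75
span_end: 90
upstream_flank: CTTGGGGAATCGACTCGAG
downstream_flank: CCAAGCCAATCCAGCTTTAAAC
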