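# C-terminal membrane-spanning segment of human L-Selectin (CLS), as printed.
# Numbering anchored so that the Results mutant names match the sequence
# (Val302, Met303, Val304, Leu310, Ala311): first printed residue = 295.
# Flanks are the printed inner PCR-primer tails adjoining the insert; the
# full vector context is not published, so these are synthetic anchors.
name: cls
dna: CCGCTGTTCATCCCGGTTGCAGTTATGGTTACCGCTTTTAGTGGATTGGCGTTTATCATCTGGCTGGCT
protein: PLFIPVAVMVTAFSGLAFIIWLA
numbering_offset: 294
span_start: 295
span_end: 317
upstream_flank: CTTGGGGAATCGACTCGAG
downstream_flank: CCAAGCCAATCCAGCTTTAAAC
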