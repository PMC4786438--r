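# Small fixtures built in code; no data files.

# four-codon toy construct for hand-crafted read tests
mini_construct <- function() {
  construct(name = "mini",
            dna = "ATGGTTACCGCT",          # M V T A
            span_start = 1, span_end = 4,
            numbering_offset = 0,
            upstream_flank = "ACGTACGTAC",
            downstream_flank = "TTGCATGCAA")
}

mini_amplicon <- function(x = mini_construct()) {
  paste0(x$upstream_flank, x$dna, x$downstream_flank)
}

# perfect read pair covering an amplicon with read length rl
mini_pair <- function(amp, rl = 20L) {
  list(r1 = substr(amp, 1, rl),
       r2 = degenerate_revcomp(substring(amp, nchar(amp) - rl + 1)))
}

# substitute one base of a sequence (1-based position)
sub_base <- function(seq, at, base) {
  substr(seq, at, at) <- base
  seq
}

# insertion world used across tests: synthetic 27-position CLS scan
cls27_world <- function(seed, depth = 4e6, sigma = 0.5) {
  x <- example_construct("cls27")
  truth <- truth_landscape(x, midplane = 311)
  cfg <- sim_config(depth = depth, clonal_bias_sigma = sigma,
                    rng_seed = seed)
  ref <- simulate_reference_counts(x, cfg)
  sel <- simulate_selected_counts(ref, truth, cfg)
  mask <- apply_reference_filter(ref, 100)
  land <- to_ddg(selection_coefficients(sel, ref, mask))
  list(construct = x, truth = truth, config = cfg,
       reference = ref, selected = sel, mask = mask, landscape = land)
}
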