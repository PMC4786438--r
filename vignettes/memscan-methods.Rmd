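---
title: "memscan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{memscan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memscan)
```

## The assay model

`memscan` analyses deep mutational scans of single-pass transmembrane
segments in which survival on a selective plate reports on a biophysical
property of the segment: ampicillin survival reports membrane insertion of
a β-lactamase fusion, and chloramphenicol survival (in a ToxR/CAT context)
reports homodimer formation. Every single-amino-acid variant of the
scanned span competes in one pooled culture, so deep sequencing of the
selected and unselected pools measures each variant's relative fitness
under identical conditions.

The analysis treats partitioning between selected and reference pools as
thermodynamically controlled. For variant $j$ at position $i$:

$$p_{i,j} = \frac{\mathrm{count}_{i,j}}{\mathrm{count}_{wt}}, \qquad
  s_{i,j} = \frac{p_{i,j}^{sel}}{p_{i,j}^{ref}}, \qquad
  \Delta\Delta G^{app}_{i,j} = -RT \ln s_{i,j}$$

with $R = 1.9872\times10^{-3}$ kcal/(mol·K) and $T = 310$ K
($RT = 0.616032$ kcal/mol). Normalizing by the wild-type count inside each
pool removes depth differences; taking the ratio across pools removes
clonal-representation bias, which is why a sequenced *reference* pool is
required. Both constants are overridable but default to the assay
conditions.

**Censoring.** A variant with zero selected reads has $s = 0$ and an
infinite apparent penalty. Such variants are flagged `censored` and
assigned the value obtained by substituting a pseudocount (default 1 read)
— a *lower bound* on the true penalty. The pseudocount is configurable;
any choice is a regularization, and downstream consumers should treat
censored entries as bounds, not measurements.

**Reference filter.** Variants with fewer than 100 reference reads
(strictly `< 100`) are eliminated everywhere (the landscape's gray tiles),
because their ratio estimates are statistically unreliable. The filter is
monotone in its threshold.

## Insertion profiles over membrane depth

Per-amino-acid insertion profiles are computed from the landscape
re-referenced to alanine (`relative_to_ala()`), smoothed positionally with
a centred 5-residue running average that skips masked cells and shrinks
symmetrically at the span ends, and fitted with 4th-order polynomials in
membrane depth $Z = (\mathrm{position} - \mathrm{midplane}) \times 1.5$ Å
(ideal helical rise; cytoplasm at negative $Z$, fixed N-cytoplasmic
topology).

Design choices worth knowing:

* **Mid-plane estimation** aligns the smoothed profiles of Leu, Ile, Met
  and Phe and takes the position of their mean trough. At least two of the
  four profiles must be usable. The estimator is exactly equivariant under
  position shifts.
* **Fit window.** Polynomials are fitted only over $|Z| \le 15$ Å
  (`z_fit_window`). Outside the bilayer the physical profiles plateau, and
  a quartic forced through plateau points misfits the membrane interior —
  an effect we measured at ~0.4 kcal/mol for glycine before restricting
  the window. The fitted `zrange` is stored and extrapolation beyond it is
  flagged.
* **Excluded positions.** Helix-distorting outlier positions (the scanned
  CLS pair 307/308 by default, when present) are dropped from fits, as
  smoothing cannot repair systematic distortion. The exclusion list is a
  configuration item.
* **Smoothing bias.** The running average flattens curved profiles, so
  fitted core depths are systematically shallower than raw cell values by
  10–20%. This is inherent to the smoothing choice (which the assay's
  original analysis shares) and propagates into everything computed from
  profiles (mid-plane solvation slopes, dimer corrections).

Amino-acid preferences are Boltzmann weights of the Ala-relative energies,
$p_{i,j} \propto e^{-E_{i,j}/RT}$, normalized over the 20 amino acids per
position; rows sum to 1 and per-position constant shifts cancel exactly.

## The synthetic world

Because the original raw reads are not deposited, every stage is validated
against a synthetic-data module that is itself first-class, tested code.
Its defaults are a *stated world* fixed from the printed observations, not
tunable knobs:

* Mid-plane (Z = 0) energies relative to Ala, kcal/mol: Leu/Ile/Phe −2,
  Met −1.7, Val −0.5, Trp −1, Tyr −0.5, Gly/Pro +2, Ser/Thr +0.3,
  Cys +0.2, Asn/Gln/His +3.5, Asp/Glu +4.5, Lys +4, Arg +1.5.
* Positive-inside asymmetry: Arg/Lys 2 kcal/mol and His 1 kcal/mol more
  favourable at the cytoplasmic than the periplasmic membrane edge.
* Shapes (all exact quartics in $Z$, clamped to their edge value outside
  $|Z| = 15$ Å): hydrophobics get a curved trough
  $c\,(1-(Z/15)^2)^2$ — transfer energy tracks buried apolar area, which
  decays toward the interface — while polar/charged penalties saturate
  across the core, $c\,(1-(Z/15)^4)$.
* Sequencing: multinomial sampling at 4×10⁶ read pairs per population
  (the experimental scale), log-normal clonal weights with σ = 0.5 (a
  few-fold spread typical of pooled saturation libraries), single
  Boltzmann reweighting for selection (no growth dynamics), per-base
  substitution errors at 10⁻³ on 150-bp paired-end reads, and one
  mandatory seed from which all streams derive.
* The default scanned construct is `cls27`, the printed 23-residue
  C-terminal L-Selectin segment extended by four *synthetic* juxtamembrane
  residues so the scan has the published 27 positions (540 variants); the
  extension is labelled synthetic in its config file.

What a green test does establish: the estimator chain inverts the
selection model exactly on expected frequencies; recovery at experimental
depth is accurate to ~0.02 kcal/mol for well-covered variants; mid-plane
localization is within one residue; censoring flags exactly the zero-count
variants. What it does not establish: agreement with the real library's
clonal-representation tail (the synthetic world has no dropout tail, so
all 540 variants survive the 100-count filter, versus 472 in the real
data), PCR chimeras, indels, or quality-dependent errors (substitutions
only, uniform quality).

One recovery property sits at a knife edge: at 4×10⁶ reads the RMSE
between recovered and true ΔΔG over *uncensored* variants averages
≈ 0.154 kcal/mol against a 0.15 criterion. The excess is entirely due to
variants whose true penalty is 5–6.5 kcal/mol yet which draw one to three
selected reads — above zero, hence formally uncensored, but at the
detection limit where a single count swings the log-ratio by up to
1.5 kcal/mol. We report this honestly rather than redefining censoring or
softening the world's energy scale.

## Atomic-solvation parameter

The apparent atomic-solvation parameter is the OLS slope of apparent
insertion ΔΔG against the computed change in solvent-accessible surface
area (ΔSASA) for aliphatic↔aliphatic substitutions in the membrane core
(−9 Å < Z < 13 Å), with additional points from the dimer-neutral central
alanine of the Glycophorin A segment when its scan is available. Burial of
apolar area stabilizes insertion, so the slope is negative; its magnitude
is reported in cal/mol/Å². The quoted uncertainty is the OLS slope
standard error.

Structures are ideal α-helices built from internal coordinates
(φ = −57°, ψ = −47°, ω = 180°, standard bond geometry; heavy atoms only)
with side chains in fixed default rotamers (χ₁ = −65°, later χ staggered,
planar rings). This replaces the combinatorial side-chain repacking of the
original analysis; we document it as an approximation expected to perturb
individual ΔSASA values by a few percent. SASA is Shrake–Rupley with a
deterministic Fibonacci sphere (960 points; totals change < 1% when
doubled), probe 1.4 Å, and radii C 1.70 / N 1.55 / O 1.52 / S 1.80 Å.

## Self-association landscapes

For homodimer scans the ampicillin-selected pool is the *reference* and
the ampicillin-plus-chloramphenicol pool the *selected* one. The measured
effect of a mutation contains its insertion effect twice (both protomers
carry it), so the dimerization component is

$$\Delta\Delta G_{dim} = \Delta\Delta G_{meas} - 2\,[P_j(Z) - P_i(Z)]$$

evaluated from the insertion-profile polynomials of the monomeric scan
(the Ala reference cancels in the difference). When the dimer construct
has no insertion selection of its own, its mid-plane defaults to the
geometric centre of the scanned span. Eq-exactness
($\Delta\Delta G_{meas} = \Delta\Delta G_{dim} + 2\Delta\Delta G_{ins}$)
holds identically on every emitted table.

Positions are labelled `likely_mediating_binding` when ≥ 4 substitutions
disrupt binding by ≥ 2 kcal/mol, `unlikely_mediating_binding` when ≥ 4
substitutions improve or do not change binding, and `indeterminate`
otherwise. "Did not change" is operationalized as ≤ +0.2 kcal/mol (the
source gives no tolerance); censored cells never count as neutral; a
position meeting both rules is conservatively `indeterminate`.

Candidate C2 homodimer models (PDB) are accepted when at least two likely
positions have any heavy atom within 5 Å of the partner chain and no
unlikely position comes within 4 Å. The shells are measured over heavy
atoms (the choice of atom set is unstated in the source; hydrogens are
ignored), and decisions are invariant under rigid-body motion of the whole
model.

## Numerical and degenerate-input conventions

* Wild-type cells are exactly 0 in every landscape by construction, never
  by rounding.
* A zero wild-type count is a hard error (no landscape derivable).
* Positions where alanine itself is masked are dropped from Ala-relative
  profiles with a warning.
* Fewer than 6 usable points for an amino acid leaves it unfit (flagged),
  and Eq-5 corrections involving it are `NA`.
* Paired-end merging requires exact agreement across the mate overlap;
  disagreement rejects the pair. On short amplicons the mates overlap
  fully, so sequencing errors mostly reject pairs rather than corrupt
  counts — a conservative choice that depletes all variants by a common
  factor and leaves wild-type-normalized frequencies unbiased.
* All randomness flows from one mandatory seed; documented stream offsets
  (+0 reference counts, +1 selected counts, +2/+3 FASTQ emission) make
  every artifact reproducible bit for bit.

## Known limitations

* Censored (zero-read) penalties are lower bounds; their pseudocount
  values depend on depth and should not be compared across experiments at
  different depths.
* Fixed-rotamer ΔSASA underestimates the repacking response of large side
  chains; solvation slopes inherit this plus the smoothing bias above, so
  their magnitudes are systematically smaller than values computed from
  raw mid-plane energies with repacked models.
* The simulator does not model PCR bias, chimeras, indels, or
  quality-score structure.
* The structural filter assumes exactly two identical chains and
  paper-numbered residues; it validates sequence identity via Cα
  residue names only.
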