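---
title: "Methods: exome filtering, segregation and CSPα physicochemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exome filtering, segregation and CSPα physicochemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anclxome)
```

## The problem this package addresses

Autosomal dominant adult neuronal ceroid lipofuscinosis (ANCL, Parry
disease) is a rare fatal neurodegenerative disorder caused by mutations in
*DNAJC5*, the gene encoding the 198-residue synaptic co-chaperone CSPα. In
families too small for linkage analysis, the causal variant can be found by
sequencing the exomes of a handful of relatives and filtering the tens of
thousands of resulting coding variants down to the one allele compatible
with a fully penetrant dominant model. `anclxome` implements that filtering
cascade with explicit attrition accounting, the pedigree-aware
perfect-segregation and population-control screens that follow it, a
synthetic cohort simulator that makes the whole pipeline testable with
known truth, and the in-silico physicochemistry used to characterize the
effect of CSPα mutations (p.L115R, p.L116del) on membrane binding.

## The filtering cascade

Each sequenced exome passes, in order:

1. **Quality** — keep calls with read depth ≥ 5 and call quality ≥ 30
   ("standard parameters"). Calls with missing metrics are kept, with a
   warning: a filter cannot assess what was not measured.
2. **Functional class** — keep missense, nonsense, splice-site and coding
   indels; synonymous, intronic and intergenic calls are removed.
3. **Known common variants** — remove calls present in the population
   database at a frequency *strictly greater* than 5% (heterozygous) or
   30% (homozygous). Equality keeps; database-absent calls always survive.
4. **Affected intersection** — keep variant keys present in *every*
   affected exome. Identity is (chrom, pos, ref, alt); zygosity is ignored
   for matching, because a truly shared allele can be called with
   different zygosity in different samples.
5. **Control/panel subtraction** — remove any key carried by an unaffected
   control or by unrelated panel exomes. Subtractions commute.

`attrition_table()` reports per-stage counts and percent-remaining against
a fixed denominator, with the mixed printed precision used in published
attrition tables: two decimals below 1%, one decimal otherwise, and a bare
`100` at the top. One published cell is not reproducible under any standard
rounding: 19 surviving variants of 38,142 is 0.0498%, which rounds to 0.05,
not the printed 0.04. The formatter reproduces the well-determined cells
(100, 24.1, 1.8, 0.25, 0.06) and this discrepancy is documented here rather
than special-cased.

`validation_fdr()` is the plain failure fraction of genotype-validated
candidates (1 of 22 → 0.045).

## Segregation and control screening

`segregates()` tests a fully penetrant dominant model: a variant segregates
perfectly iff every typed affected member carries ≥ 1 alternate allele and
no typed unaffected member carries any. The result is deliberately
three-valued — `"no"` on any contradiction, `"unknown"` when a typed
genotype is missing and nothing contradicts, `"yes"` otherwise — so that
missing data is auditable instead of silently dropped. Elderly unaffected
members are taken at face value; no age-dependent penetrance model is
fitted.

`control_screen()` reports both the carrier frequency (carriers /
individuals) and the allele frequency ((het + 2·hom) / 2·individuals);
with 16 heterozygous carriers among 1,600 controls these are 0.01 and
0.005. Published "MAF" figures for such screens sometimes mix the two
conventions, which is why both are always reported.

`shortlist()` keeps candidates that segregate perfectly and treats *any*
carrier among population controls as exclusionary: under full penetrance a
causal dominant allele cannot be segregating in healthy controls.
Unscreened candidates are retained. Survivors are ranked by damaging
prediction, then GERP (descending, missing last), with a deterministic
(chrom, pos) tie-break.

## The synthetic cohort simulator

`simulate_cohort()` generates pedigree-structured exomes with known truth.
Its defaults are the study conditions of the motivating design and are not
tuning knobs:

* **Pedigree** (`ancl_study_pedigree()`): two affected first cousins are
  the sequenced cases (expected rare-variant sharing 2 × kinship = 1/8)
  and the unaffected elderly sibling of one of them is the sequenced
  control (sharing 1/2 with that case). The extended family supplies three
  affected and three unaffected members for segregation genotyping.
* **674 novel nonsynonymous variants per founder**, giving each sequenced
  sample an expected 674 under gene-dropping; a further 2.47 silent novel
  variants per nonsynonymous one reproduce the observed ratio of all novel
  calls to functional ones.
* **~38,179 total coding substitutions per sample**: a database-common
  pool sized analytically from the frequency spectrum (95% common,
  frequencies uniform on [0.05, 0.95]; 5% rare, uniform on
  [10⁻⁴, 5·10⁻³]) with founder genotypes drawn from Hardy–Weinberg.
* **Gene-dropping**: every non-founder receives each parental allele with
  probability 1/2, vectorized over variants. No linkage map is used —
  variants are exchangeable points, because all the arithmetic this
  supports involves genome-average sharing fractions only.
* **Flow-cell artifacts** (`artifact_rate = 0.02`): systematic false calls
  injected *identically into every co-sequenced sample* and into nobody's
  germline truth. The rate was fixed once from the excess of observed over
  expected shared calls (≈ 96 observed vs ≈ 674/8 ≈ 84 expected, an excess
  of ≈ 12, i.e. ≈ 0.02 × 674). Artifacts inflate the affected
  intersection and are then removed by control subtraction — and, because
  germline truth lacks them, by validation genotyping.
* **The causal variant**: a novel heterozygous missense allele implanted
  in every affected member and absent from everyone else, with
  high-confidence depth/quality, and a true population frequency of zero.
  Background novel variants carry small nonzero population frequencies
  (uniform on [0, 0.002]), which is what gives the control screen its
  discriminating power.

What the simulator does **not** emulate: linkage and recombination,
realistic site-frequency spectra, sequencing-read-level error processes,
population stratification, or annotation errors. Passing tests therefore
demonstrate the correctness of the filtering logic and its statistical
behaviour under Mendelian transmission — not robustness to every artifact
of real exome data.

`attrition_experiment()` repeats simulate-plus-cascade and summarizes
per-stage counts and causal retention. Note one modelling consequence: the
simulated "after filtering" stage retains, besides the implanted novel
variants, mid-frequency homozygous calls (the 30% homozygous threshold is
deliberately permissive) and rare database variants, so its count sits
somewhat above the novel-variant load. The simulator reports its own
model-based expectation for the post-control count (≈ 674 × 1/8 plus
residuals) rather than targeting any particular published value, whose
derivation is not uniquely determined.

## CSPα physicochemistry

The bundled wild-type sequence is human CSPα (UniProt Q9H3Z4, 198 aa) with
domains annotated: J-domain 15–83, linker 84–112, cysteine-string domain
(CSD) 113–136, and the experimentally defined membrane segment A108–K139.
Edits are expressed in HGVS-like protein notation: `L115R`, `L116del`,
`C113-119S` (all cysteines in 113–119 → serine; in this sequence those are
C113, C118 and C119). Reference residues are checked before editing, and
in-frame deletions shift downstream numbering.

**Codon arithmetic.** `codon_of_cds_position()` maps a 1-based coding
nucleotide to its codon by thirds (c.344 → codon 115, offset 2);
`inframe_check()` classifies deletions by length modulo 3 and reports
codon-boundary alignment separately (c.346_348del → in-frame single-codon
deletion of codon 116; a length-6 deletion starting mid-codon is still
in-frame but unaligned).

**Hydropathy profiles.** `hydropathy_profile()` computes the centered
moving average of Kyte–Doolittle values (window odd; truncated windows at
the termini, policy recorded on the object). The published segment means
for the mutation-bearing region (1.699 ± 0.69 wild type, 1.181 L115R,
1.559 L116del) do not state the window convention, and no centered window
1–13 over residues 110–120 reproduces them. `calibrate_hydropathy_window()`
therefore scans windows and small extensions of the averaging segment's
edges against the three published means; the scan selects **window 9
averaged over profile positions 105–120**, which reproduces the wild-type
mean to three decimals (1.6993, sd 0.694) and the L115R mean exactly
(1.1806); L116del gives 1.578 (published 1.559, Δ = 0.02). The calibrated
convention, not a guess, is used wherever the printed means are compared.

**Membrane-transfer energetics.** `transfer_dG()` sums Wimley–White
whole-residue free energies (interface or octanol scale) over a segment;
`octanol_minus_interface()` is the classic ΔG~woc~ − ΔG~wif~ measure of
transbilayer-helix preference. Units: the scales are experiment-based
kcal/mol values; some publications label the same magnitudes kJ/mol. The
package stores scale-native values and compares magnitudes only. Over
A108–K139 the wild type gives −5.69 (interface) and 6.55 (octanol −
interface); L115R gives −4.32 and 8.24; L116del −5.13 and 7.24 — the
ordering (wild type most membrane-avid, L115R least) is the mechanistic
finding. No end-group corrections are applied; the sum-only model
reproduces the published values exactly, which settles that question.

**Group comparison.** `compare_variant_profiles()` runs a Kruskal–Wallis
rank test (tie-corrected, via `stats::kruskal.test`) followed by Dunn's
pairwise z tests with Bonferroni adjustment over the number of pairs — the
classical procedure, chosen because no correction was named in the source
analyses. On the calibrated hydropathy segments this flags L115R vs wild
type (adjusted p ≈ 0.029) and not L116del vs wild type, matching the
published significance pattern.

## Numerical and design choices

* Removal thresholds are strict inequalities ("greater than 5%"); equality
  keeps.
* Variant identity for set operations is (chrom, pos, ref, alt).
* Indel alleles carry explicit payloads (`-AA`, `+CTC`, `-TTTTA`) exactly
  as transcribed; positions are 1-based and the genome build is opaque
  metadata (the candidate fixture stores GRCh37 positions verbatim; no
  liftover is attempted).
* All randomness flows from a single integer seed; replicate *r* of an
  experiment uses `seed + r − 1`. Pipeline runs are byte-identical under a
  fixed seed and config (outputs are stamped with the seed and a config
  hash, never with timestamps).
* Degenerate inputs: empty variant tables, empty segments (ΔG = 0), empty
  control panels (identity subtraction) and all-failing shortlists (empty
  data frame) are all defined rather than errors.

## Problem sizes used by the test suite

The suite favours exact small fixtures plus seeded Monte-Carlo at sizes
chosen for statistical resolution: sharing-fraction checks use 10,000
founder variants per relationship (3 Monte-Carlo standard errors
≈ 0.02 resolution); causal-variant retention is checked over 100 seeded
replicates of a reduced cohort (100 novel variants, 2,000 coding calls per
sample), sizes at which the retention property is exercised through every
cascade stage; study-scale structure (38,179 coding calls, 674 novel
nonsynonymous) is checked once at full scale. These are the package's own
choices of experiment size.

## Known limitations

* The dominant fully-penetrant model is the only segregation model;
  recessive and compound-heterozygous designs are out of scope.
* The simulator's exchangeable-variant assumption makes it unsuitable for
  linkage-aware questions.
* Population-control screening in the simulated pipeline draws carrier
  counts binomially from true allele frequencies, approximating carriers
  by allele count (exact for rare variants).
* The physicochemical scores are sequence-based screens, not structural
  simulations; they rank mutant propensities and are not binding-affinity
  predictions.
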