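---
title: "Methods: mining Lys/Arg methylation sites from PSMs"
author: "methylsieve developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining Lys/Arg methylation sites from PSMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylsieve)
```

## The problem

Shotgun proteomics identifies peptides by matching MS/MS spectra against a
protein database. When the search allows methylation of Lys (me1/me2/me3)
and Arg (me1/me2) as variable modifications, the resulting methyl-PSMs have
a much higher false-discovery rate than ordinary PSMs, for two chemical
reasons:

* **Substitution isobars.** A methyl mass shift equals some single
  amino-acid substitutions exactly: +14.01565 Da (me1) is D→E, N→Q, G→A,
  S→T or V→L/I; +28.03130 Da (me2) is A→V or C→M; +42.04695 Da (me3) is
  A→L/I or G→V. A search engine can assign such spectra to a sequence
  variant with a nearly identical score.
* **The trimethyl/acetyl near-isobar.** Trimethylation (+42.04695 Da) and
  acetylation (+42.01056 Da) differ by 0.03639 Da. Two ±`tol` ppm windows
  separated by Δ overlap once the peptide neutral mass exceeds
  Δ/(2·tol·10⁻⁶) — 1819.5 Da at 10 ppm — so precursor mass alone cannot
  discriminate heavy peptides.

`methylsieve` implements a six-step filter that addresses both, plus a
methyl-specific target-decoy FDR, site aggregation with spectral-count
stoichiometry, and a synthetic-data generator that makes every stage
testable without external data.

## Mass model

All masses derive from one hard-coded atomic monoisotopic table
(C 12.000000, H 1.0078250319, N 14.0030740052, O 15.9949146221,
S 31.97207069) so results are bit-reproducible with no runtime dependency
on an element database. The proton mass convention for m/z is
1.00727646677 Da. Residue masses are amino acid minus water; peptide mass is
Σresidues + H₂O + Σmodification deltas. Fragment m/z follows the usual b/y
convention (b_i = prefix residues + charge·proton; y_i = suffix residues +
water + charge·proton), with modification deltas carried by every covering
fragment. The modification registry holds the variable search set (Lys
me1/2/3, Arg me1/2, Met ox/diox, Cys trioxidation, N-terminal acetyl) plus
fixed carbamidomethyl-Cys; Lys acetyl is present purely as the competing
hypothesis for step 6, not as a search modification. Reports round Da to 5
decimals and ppm to 1 decimal, the precision at which these quantities are
conventionally printed.

## Digestion and decoys

Digestion uses the Trypsin/P rule — cleave after every K or R, including
before proline — with up to three missed cleavages (methylated K/R impair
the protease, so methylpeptides typically carry a missed cleavage).
Coordinates are 1-based on the full precursor sequence, initiator Met and
transit peptide included, so site numbering matches full-length protein
coordinates. Decoys are end-to-end reversed sequences with a configurable
accession prefix (`rev_` by default); a PSM is a decoy match iff all its
accessions are decoys.

## The six-step filter

Given parse-filtered PSMs (score ≥ 20, rank 1, engine homology threshold
passed; duplicated peptide sequences deliberately conserved):

1. **Seeds**: methyl-PSMs with score ≥ 50 (`seed_score`).
2. **Quality**: each seed's spectrum must match ≥ 50 % of theoretical
   singly charged b/y ions within 0.8 Da and place ≥ 1 matched fragment
   across the methylated residue. This is an explicit, reproducible rule
   standing in for expert spectrum inspection; both thresholds are
   configurable and reported. A seed without a spectrum fails quality.
3. **Corroboration**: every methyl-PSM with score ≥ 20 mapping to a seeded
   (protein, position, residue) site — through any modification pattern or
   overlapping miscleaved peptide — attaches as support; methyl degrees are
   pooled (a site observed as me1 and me3 is one site with degrees
   {1, 3}).
4. **Minimum evidence**: sites with fewer than 2 supporting PSMs are
   removed.
5. **Substitution ambiguity**: for each supporting PSM the package
   enumerates all single-residue substitutions (any position except the
   methylated site itself, any standard residue) whose mass change matches
   the methyl delta within 10 ppm of the peptide mass; *exact* isobars mark
   the PSM ambiguous. A site whose every supporting PSM is ambiguous is
   removed; mixed support survives with a flag. In-place replacement of the
   methylated residue is excluded because no standard residue sits exactly
   at K/R + methyl delta — a testable consequence of the mass table.
6. **Trimethyl vs acetyl**: each trimethyl-supporting PSM is scored under
   both hypotheses. The precursor error calibration is the median and
   1.4826·MAD of ppm errors from all target PSMs with score > 40 (≥ 20 of
   them required); a hypothesis is "in band" when its error lies within
   median ± 3·MAD-spread. Verdict per PSM: *trimethyl* if mass favors
   trimethyl alone, or the trimethylamine neutral loss is present and
   acetyl is not favored alone; *acetyl* if mass favors acetyl alone with
   no loss; otherwise *ambiguous*. Per site: any trimethyl verdict confirms;
   otherwise any acetyl verdict removes; otherwise the site is retained
   with an unresolved-ambiguity flag. This combination rule is the
   package's own — only the per-site outcomes of the original procedure are
   documented — and is stated here so it can be criticised.

The neutral-loss check searches, within the 0.8 Da *fragment* tolerance
(the loss is read from MS/MS peaks), for peaks at precursor − 59.0735/z and
at site-covering singly charged fragments − 59.0735, where 59.07350 Da is
the computed monoisotopic mass of C3H9N ("−59" being its nominal label).
One refinement matters: a candidate loss peak lying within the fragment
tolerance of *any* theoretical b/y ion of the peptide is discarded, because
two ordinary fragments ~59 Da apart would otherwise fake the diagnostic
loss; without this rule the loss detector has a substantial false-positive
rate on loss-free spectra.

The methyl FDR, `FDR = 2·n_rev/(n_rev + n_real)` capped at 1 (the raw
formula exceeds 1 when decoys dominate), is reported before step 1 and over
the supporting PSMs of surviving sites, and the audit log records the
per-step site counts and each removed site with its removal step.

### Localization ambiguity

When a peptide contains another legal acceptor residue and no matched
fragment covers exactly one of the two positions in any assessed seed
spectrum, the site is flagged localization-ambiguous with its alternative
positions; it still counts as one site in summaries (mirroring the
single-row treatment of such sites in curated inventories).

## Stoichiometry, windows, inventory

Site occupancy is proxied by spectral counts: SC_methyl (supporting
methyl-PSMs) over SC_total (all PSMs, methylated or not, whose peptide
covers the site). The ratio is undefined at SC_total = 0 and reported
missing. Motif context is the exact 13-mer (site ± 6 residues) padded with
`-` at termini, ready for sequence-logo tools.

The package ships a curated site-level inventory fixture (37 sites in 28
proteins; 31 sites in 23 chloroplast-localized proteins across stroma,
thylakoid and envelope) transcribed with positions, degree sets
(`me1/2/3`-style), status flags (`c` trimethyl-confirmed, `a`
trimethyl/acetyl-unresolved), alternative positions for the one
localization-ambiguous site, and the single spectral-count pair printed in
the source text (ATP-B R52: 2/45). Its checksum is verified on load;
`count_summary()` over it is the package's primary regression suite. The 3D
accessibility annotation of the original table is out of scope and not
carried.

## The synthetic world

`simulate_dataset()` generates the statistical structure the pipeline
assumes, with the truth retained:

* **Scores**: forward PSMs ~ Normal(65, 15) truncated at 0, decoys ~
  Normal(25, 8) — shapes emulating the clear forward/decoy separation that
  motivates the score-50 seed threshold. The parameters themselves are
  artifact choices, not measured values.
* **Precursor errors**: Normal(0, 1.5) ppm applied multiplicatively to
  m/z, a realistic calibrated-FT-instrument spread; the drawn error of every
  PSM is retained in the provenance table.
* **Sites**: each planted event gets a designed tryptic cassette
  (`R` + 3-residue flank + K/R + 3-residue flank + K/R) spliced into a
  random protein at a recorded position. Flank alphabets exclude exactly
  the residues that admit exact isobars for the planted degree, so true
  sites survive step 5 *by construction* — which also means a green
  recovery test does not exercise step 5's behaviour on borderline true
  sites, only on the planted mimics. Cassette peptides are ≤ 8 residues
  (< 1506 Da even all-Trp), keeping every trimethyl case below the
  1819.5 Da separability limit.
* **Occupancy**: each true site draws an occupancy from U(0.3, 1); covering
  PSMs (~Poisson(20)) are methylated with that probability, with a floor of
  two methyl-PSMs and one seed-grade score (a forward-model draw
  conditioned ≥ 50) so the stated scenario — every true site has ≥ 2 PSMs
  and a seed — holds deterministically. The conditioning touches a handful
  of draws and leaves the score-mean checks intact.
* **Confounders**: single-PSM spurious sites (removed at step 4), an
  acetylated peptide reported under the trimethyl hypothesis with the
  correspondingly shifted precursor (removed at step 6), and a monomethyl
  site whose only peptide contains D (exact D→E; removed at step 5).
  Confounder scores are floored at 55 so each one actually reaches the step
  built to remove it.
* **Spectra**: singly charged b/y peaks each emitted with probability 0.9,
  uniform intensities, 10 uniform noise peaks, and — for trimethyl spectra,
  with probability `p_neutral_loss` — precursor-loss and fragment-loss
  peaks. Noise is rejected from ±1 Da around the loss-target windows so
  neutral-loss detection reflects only the planted emission flag; real data
  offers no such guarantee, which is exactly why the detector also excludes
  fragment-coincident peaks.
* **Determinism**: one global RNG seeded from the mandatory config seed;
  draws occur in a fixed documented order (event plan, proteome, per-event
  PSMs/spectra, background, decoys), so identical configs give
  byte-identical outputs.

What the generator does **not** emulate: chromatography, charge-state and
isotope envelopes, intensity structure, score-spectrum coupling (scores are
simulated, never computed from peaks), shared peptides between paralogs,
and real calibration drift. A green end-to-end test therefore establishes
the correctness of the filtering logic under the stated error model, not
instrument-level performance.

## Numerical choices and degenerate inputs

* Exactness of an isobar is |Δ| < 10⁻⁶ Da; tolerance windows are relative
  (ppm of the peptide mass) for precursors and absolute Da for fragments.
* The score cutoff is inclusive (score ≥ 20 kept); declared because
  "cutoff applied" is ambiguous, and tested at the 19.9/20.0 boundary.
* Protein groups merge accessions with identical matched-peptide sets; the
  representative is the lexicographically smallest accession.
* Empty PSM input to the pipeline raises an explicit "no methyl-PSMs"
  error; a calibration population below 20 refuses rather than degrades;
  FDR with an empty population is an explicit error, not NaN.
* `separability_mass_limit(delta, 0)` returns Inf (always separable).
* Peptide-to-protein mapping uses the first exact occurrence; the generator
  guarantees planted peptides occur exactly once.

## Known limitations

* Site-localization probabilities (Ascore-style) are out of scope; the
  localization flag is binary.
* Step 5 judges substitutions by mass only; it does not check whether the
  substituted sequence exists in the database, so it is conservative
  (removes more than an engine-aware re-search would).
* The packaged inventory's spectral counts are unknown except one site, so
  stoichiometry over the fixture is mostly missing by design.
* The CLI's TOML reader covers the flat `key = value` subset used by its
  own config schema, nothing more.
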