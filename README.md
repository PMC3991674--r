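# methylsieve

Discovery of lysine and arginine methylation sites from shotgun-proteomics
peptide-spectrum matches (PSMs).

Protein Lys/Arg methylation is hard to mine from standard database-search
results: methyl mass shifts are isobaric to single amino-acid substitutions
(e.g. D→E explains +14.01565 Da exactly), and trimethylation
(+42.04695 Da) is nearly isobaric to acetylation (+42.01056 Da, a gap of
only 0.03639 Da). `methylsieve` implements a reproducible filtering pipeline
that turns scored methyl-PSMs into a validated, site-level methylprotein
inventory:

1. **Seed selection** — methyl-PSMs with search score ≥ 50;
2. **Spectral quality** — automated stand-in for expert inspection (matched
   b/y-fragment fraction, site-covering ions);
3. **Corroboration** — lower-score PSMs (score ≥ 20) hitting the same
   (protein, position, residue) site across modification patterns and
   miscleaved peptides;
4. **Minimum evidence** — sites supported by fewer than two PSMs are dropped;
5. **Substitution ambiguity** — sites relying solely on PSMs that admit an
   exact isobaric single-residue substitution are discarded;
6. **Trimethyl vs acetyl** — resolved by accurate precursor mass against a
   robust calibration band (median ± 3·MAD of errors from PSMs with score
   > 40) and by the trimethylamine neutral loss (C3H9N, −59 Da), the
   MS/MS signature of trimethyl-lysine.

A methyl-specific target-decoy FDR, `FDR = 2·n_rev/(n_rev+n_real)`, is
estimated before and after filtering. Supporting machinery includes
monoisotopic mass bookkeeping, in-silico Trypsin/P digestion with up to
three missed cleavages, reversed-decoy database construction, PSM/MGF/FASTA
IO, spectral-count stoichiometry (SC_methyl/SC_total), ±6-residue motif
windows, and a fully seeded synthetic-data generator with retained ground
truth so the whole pipeline is testable without any external data.

## Worked example

```r
library(methylsieve)

# a ground-truth dataset: 5 true methylation sites, 2 single-PSM spurious
# sites, 1 acetylated peptide reported as trimethyl, 1 exact D->E
# substitution mimic
ds  <- simulate_dataset(simulation_config(seed = 1L))
res <- run_pipeline(ds$psms, ds$spectra, ds$proteome)
res
#> methylsieve pipeline result
#>   input PSMs:         300
#>   methyl-PSMs:        115
#>   initial methyl FDR: 0.591
#>   final methyl FDR:   0
#>   validated sites:    5

truth_eval(res$sites, ds$truth)[c("precision", "recall")]
#> $precision
#> [1] 1
#> $recall
#> [1] 1

res$audit$removed
#>           site step                                                   reason
#> 1 SYN001:168:K    5 all supporting PSMs admit an exact isobaric substitution
#> 2 SYN009:126:K    4          fewer supporting PSMs than min_spectra_per_site
#> 3 SYN010:196:K    4          fewer supporting PSMs than min_spectra_per_site
#> 4 SYN020:100:K    6 accurate mass favors acetylation, no trimethylamine loss
```

The initial methyl FDR of 0.59 reflects the decoy methyl-PSMs planted by the
simulator; after the six steps every decoy and confounder is gone (final FDR
0), all five true sites are recovered, and each confounder is removed at the
step designed to catch it.

The curated site inventory packaged with `methylsieve` summarizes to the
reference counts:

```r
inv <- load_packaged_inventory()
count_summary(inv, chloroplast_only = TRUE)[c("n_sites", "n_proteins", "by_residue")]
#> $n_sites   [1] 31
#> $n_proteins [1] 23
#> $by_residue  K  R
#>             24  7
```

## Command line

```sh
methylsieve simulate --seed 17 --outdir data/
methylsieve filter   --psms data/psms.tsv --mgf data/spectra.mgf \
                     --fasta data/target_decoy.fasta --out sites.tsv
methylsieve report   --sites sites.tsv --fasta data/target_decoy.fasta \
                     --out summary.json --windows windows.tsv
```

(the launcher is installed under `exec/methylsieve` in the package library;
`methylsieve_main()` exposes the same interface from R). A JSON manifest with
configuration, seed and input checksums is written beside every output.

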