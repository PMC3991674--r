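Package: methylsieve
Title: Discovery of Lysine and Arginine Methylation Sites from Shotgun Proteomics PSMs
Version: 0.1.0
Authors@R:
    person("methylsieve", "developers", email = "methylsieve@example.org",
           role = c("aut", "cre"))
Description: A filtering pipeline that mines lysine and arginine methylation
    sites from scored peptide-spectrum matches (PSMs). Implements monoisotopic
    mass bookkeeping for methyl-class modifications, in-silico Trypsin/P
    digestion with missed cleavages and reversed-decoy database construction,
    target-decoy false discovery rate estimation specific to methyl-PSMs, a
    six-step candidate filter including isobaric amino-acid substitution
    screening and trimethyl-versus-acetyl disambiguation by accurate precursor
    mass and trimethylamine neutral-loss detection, site-level aggregation
    with spectral-count stoichiometry, and a seeded synthetic-data generator
    providing ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
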