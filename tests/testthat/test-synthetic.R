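test_that("simulation is byte-deterministic for a fixed configuration", {
  cfg <- simulation_config(seed = 42L)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$psms, b$psms)
  expect_identical(a$proteome, b$proteome)
  expect_identical(a$spectra, b$spectra)
  expect_identical(a$truth, b$truth)
})

test_that("score models reproduce their configured means", {
  cfg <- simulation_config(seed = 101L, n_decoy_psms = 120L,
                           n_background_psms = 150L)
  ds <- simulate_dataset(cfg)
  dec <- ds$psms$score[ds$psms$is_decoy]
  fwd <- ds$psms$score[!ds$psms$is_decoy &
                         ds$truth$provenance$label == "background"]
  expect_lt(abs(mean(dec) - cfg$decoy_score_mean),
            3 * cfg$decoy_score_sd / sqrt(length(dec)))
  expect_lt(abs(mean(fwd) - cfg$forward_score_mean),
            3 * cfg$forward_score_sd / sqrt(length(fwd)))
  # forward/decoy separation: decoys essentially never reach the seed score
  expect_gt(mean(fwd), mean(dec))
})

test_that("observed precursors match peptide mass plus the planted ppm error", {
  ds <- simulate_dataset(simulation_config(seed = 13L))
  prov <- ds$truth$provenance
  for (i in seq_len(nrow(ds$psms))) {
    eps <- prov$ppm_true[prov$spectrum_id == ds$psms$spectrum_id[i]]
    theo <- peptide_mass(ds$psms$peptide[i], ds$psms$mods[i])
    if (prov$label[prov$spectrum_id == ds$psms$spectrum_id[i]] ==
        "acetyl_mimic") {
      mods <- parse_mods(ds$psms$mods[i])
      mods$name[mods$name == "trimethyl"] <- "acetyl"
      theo <- peptide_mass(ds$psms$peptide[i], mods)
    }
    expected <- mass_to_mz(theo, ds$psms$charge[i]) * (1 + eps * 1e-6)
    expect_equal(ds$psms$obs_mz[i], expected, tolerance = 1e-6)
  }
})

test_that("degenerate neutral-loss probability silences detection", {
  ds <- simulate_dataset(simulation_config(seed = 17L, p_neutral_loss = 0))
  tri <- which(grepl("trimethyl@", ds$psms$mods) & !ds$psms$is_decoy)
  prov <- ds$truth$provenance
  for (i in tri) {
    id <- ds$psms$spectrum_id[i]
    if (is.null(ds$spectra[[id]])) next
    out <- detect_neutral_loss(ds$spectra[[id]], ds$psms[i, ])
    expect_false(out$detected)
  }
})

test_that("occupancy is recovered through spectral-count stoichiometry", {
  cfg <- simulation_config(seed = 29L, n_true_sites = 10L, psm_mean = 40,
                           n_proteins = 25L, n_spurious = 0L,
                           n_acetyl_mimic = 0L, n_substitution_mimic = 0L)
  ds <- simulate_dataset(cfg)
  res <- run_pipeline(ds$psms, ds$spectra, ds$proteome)
  ev <- ds$truth$events
  m <- merge(res$sites, ev, by = c("accession", "position"))
  expect_identical(nrow(m), 10L)
  expect_gt(cor(m$stoichiometry, m$occupancy, method = "spearman"), 0.9)
})

test_that("infeasible configurations are rejected before generation", {
  cfg <- simulation_config(seed = 1L, n_proteins = 3L)
  expect_error(simulate_dataset(cfg), "infeasible")
  expect_error(simulation_config(), "seed is mandatory")
  expect_error(simulation_config(seed = 1L, p_fragment = 1.5),
               "probabilities")
})

test_that("truth_eval computes exact set precision and recall", {
  ds <- simulate_dataset(simulation_config(seed = 5L))
  ev <- ds$truth$events
  true_sites <- ev[ev$type == "true_methyl",
                   c("accession", "position", "residue")]
  perfect <- truth_eval(true_sites, ds$truth)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  none <- truth_eval(true_sites[0, ], ds$truth)
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)
  # confounder table flags nothing for the perfect set
  expect_false(any(perfect$confounders$validated))
})

test_that("write_dataset emits readable standard formats", {
  ds <- simulate_dataset(simulation_config(seed = 23L, n_proteins = 12L,
                                           n_true_sites = 2L,
                                           psm_mean = 6,
                                           n_background_psms = 25L,
                                           n_decoy_psms = 10L))
  outdir <- withr::local_tempdir()
  paths <- write_dataset(ds, outdir)
  expect_true(all(file.exists(paths)))
  back_psms <- read_psm_table(paths[["psms"]])
  expect_equal(back_psms$obs_mz, ds$psms$obs_mz, tolerance = 1e-9)
  expect_identical(back_psms$mods, ds$psms$mods)
  back_fasta <- read_fasta(paths[["fasta"]])
  expect_identical(back_fasta$sequence, ds$proteome$sequence)
  back_mgf <- read_mgf(paths[["mgf"]])
  expect_identical(names(back_mgf), names(ds$spectra))
})
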