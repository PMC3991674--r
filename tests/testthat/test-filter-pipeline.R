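test_that("the target-decoy FDR formula, cap and zero-decoy cases hold", {
  psms <- rbind(
    do.call(rbind, lapply(1:99, function(i)
      make_psm(sprintf("t%d", i), score = 60))),
    make_psm("d1", score = 60, is_decoy = TRUE))
  est <- estimate_fdr(psms, 50)
  expect_identical(est$n_rev, 1L)
  expect_identical(est$n_real, 99L)
  expect_equal(est$fdr, 0.02)
  # zero decoys -> 0
  expect_equal(estimate_fdr(psms[1:10, ], 0)$fdr, 0)
  # decoys dominate -> capped at 1
  mix <- rbind(psms[1:5, ],
               do.call(rbind, lapply(1:5, function(i)
                 make_psm(sprintf("dd%d", i), score = 60, is_decoy = TRUE))))
  expect_equal(estimate_fdr(mix, 0)$fdr, 1)
  # nothing above threshold -> explicit error
  expect_error(estimate_fdr(psms, 1000), "undefined")
})

test_that("spectral quality assessment scores matches and site coverage", {
  psm <- make_psm(peptide = "LNTEWKAFER", mods = "dimethyl@6")
  cfg <- pipeline_config()
  # every theoretical b/y present -> fraction 1, pass
  q1 <- assess_spectrum_quality(make_self_spectrum(psm), psm, cfg)
  expect_true(q1$pass)
  expect_equal(q1$matched_fraction, 1.0)
  # pure noise -> fail
  noise <- list(spectrum_id = "s1", precursor_mz = psm$obs_mz, charge = 2L,
                mz = seq(2000, 2100, by = 10), intensity = rep(1, 11))
  expect_false(assess_spectrum_quality(noise, psm, cfg)$pass)
  # all non-covering fragments present, none covering the site -> fail on
  # site-determining count even though the fraction can be decent
  fr <- fragment_ions(psm$peptide, psm$mods, charge = 1L)
  non_cov <- fr[!(fr$start <= 6 & 6 <= fr$end), ]
  sp <- list(spectrum_id = "s1", precursor_mz = psm$obs_mz, charge = 2L,
             mz = sort(non_cov$mz), intensity = rep(5, nrow(non_cov)))
  q3 <- assess_spectrum_quality(sp, psm, cfg)
  expect_identical(q3$n_site_determining, 0L)
  expect_false(q3$pass)
  # id mismatch is an error
  bad <- make_self_spectrum(psm); bad$spectrum_id <- "other"
  expect_error(assess_spectrum_quality(bad, psm, cfg), "mismatch")
})

make_mini_world <- function() {
  # one protein containing the tryptic peptide LNTEWKAFER (K at position 26)
  prot <- data.frame(
    accession = "P1", description = "",
    sequence = paste0("MTTAPLHHEFAIWQPPLIERLNTEWKAFERGGHTLPWYQTTIHK"),
    is_decoy = FALSE, stringsAsFactors = FALSE)
  make_target_decoy(prot)
}

test_that("seeding and corroboration pool PSMs onto protein sites", {
  proteome <- make_mini_world()
  cfg <- pipeline_config(calibration_min_n = 1)
  seed_psm <- make_psm("s1", peptide = "LNTEWKAFER", mods = "trimethyl@6",
                       score = 62)
  support <- make_psm("s2", peptide = "LNTEWKAFER", mods = "trimethyl@6",
                      score = 34)
  # overlapping 1-missed-cleavage extension covering the same site
  extension <- make_psm("s3", peptide = "LNTEWKAFERGGHTLPWYQTTIHK",
                        mods = "trimethyl@6", score = 41)
  orphan <- make_psm("s4", peptide = "LNTEWKAFER", mods = "monomethyl@6",
                     score = 47)  # no seed-score PSM anywhere else
  psms <- rbind(seed_psm, support, extension)
  spectra <- list(s1 = make_self_spectrum(seed_psm))
  cands <- seed_and_corroborate(psms, spectra, proteome, cfg)
  expect_length(cands, 1L)
  site <- cands[[1]]
  expect_identical(site$position, 26L)
  expect_identical(site$residue, "K")
  expect_length(site$psm_idx, 3L)
  # degrees pooled across supporting PSMs
  psms2 <- rbind(seed_psm, orphan)
  spectra2 <- list(s1 = make_self_spectrum(seed_psm))
  cands2 <- seed_and_corroborate(psms2, spectra2, proteome, cfg)
  expect_identical(cands2[[1]]$degrees, c(1L, 3L))
  # a score-47 PSM with no seed never founds a site
  cands3 <- seed_and_corroborate(orphan, list(), proteome, cfg)
  expect_length(cands3, 0L)
})

test_that("the minimum-spectra rule removes singleton sites", {
  proteome <- make_mini_world()
  cfg <- pipeline_config()
  seed_psm <- make_psm("s1", peptide = "LNTEWKAFER", mods = "trimethyl@6",
                       score = 62)
  spectra <- list(s1 = make_self_spectrum(seed_psm))
  cands <- seed_and_corroborate(seed_psm, spectra, proteome, cfg)
  out <- apply_min_spectra(cands, cfg)
  expect_identical(out[[1]]$removed_at, 4L)
  # with a second PSM the site survives
  psms <- rbind(seed_psm, make_psm("s2", peptide = "LNTEWKAFER",
                                   mods = "trimethyl@6", score = 30))
  cands2 <- seed_and_corroborate(psms, spectra, proteome, cfg)
  out2 <- apply_min_spectra(cands2, cfg)
  expect_true(is.na(out2[[1]]$removed_at))
  expect_identical(apply_min_spectra(list(), cfg), list())
})

test_that("mixed substitution support survives step 5, pure support does not", {
  # QDTLKR with monomethyl-K admits the exact D->E substitution; the same
  # peptide with dimethyl-K admits none (no A or C present)
  prot <- data.frame(
    accession = "P1", description = "",
    sequence = "MTTAPLHHEFAIWRQDTLKRFQHETPLIWK",
    is_decoy = FALSE, stringsAsFactors = FALSE)
  proteome <- make_target_decoy(prot)
  cfg <- pipeline_config()
  set.seed(67)
  calib <- make_calibration(rnorm(25, 0, 1.5))
  amb1 <- make_psm("s1", peptide = "QDTLKR", mods = "monomethyl@5", score = 62)
  amb2 <- make_psm("s2", peptide = "QDTLKR", mods = "monomethyl@5", score = 55)
  spectra <- list(s1 = make_self_spectrum(amb1), s2 = make_self_spectrum(amb2))
  psms <- rbind(amb1, amb2)
  cands <- seed_and_corroborate(psms, spectra, proteome, cfg)
  cands <- apply_ambiguity_filters(cands, psms, spectra, calib, cfg)
  expect_identical(cands[[1]]$removed_at, 5L)
  # same site with one additional unambiguous supporting PSM: retained,
  # flagged
  clean <- make_psm("s3", peptide = "QDTLKR", mods = "dimethyl@5", score = 45)
  psms2 <- rbind(amb1, amb2, clean)
  cands2 <- seed_and_corroborate(psms2, spectra, proteome, cfg)
  cands2 <- apply_ambiguity_filters(cands2, psms2, spectra, calib, cfg)
  expect_true(is.na(cands2[[1]]$removed_at))
  expect_true(cands2[[1]]$flag_substitution)
  expect_identical(cands2[[1]]$degrees, c(1L, 2L))
})

test_that("run_pipeline is deterministic and monotone in the seed score", {
  ds <- simulate_dataset(simulation_config(seed = 7L))
  r1 <- run_pipeline(ds$psms, ds$spectra, ds$proteome)
  r2 <- run_pipeline(ds$psms, ds$spectra, ds$proteome)
  expect_identical(r1$sites, r2$sites)
  expect_identical(r1$audit, r2$audit)
  # raising the seed score can only shrink or preserve the validated set
  strict <- run_pipeline(ds$psms, ds$spectra, ds$proteome,
                         pipeline_config(seed_score = 75))
  key <- function(s) paste(s$accession, s$position, s$residue)
  expect_true(all(key(strict$sites) %in% key(r1$sites)))
  # the methyl FDR does not increase through the pipeline
  expect_lte(r1$fdr_final$fdr, r1$fdr_initial$fdr)
})

test_that("run_pipeline surfaces an explicit error when no methyl-PSMs", {
  proteome <- make_mini_world()
  plain <- make_psm("s1", peptide = "LNTEWKAFER", score = 80)
  expect_error(run_pipeline(plain, list(), proteome), "no methyl-PSMs")
})

test_that("validated sites all retain minimum support and a clean PSM", {
  ds <- simulate_dataset(simulation_config(seed = 19L))
  res <- run_pipeline(ds$psms, ds$spectra, ds$proteome)
  cfg <- pipeline_config()
  expect_true(all(res$sites$n_psms >= cfg$min_spectra_per_site))
  expect_true(all(res$sites$n_seed >= 1))
  expect_true(all(res$sites$sc_methyl <= res$sites$sc_total))
  # sites table is a subset of seeded candidates
  seeded <- names(res$candidates)
  expect_true(all(paste(res$sites$accession, res$sites$position,
                        res$sites$residue, sep = ":") %in% seeded))
})
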