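test_that("known exact isobars are found", {
  # D->E explains monomethyl exactly
  subs <- find_isobaric_substitutions("ADTLKR", "monomethyl@5", site = 5)
  expect_true(any(subs$from == "D" & subs$to == "E" & subs$exact))
  # trimethyl: A->L, A->I, G->V
  subs3 <- find_isobaric_substitutions("AGTLKR", "trimethyl@5", site = 5)
  expect_true(all(c("L", "I") %in% subs3$to[subs3$from == "A" & subs3$exact]))
  expect_true(any(subs3$from == "G" & subs3$to == "V" & subs3$exact))
  # peptide with no substitutable residue within tolerance -> empty
  none <- find_isobaric_substitutions("TTTTKR", "trimethyl@5", site = 5,
                                      tol_ppm = 1)
  expect_identical(nrow(none), 0L)
  expect_error(find_isobaric_substitutions("ADTLKR", "", site = 5),
               "methyl-class")
})

test_that("substitution scan matches the brute-force oracle", {
  set.seed(53)
  for (rep in 1:60) {
    len <- sample(3:8, 1)
    pep <- random_peptide(len)
    kr <- which(strsplit(pep, "")[[1]] %in% c("K", "R"))
    if (!length(kr)) next
    site <- sample(rep(kr, 2), 1)
    res <- substr(pep, site, site)
    degree <- if (res == "K") sample(1:3, 1) else sample(1:2, 1)
    tol <- sample(c(1, 10, 50), 1)
    got <- find_isobaric_substitutions(
      pep, sprintf("%s@%d", methyl_mod_name(degree), site), site, tol)
    want <- oracle_substitutions(pep, site, degree, tol)
    got <- got[order(got$position, got$to), c("position", "from", "to", "exact")]
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want, info = paste(pep, site, degree, tol))
  }
})

test_that("separability limit follows delta / (2 tol) and is monotone", {
  expect_equal(separability_mass_limit(0.03639, 10), 1819.5, tolerance = 1e-6)
  expect_equal(separability_mass_limit(0.03639, 5), 3639, tolerance = 1e-6)
  expect_identical(separability_mass_limit(0.03639, 0), Inf)
  tols <- c(1, 2, 5, 10, 20)
  lims <- vapply(tols, function(t) separability_mass_limit(0.03639, t),
                 numeric(1))
  expect_true(all(diff(lims) < 0))
  deltas <- c(0.01, 0.02, 0.05)
  lims2 <- vapply(deltas, function(d) separability_mass_limit(d, 10),
                  numeric(1))
  expect_true(all(diff(lims2) > 0))
})

test_that("neutral-loss detection finds precursor and fragment loss peaks", {
  psm <- make_psm(peptide = "LNTEWKAFER", mods = "trimethyl@6", charge = 2L)
  loss <- trimethylamine_mass()
  # spectrum with a peak at precursor_mz - loss/2 (charge 2)
  sp <- list(spectrum_id = "s1", precursor_mz = psm$obs_mz, charge = 2L,
             mz = c(200, psm$obs_mz - loss / 2, 900), intensity = c(1, 5, 2))
  out <- detect_neutral_loss(sp, psm)
  expect_true(out$detected)
  expect_true(out$precursor_loss)
  expect_false(out$fragment_loss)
  # a site-covering fragment minus the loss
  fr <- fragment_ions(psm$peptide, psm$mods, charge = 1L)
  cov <- fr[fr$start <= 6 & 6 <= fr$end, ][1, ]
  sp2 <- list(spectrum_id = "s1", precursor_mz = psm$obs_mz, charge = 2L,
              mz = cov$mz - loss, intensity = 3)
  out2 <- detect_neutral_loss(sp2, psm)
  expect_true(out2$detected)
  expect_true(out2$fragment_loss)
  # empty peak list
  sp3 <- list(spectrum_id = "s1", precursor_mz = psm$obs_mz, charge = 2L,
              mz = numeric(0), intensity = numeric(0))
  expect_false(detect_neutral_loss(sp3, psm)$detected)
  bad <- psm; bad$charge <- 0L
  expect_error(detect_neutral_loss(sp, bad), "charge")
})

test_that("calibration is robust and refuses small populations", {
  set.seed(59)
  errs <- rnorm(40, 0.3, 1.2)
  calib <- make_calibration(errs)
  expect_equal(calib$center, median(errs), tolerance = 1e-6)
  expect_equal(calib$spread, mad(errs), tolerance = 1e-6)
  few <- do.call(rbind, lapply(1:5, function(i)
    make_psm(sprintf("s%d", i), score = 80)))
  expect_error(build_calibration(few, 40, 20), "at least")
})

test_that("trimethyl/acetyl verdicts follow mass and neutral-loss evidence", {
  calib <- make_calibration(rnorm(30, 0, 1.5))
  set.seed(61)
  pep <- "LNTEWKAFER"  # ~1300 Da: below the 10 ppm separability limit
  loss <- trimethylamine_mass()
  # genuine trimethyl: mass in band, loss present -> trimethyl
  tri <- make_psm(peptide = pep, mods = "trimethyl@6", ppm = 0.5)
  sp_tri <- make_self_spectrum(tri, extra_mz = tri$obs_mz - loss / 2)
  v1 <- resolve_trimethyl_acetyl(tri, sp_tri, calib)
  expect_identical(v1$verdict, "trimethyl")
  expect_true(v1$neutral_loss_detected)
  expect_lt(abs(v1$error_vs_trimethyl), 3 * calib$spread + abs(calib$center))
  # actually acetylated but reported trimethyl: mass favors acetyl, no loss
  ace_mass <- peptide_mass(pep, "acetyl@6")
  ace <- make_psm(peptide = pep, mods = "trimethyl@6",
                  obs_mz = mass_to_mz(ace_mass, 2) * (1 + 0.3e-6))
  sp_ace <- make_self_spectrum(ace)
  v2 <- resolve_trimethyl_acetyl(ace, sp_ace, calib)
  expect_identical(v2$verdict, "acetyl")
  expect_gt(abs(v2$error_vs_trimethyl), 15)
  # heavy peptide with both hypotheses inside the band, no loss -> ambiguous
  calib_wide <- make_calibration(seq(-4.5, 4.5, length.out = 30))
  heavy <- paste(rep("LNTEWKAFER", 4), collapse = "")
  expect_gt(peptide_mass(heavy, "trimethyl@6"),
            separability_mass_limit(mod_delta("trimethyl") -
                                      mod_delta("acetyl"), 10))
  hv <- make_psm(peptide = heavy, mods = "trimethyl@6", ppm = 0.1)
  v3 <- resolve_trimethyl_acetyl(hv, make_self_spectrum(hv), calib_wide)
  expect_identical(v3$verdict, "ambiguous")
  expect_true(v3$trimethyl_in_band && v3$acetyl_in_band)
  # verdicts are deterministic
  expect_identical(resolve_trimethyl_acetyl(tri, sp_tri, calib), v1)
})
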