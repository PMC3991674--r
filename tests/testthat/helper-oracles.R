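# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive: they re-derive expected values by enumeration rather
# than calling the code paths they check.

AA20 <- names(residue_masses())

random_peptide <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Brute-force Trypsin/P digestion: enumerate all (start, end) windows and
# keep those whose boundaries are cleavage points and whose internal
# cleavage-site count is within the allowance.
oracle_digest <- function(sequence, max_missed) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  cut_after <- c(0L, which(res %in% c("K", "R")), n)
  cut_after <- sort(unique(cut_after))
  out <- list()
  for (s in cut_after) for (e in cut_after) {
    if (e <= s) next
    internal <- sum(cut_after > s & cut_after < e)
    if (internal <= max_missed)
      out[[length(out) + 1L]] <- data.frame(
        sequence = substr(sequence, s + 1L, e),
        start = s + 1L, end = e, missed_cleavages = internal,
        stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, out)
  d <- d[order(d$start, d$end), ]
  rownames(d) <- NULL
  d
}

# Brute-force isobaric-substitution scan: try replacing each residue (except
# the methyl site) by each other residue and compare the resulting peptide
# mass with the methyl-modified mass.
oracle_substitutions <- function(sequence, site, degree, tol_ppm) {
  mod <- sprintf("%s@%d", methyl_mod_name(degree), site)
  target_mass <- peptide_mass(sequence, mod)
  tol_da <- tol_ppm * 1e-6 * target_mass
  res <- strsplit(sequence, "")[[1]]
  out <- list()
  for (pos in seq_along(res)) {
    if (pos == site) next
    for (to in setdiff(AA20, res[pos])) {
      variant <- res
      variant[pos] <- to
      m <- peptide_mass(paste(variant, collapse = ""))
      if (abs(m - target_mass) <= tol_da)
        out[[length(out) + 1L]] <- data.frame(
          position = pos, from = res[pos], to = to,
          exact = abs(m - target_mass) < 1e-6, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(position = integer(0), from = character(0),
                      to = character(0), exact = logical(0),
                      stringsAsFactors = FALSE))
  d <- do.call(rbind, out)
  d[order(d$position, d$to), ]
}

make_psm <- function(spectrum_id = "s1", run_id = "run1", peptide = "AAELK",
                     mods = "", charge = 2L, obs_mz = NULL, score = 60,
                     rank = 1L, homology_pass = TRUE, accessions = "P1",
                     is_decoy = FALSE, ppm = 0) {
  if (is.null(obs_mz))
    obs_mz <- mass_to_mz(peptide_mass(peptide, mods) * (1 + ppm * 1e-6),
                         charge)
  data.frame(spectrum_id = spectrum_id, run_id = run_id, peptide = peptide,
             mods = mods, charge = charge, obs_mz = obs_mz, score = score,
             rank = rank, homology_pass = homology_pass,
             accessions = accessions, is_decoy = is_decoy,
             stringsAsFactors = FALSE)
}

# A calibration object backed by n well-behaved unmodified PSMs whose planted
# ppm errors are known.
make_calibration <- function(errors) {
  psms <- do.call(rbind, lapply(seq_along(errors), function(i)
    make_psm(spectrum_id = sprintf("cal%03d", i), peptide = "AAELTYHIK",
             score = 80, ppm = errors[i])))
  build_calibration(psms, score_floor = 40, min_n = length(errors))
}

# Full-match spectrum for a PSM: every theoretical singly charged b/y peak.
make_self_spectrum <- function(psm, extra_mz = numeric(0)) {
  fr <- fragment_ions(psm$peptide, psm$mods, charge = 1L)
  mz <- c(fr$mz, extra_mz)
  o <- order(mz)
  list(spectrum_id = psm$spectrum_id, precursor_mz = psm$obs_mz,
       charge = psm$charge, mz = mz[o],
       intensity = rep(50, length(mz))[o])
}
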