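# Chemistry of confusable assignments: single-residue substitutions isobaric
# to a methyl mass shift (filter step 5) and trimethyl-vs-acetyl
# disambiguation by accurate precursor mass and trimethylamine neutral loss
# (filter step 6).

#' Ordered residue-substitution mass-difference table
#'
#' Mass change of every ordered single-residue substitution (380 pairs of
#' distinct standard residues).
#'
#' @return data.frame with columns \code{from}, \code{to}, \code{delta}
#'   (mass(to) - mass(from), Da).
#' @export
substitution_delta_table <- function() {
  aa <- names(residue_masses())
  g <- expand.grid(from = aa, to = aa, stringsAsFactors = FALSE)
  g <- g[g$from != g$to, , drop = FALSE]
  g$delta <- residue_masses()[g$to] - residue_masses()[g$from]
  rownames(g) <- NULL
  g
}

#' Find single-residue substitutions isobaric to a methyl assignment
#'
#' Enumerates every substitution of one residue of the peptide (excluding the
#' methylated site itself) by another standard residue whose mass change
#' matches the methyl delta within \code{tol_ppm} of the peptide mass.
#' Exact isobars (e.g. D->E for monomethyl, A->L for trimethyl) are flagged:
#' these are the ambiguities that can never be resolved by precursor mass.
#'
#' @param sequence Peptide sequence.
#' @param mods Modification string or data.frame; must carry a methyl-class
#'   modification at \code{site}.
#' @param site 1-based position of the methylated residue within the peptide.
#' @param tol_ppm Precursor mass tolerance in ppm (default 10).
#' @return data.frame with columns \code{position}, \code{from}, \code{to},
#'   \code{exact_mass_difference} (substitution delta minus methyl delta, Da),
#'   \code{exact} (TRUE when the match is exact to 1e-6 Da),
#'   \code{within_tolerance}.
#' @export
find_isobaric_substitutions <- function(sequence, mods, site, tol_ppm = 10) {
  if (is.character(mods)) mods <- parse_mods(mods)
  validate_mods(sequence, mods)
  at_site <- mods$name[mods$position == site]
  deg <- methyl_degree(at_site)
  deg <- deg[!is.na(deg)]
  if (!length(deg))
    stop("position ", site, " does not carry a methyl-class modification")
  delta <- mod_delta(methyl_mod_name(deg[1]))
  pep_mass <- peptide_mass(sequence, mods)
  tol_da <- tol_ppm * 1e-6 * pep_mass
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  tab <- substitution_delta_table()
  out <- list()
  k <- 0L
  for (pos in seq_along(res)) {
    if (pos == site) next  # in-place replacement of the methylated residue:
                           # no standard residue has mass K/R + delta exactly
    cand <- tab[tab$from == res[pos] & abs(tab$delta - delta) <= tol_da, ,
                drop = FALSE]
    if (nrow(cand)) {
      k <- k + 1L
      out[[k]] <- data.frame(
        position = pos, from = cand$from, to = cand$to,
        exact_mass_difference = cand$delta - delta,
        exact = abs(cand$delta - delta) < 1e-6,
        within_tolerance = TRUE,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!k)
    return(data.frame(position = integer(0), from = character(0),
                      to = character(0), exact_mass_difference = numeric(0),
                      exact = logical(0), within_tolerance = logical(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Peptide mass above which two isobaric hypotheses become inseparable
#'
#' Two modification hypotheses whose deltas differ by \code{delta} are
#' distinguishable at a precursor tolerance of \code{tol_ppm} only while the
#' two +/- tolerance windows do not overlap, i.e. for neutral masses below
#' \code{delta / (2 * tol_ppm * 1e-6)}.
#'
#' @param delta Absolute mass difference between the hypotheses (Da).
#' @param tol_ppm Precursor tolerance (ppm).
#' @return The separability mass limit in Da (Inf as tol_ppm -> 0).
#' @examples
#' separability_mass_limit(mod_delta("trimethyl") - mod_delta("acetyl"), 10)
#' @export
separability_mass_limit <- function(delta, tol_ppm) {
  if (delta <= 0) stop("delta must be positive")
  if (tol_ppm < 0) stop("tol_ppm must be non-negative")
  if (tol_ppm == 0) return(Inf)
  delta / (2 * tol_ppm * 1e-6)
}

#' Detect the trimethylamine neutral loss in a spectrum
#'
#' Looks for peaks consistent with loss of neutral trimethylamine (C3H9N,
#' 59.07350 Da, the "-59 Da" signature of trimethyl-lysine) from (a) the
#' precursor at its charge state and (b) any singly charged b/y fragment that
#' covers the methylated site.
#'
#' @param spectrum Spectrum list (\code{mz}, \code{intensity},
#'   \code{precursor_mz}, \code{charge}).
#' @param psm One-row PSM data.frame (or list) with \code{peptide},
#'   \code{mods}, \code{charge}, \code{obs_mz}.
#' @param site Methylated position within the peptide; if NULL, taken from the
#'   first trimethyl modification.
#' @param loss_mass Neutral-loss mass (default \code{trimethylamine_mass()}).
#' @param tol Fragment match tolerance in Da (default 0.8, the fragment-ion
#'   setting; the loss is read from MS/MS peaks, not from the precursor scan).
#' @return List with \code{detected}, \code{precursor_loss},
#'   \code{fragment_loss} and \code{matches} (data.frame of matched peaks).
#' @export
detect_neutral_loss <- function(spectrum, psm, site = NULL,
                                loss_mass = trimethylamine_mass(), tol = 0.8) {
  charge <- psm$charge
  if (is.na(charge) || charge < 1) stop("charge must be >= 1")
  mods <- parse_mods(psm$mods)
  if (is.null(site)) {
    tri <- mods$position[mods$name == "trimethyl"]
    site <- if (length(tri)) tri[1] else NA_integer_
  }
  mz <- spectrum$mz
  # a diagnostic loss peak must not itself be an ordinary b/y fragment of the
  # peptide: peaks explainable as canonical fragments carry no loss evidence
  theo_frag <- if (nchar(psm$peptide) >= 2)
    fragment_ions(psm$peptide, psm$mods, charge = 1L)$mz else numeric(0)
  matches <- list()
  hit <- function(target, label) {
    i <- which(abs(mz - target) <= tol)
    if (length(i) && length(theo_frag))
      i <- i[vapply(mz[i], function(m) all(abs(m - theo_frag) > tol),
                    logical(1))]
    if (length(i))
      data.frame(kind = label, target_mz = target, matched_mz = mz[i],
                 intensity = spectrum$intensity[i], stringsAsFactors = FALSE)
    else NULL
  }
  prec_target <- psm$obs_mz - loss_mass / charge
  matches$precursor <- hit(prec_target, "precursor_loss")
  frag_hits <- NULL
  if (!is.na(site) && nchar(psm$peptide) >= 2) {
    fr <- fragment_ions(psm$peptide, psm$mods, charge = 1L)
    covering <- fr[fr$start <= site & site <= fr$end, , drop = FALSE]
    for (j in seq_len(nrow(covering))) {
      h <- hit(covering$mz[j] - loss_mass,
               paste0("fragment_loss:", covering$ion[j]))
      if (!is.null(h)) frag_hits <- rbind(frag_hits, h)
    }
  }
  matches$fragment <- frag_hits
  all_matches <- do.call(rbind, matches)
  rownames(all_matches) <- NULL
  list(
    detected = !is.null(all_matches) && nrow(all_matches) > 0,
    precursor_loss = !is.null(matches$precursor),
    fragment_loss = !is.null(frag_hits),
    matches = if (is.null(all_matches))
      data.frame(kind = character(0), target_mz = numeric(0),
                 matched_mz = numeric(0), intensity = numeric(0),
                 stringsAsFactors = FALSE) else all_matches
  )
}

#' Build a precursor mass-error calibration distribution
#'
#' The accurate-mass comparison for trimethyl-vs-acetyl judges a candidate's
#' precursor error against the error distribution of all confident PSMs
#' (score above \code{score_floor}), summarized robustly by the median and
#' the scaled median absolute deviation.
#'
#' @param psms PSM data.frame (target PSMs are used; decoys excluded).
#' @param score_floor Minimum score for a PSM to enter the calibration
#'   (default 40, exclusive).
#' @param min_n Minimum number of calibration PSMs (default 20).
#' @return List of class \code{ppm_calibration} with \code{center} (median
#'   ppm), \code{spread} (1.4826 * MAD, ppm), \code{n}, \code{errors}.
#' @export
build_calibration <- function(psms, score_floor = 40, min_n = 20) {
  sel <- psms[psms$score > score_floor & !psms$is_decoy, , drop = FALSE]
  if (nrow(sel) < min_n)
    stop("calibration needs at least ", min_n, " PSMs with score > ",
         score_floor, " (got ", nrow(sel), ")")
  errs <- psm_ppm_errors(sel)
  structure(list(center = stats::median(errs),
                 spread = stats::mad(errs),  # already scaled by 1.4826
                 n = length(errs), errors = errs,
                 score_floor = score_floor),
            class = "ppm_calibration")
}

#' Resolve a trimethyl-vs-acetyl ambiguity for one PSM
#'
#' Computes the precursor ppm error of the PSM under both the trimethyl and
#' the acetyl hypothesis at the flagged lysine, compares each against the
#' calibration band (center +/- k * spread), and checks the spectrum for the
#' trimethylamine neutral loss. Verdict rules: \emph{trimethyl} when the mass
#' evidence favors trimethyl alone, or when the neutral loss is present and
#' acetyl is not favored alone; \emph{acetyl} when mass favors acetyl alone
#' and no loss is seen; otherwise \emph{ambiguous} (retained downstream but
#' flagged).
#'
#' @param psm One-row PSM with a trimethyl modification.
#' @param spectrum Matching spectrum, or NULL (no loss evidence).
#' @param calib \code{\link{build_calibration}} result.
#' @param k_spread Width of the acceptance band in spreads (default 3).
#' @param fragment_tol Da tolerance for the neutral-loss peak search.
#' @return List with \code{verdict} ("trimethyl", "acetyl", "ambiguous"),
#'   \code{error_vs_trimethyl}, \code{error_vs_acetyl} (ppm),
#'   \code{trimethyl_in_band}, \code{acetyl_in_band},
#'   \code{neutral_loss_detected}, \code{calibration_center},
#'   \code{calibration_spread}.
#' @export
resolve_trimethyl_acetyl <- function(psm, spectrum, calib, k_spread = 3,
                                     fragment_tol = 0.8) {
  if (!inherits(calib, "ppm_calibration"))
    stop("calib must come from build_calibration()")
  mods <- parse_mods(psm$mods)
  tri <- which(mods$name == "trimethyl")
  if (!length(tri)) stop("PSM does not carry a trimethyl hypothesis")
  site <- mods$position[tri[1]]
  mods_acetyl <- mods
  mods_acetyl$name[tri[1]] <- "acetyl"
  m_tri <- peptide_mass(psm$peptide, mods)
  m_ace <- peptide_mass(psm$peptide, mods_acetyl)
  obs <- mz_to_mass(psm$obs_mz, psm$charge)
  err_tri <- ppm_error(obs, m_tri)
  err_ace <- ppm_error(obs, m_ace)
  band <- k_spread * calib$spread
  tri_in <- abs(err_tri - calib$center) <= band
  ace_in <- abs(err_ace - calib$center) <= band
  loss <- if (!is.null(spectrum))
    detect_neutral_loss(spectrum, psm, site = site, tol = fragment_tol)$detected
  else FALSE
  verdict <- if (tri_in && !ace_in) "trimethyl"
  else if (loss && !(ace_in && !tri_in)) "trimethyl"
  else if (ace_in && !tri_in && !loss) "acetyl"
  else "ambiguous"
  list(
    verdict = verdict,
    error_vs_trimethyl = err_tri,
    error_vs_acetyl = err_ace,
    trimethyl_in_band = tri_in,
    acetyl_in_band = ace_in,
    neutral_loss_detected = loss,
    calibration_center = calib$center,
    calibration_spread = calib$spread
  )
}
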