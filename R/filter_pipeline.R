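# The six-step methylpeptide candidate filter plus methyl-specific
# target-decoy FDR estimation. Turns parsed PSMs into validated methylation
# sites:
#   1. seed selection: methyl-PSMs with score >= seed_score
#   2. spectral quality assessment (automated stand-in for manual inspection)
#   3. corroboration: lower-score methyl-PSMs hitting the same site
#   4. removal of sites supported by a single PSM
#   5. removal of sites explained entirely by exact isobaric substitutions
#   6. trimethyl-vs-acetyl disambiguation

#' Pipeline configuration
#'
#' @param seed_score Minimum score for a PSM to seed a site (default 50).
#' @param support_score_floor Minimum score for corroborating PSMs
#'   (default 20); must not exceed \code{seed_score}.
#' @param min_spectra_per_site Minimum supporting PSMs for a validated site
#'   (default 2).
#' @param calibration_score_floor Score floor for the ppm calibration
#'   population (default 40, exclusive).
#' @param calibration_min_n Minimum calibration population size (default 20).
#' @param k_spread Accurate-mass band half-width in calibration spreads
#'   (default 3).
#' @param min_matched_fraction Minimum fraction of theoretical b/y ions
#'   matched for a seed spectrum to pass quality (default 0.5).
#' @param min_site_determining Minimum matched fragments covering the
#'   methylated site (default 1).
#' @param precursor_tol_ppm Precursor tolerance (default 10 ppm).
#' @param fragment_tol Fragment tolerance (default 0.8 Da).
#' @param score_cutoff,require_rank1,require_homology Parsing-filter settings
#'   (see \code{\link{parse_config}}).
#' @param decoy_prefix Decoy accession prefix (default "rev_").
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed_score = 50, support_score_floor = 20,
                            min_spectra_per_site = 2L,
                            calibration_score_floor = 40,
                            calibration_min_n = 20L, k_spread = 3,
                            min_matched_fraction = 0.5,
                            min_site_determining = 1L,
                            precursor_tol_ppm = 10, fragment_tol = 0.8,
                            score_cutoff = 20, require_rank1 = TRUE,
                            require_homology = TRUE, decoy_prefix = "rev_") {
  if (seed_score < support_score_floor)
    stop("seed_score must be >= support_score_floor")
  if (min_spectra_per_site < 1) stop("min_spectra_per_site must be >= 1")
  structure(list(
    seed_score = seed_score, support_score_floor = support_score_floor,
    min_spectra_per_site = as.integer(min_spectra_per_site),
    calibration_score_floor = calibration_score_floor,
    calibration_min_n = as.integer(calibration_min_n), k_spread = k_spread,
    min_matched_fraction = min_matched_fraction,
    min_site_determining = as.integer(min_site_determining),
    precursor_tol_ppm = precursor_tol_ppm, fragment_tol = fragment_tol,
    score_cutoff = score_cutoff, require_rank1 = require_rank1,
    require_homology = require_homology, decoy_prefix = decoy_prefix
  ), class = "pipeline_config")
}

#' Target-decoy FDR for methyl-PSMs
#'
#' Counts methyl-PSMs at or above a score threshold by decoy status and
#' applies FDR = 2 * n_rev / (n_rev + n_real), capped at 1 (the formula can
#' exceed 1 when decoys dominate).
#'
#' @param psms Methyl-PSM data.frame with an \code{is_decoy} column.
#' @param score_threshold Score threshold (inclusive).
#' @return List of class \code{fdr_estimate} with \code{n_rev}, \code{n_real},
#'   \code{fdr}, \code{score_threshold}.
#' @export
estimate_fdr <- function(psms, score_threshold = 0) {
  sel <- psms[psms$score >= score_threshold, , drop = FALSE]
  n_rev <- sum(sel$is_decoy)
  n_real <- sum(!sel$is_decoy)
  if (n_rev + n_real == 0L)
    stop("no methyl-PSMs at or above score ", score_threshold,
         ": FDR undefined")
  structure(list(n_rev = n_rev, n_real = n_real,
                 fdr = min(1, 2 * n_rev / (n_rev + n_real)),
                 score_threshold = score_threshold),
            class = "fdr_estimate")
}

#' Automated spectral-quality assessment for a methyl-PSM
#'
#' Stand-in for expert inspection: computes the fraction of theoretical
#' singly charged b/y ions matched in the spectrum within the fragment
#' tolerance, and the number of matched fragments covering the methylated
#' site (site-determining ions). A pass requires both to meet their
#' thresholds. Alternative acceptor positions in the peptide that no matched
#' fragment can distinguish from the assigned site are reported for the
#' localization-ambiguity flag.
#'
#' @param spectrum Spectrum list; \code{spectrum_id} must match the PSM's.
#' @param psm One-row methyl-PSM.
#' @param cfg \code{\link{pipeline_config}}.
#' @param site Methylated position within the peptide (default: first methyl
#'   modification).
#' @return List with \code{pass}, \code{matched_fraction},
#'   \code{n_site_determining}, \code{undistinguished_alternatives} (peptide
#'   positions).
#' @export
assess_spectrum_quality <- function(spectrum, psm, cfg = pipeline_config(),
                                    site = NULL) {
  if (!identical(spectrum$spectrum_id, psm$spectrum_id))
    stop("spectrum id mismatch: ", spectrum$spectrum_id, " vs ",
         psm$spectrum_id)
  mods <- parse_mods(psm$mods)
  methyl <- mods[mods$name %in% c("monomethyl", "dimethyl", "trimethyl"), ,
                 drop = FALSE]
  if (is.null(site)) {
    if (!nrow(methyl)) stop("PSM carries no methyl-class modification")
    site <- methyl$position[1]
  }
  fr <- fragment_ions(psm$peptide, psm$mods, charge = 1L)
  matched <- vapply(fr$mz, function(m)
    any(abs(spectrum$mz - m) <= cfg$fragment_tol), logical(1))
  frac <- mean(matched)
  covering <- fr$start <= site & site <= fr$end
  n_sdi <- sum(matched & covering)
  # alternative acceptors: residues elsewhere in the peptide that the methyl
  # modification could legally sit on
  modname <- methyl$name[methyl$position == site][1]
  targets <- strsplit(modification_registry()[modname, "targets"], ",")[[1]]
  resv <- strsplit(psm$peptide, "", fixed = TRUE)[[1]]
  alts <- setdiff(which(resv %in% targets), site)
  undist <- integer(0)
  for (q in alts) {
    covers_one <- xor(fr$start <= site & site <= fr$end,
                      fr$start <= q & q <= fr$end)
    if (!any(matched & covers_one)) undist <- c(undist, q)
  }
  list(
    pass = frac >= cfg$min_matched_fraction &&
      n_sdi >= cfg$min_site_determining,
    matched_fraction = frac,
    n_site_determining = n_sdi,
    undistinguished_alternatives = undist
  )
}

# Map each methyl-PSM to (accession, protein position, residue) site
# attributions via the protein sequences. Returns one row per
# (PSM, methyl mod, accession).
.site_attributions <- function(psms, proteome, decoy_prefix = "rev_") {
  seq_by_acc <- stats::setNames(proteome$sequence, proteome$accession)
  out <- list(); k <- 0L
  for (i in seq_len(nrow(psms))) {
    mods <- parse_mods(psms$mods[i])
    methyl <- mods[mods$name %in% c("monomethyl", "dimethyl", "trimethyl"), ,
                   drop = FALSE]
    if (!nrow(methyl)) next
    accs <- strsplit(psms$accessions[i], ",", fixed = TRUE)[[1]]
    for (acc in accs) {
      pseq <- seq_by_acc[[acc]]
      if (is.null(pseq)) next
      start <- as.integer(regexpr(psms$peptide[i], pseq, fixed = TRUE))
      if (start < 1L) next
      for (j in seq_len(nrow(methyl))) {
        k <- k + 1L
        pos <- start + methyl$position[j] - 1L
        out[[k]] <- data.frame(
          psm_idx = i, accession = acc, position = pos,
          residue = substr(pseq, pos, pos),
          pep_site = methyl$position[j],
          degree = methyl_degree(methyl$name[j]),
          acc_is_decoy = startsWith(acc, decoy_prefix),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!k)
    return(data.frame(psm_idx = integer(0), accession = character(0),
                      position = integer(0), residue = character(0),
                      pep_site = integer(0), degree = integer(0),
                      acc_is_decoy = logical(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.site_key <- function(accession, position, residue)
  paste(accession, position, residue, sep = ":")

#' Seed methylation-site candidates and attach corroborating PSMs
#'
#' Steps 1-3 of the filter: sites are seeded only by quality-passing
#' methyl-PSMs with score >= \code{seed_score}; then every methyl-PSM with
#' score >= \code{support_score_floor} mapping to the same
#' (protein, position, residue) — across different modification patterns and
#' overlapping miscleaved peptides — is attached as support, and methyl
#' degrees are pooled.
#'
#' @param psms Parse-filtered PSM data.frame.
#' @param spectra Named list of spectra (by spectrum_id); seeds without a
#'   spectrum fail quality assessment.
#' @param proteome Proteome data.frame (targets and decoys).
#' @param cfg \code{\link{pipeline_config}}.
#' @return List of candidate records (lists) keyed by site, plus attributes
#'   \code{audit} (step counts).
#' @export
seed_and_corroborate <- function(psms, spectra, proteome,
                                 cfg = pipeline_config()) {
  attr_tab <- .site_attributions(psms, proteome, cfg$decoy_prefix)
  seed_rows <- which(psms$score[attr_tab$psm_idx] >= cfg$seed_score)
  quality <- new.env(parent = emptyenv())  # per psm_idx quality result
  q_of <- function(i) {
    key <- as.character(i)
    if (is.null(quality[[key]])) {
      sp <- spectra[[psms$spectrum_id[i]]]
      quality[[key]] <- if (is.null(sp))
        list(pass = FALSE, matched_fraction = NA_real_,
             n_site_determining = NA_integer_,
             undistinguished_alternatives = integer(0), missing_spectrum = TRUE)
      else assess_spectrum_quality(sp, psms[i, ], cfg)
    }
    quality[[key]]
  }
  seed_pass <- vapply(seed_rows, function(r) q_of(attr_tab$psm_idx[r])$pass,
                      logical(1))
  seed_tab <- attr_tab[seed_rows[seed_pass], , drop = FALSE]
  site_keys <- unique(.site_key(seed_tab$accession, seed_tab$position,
                                seed_tab$residue))
  support_ok <- psms$score[attr_tab$psm_idx] >= cfg$support_score_floor
  all_keys <- .site_key(attr_tab$accession, attr_tab$position,
                        attr_tab$residue)
  candidates <- list()
  for (key in sort(site_keys)) {
    rows <- which(all_keys == key & support_ok)
    sub <- attr_tab[rows, , drop = FALSE]
    seed_idx <- intersect(unique(sub$psm_idx),
                          unique(seed_tab$psm_idx[.site_key(
                            seed_tab$accession, seed_tab$position,
                            seed_tab$residue) == key]))
    # localization ambiguity: alternative protein positions no assessed seed
    # PSM can distinguish from the assigned site
    alt_prot <- NULL
    first <- TRUE
    for (i in seed_idx) {
      q <- q_of(i)
      if (isTRUE(q$missing_spectrum)) next
      r <- sub[sub$psm_idx == i, , drop = FALSE][1, ]
      offset <- r$position - r$pep_site
      alts <- q$undistinguished_alternatives + offset
      alt_prot <- if (first) alts else intersect(alt_prot, alts)
      first <- FALSE
    }
    if (first) alt_prot <- integer(0)
    candidates[[key]] <- list(
      key = key,
      accession = sub$accession[1],
      position = sub$position[1],
      residue = sub$residue[1],
      is_decoy = sub$acc_is_decoy[1],
      degrees = sort(unique(sub$degree)),
      psm_idx = unique(sub$psm_idx),
      seed_idx = seed_idx,
      pep_site = stats::setNames(sub$pep_site, as.character(sub$psm_idx)),
      localization_ambiguous = length(alt_prot) > 0,
      alt_positions = sort(alt_prot),
      flag_substitution = FALSE,
      flag_trimethyl_acetyl = FALSE,
      confirmed_trimethyl = FALSE,
      removed_at = NA_integer_,
      removal_reason = NA_character_
    )
  }
  attr(candidates, "audit") <- list(
    step1_seed_psms = length(unique(attr_tab$psm_idx[seed_rows])),
    step2_quality_pass = length(unique(seed_tab$psm_idx)),
    sites_seeded = length(candidates),
    step3_support_psms = length(unique(unlist(lapply(candidates,
                                                     `[[`, "psm_idx"))))
  )
  candidates
}

#' Step 4: remove sites supported by fewer than the minimum number of PSMs
#'
#' @param candidates Candidate list from \code{\link{seed_and_corroborate}}.
#' @param cfg \code{\link{pipeline_config}}.
#' @return Candidate list with under-supported sites marked removed (step 4).
#' @export
apply_min_spectra <- function(candidates, cfg = pipeline_config()) {
  for (key in names(candidates)) {
    c_ <- candidates[[key]]
    if (is.na(c_$removed_at) &&
        length(c_$psm_idx) < cfg$min_spectra_per_site) {
      c_$removed_at <- 4L
      c_$removal_reason <- "fewer supporting PSMs than min_spectra_per_site"
      candidates[[key]] <- c_
    }
  }
  candidates
}

#' Steps 5-6: isobaric-substitution and trimethyl-vs-acetyl filters
#'
#' Step 5 removes candidates whose every supporting PSM admits an exact
#' single-residue substitution isobaric to its methyl assignment (mixed
#' support survives, flagged). Step 6 routes candidates with an observed
#' trimethyl degree through \code{\link{resolve_trimethyl_acetyl}}: an acetyl
#' verdict removes the candidate, a trimethyl verdict confirms it, and an
#' unresolved ambiguity retains it with a flag. A missing spectrum for a
#' trimethyl PSM contributes no neutral-loss evidence but is not an error.
#'
#' @param candidates Candidate list.
#' @param psms The PSM table the candidates index into.
#' @param spectra Named spectrum list.
#' @param calib \code{\link{build_calibration}} result.
#' @param cfg \code{\link{pipeline_config}}.
#' @return Updated candidate list.
#' @export
apply_ambiguity_filters <- function(candidates, psms, spectra, calib,
                                    cfg = pipeline_config()) {
  for (key in names(candidates)) {
    c_ <- candidates[[key]]
    if (!is.na(c_$removed_at)) next
    # step 5: exact isobaric substitutions
    exact <- vapply(c_$psm_idx, function(i) {
      subs <- find_isobaric_substitutions(
        psms$peptide[i], psms$mods[i],
        site = c_$pep_site[[as.character(i)]],
        tol_ppm = cfg$precursor_tol_ppm)
      any(subs$exact)
    }, logical(1))
    if (all(exact)) {
      c_$removed_at <- 5L
      c_$removal_reason <- "all supporting PSMs admit an exact isobaric substitution"
      candidates[[key]] <- c_
      next
    }
    if (any(exact)) c_$flag_substitution <- TRUE
    # step 6: trimethyl vs acetyl
    if (3L %in% c_$degrees) {
      verdicts <- character(0)
      for (i in c_$psm_idx) {
        mods <- parse_mods(psms$mods[i])
        if (!"trimethyl" %in% mods$name) next
        sp <- spectra[[psms$spectrum_id[i]]]
        ev <- resolve_trimethyl_acetyl(psms[i, ], sp, calib,
                                       k_spread = cfg$k_spread,
                                       fragment_tol = cfg$fragment_tol)
        verdicts <- c(verdicts, ev$verdict)
      }
      if (length(verdicts)) {
        if (any(verdicts == "trimethyl")) {
          c_$confirmed_trimethyl <- TRUE
        } else if (any(verdicts == "acetyl")) {
          c_$removed_at <- 6L
          c_$removal_reason <- "accurate mass favors acetylation, no trimethylamine loss"
          candidates[[key]] <- c_
          next
        } else {
          c_$flag_trimethyl_acetyl <- TRUE
        }
      }
    }
    candidates[[key]] <- c_
  }
  candidates
}

# Spectral counts: methyl SC = supporting methyl-PSMs; total SC = all PSMs
# (methylated or not) whose peptide covers the site position on the same
# accession.
.spectral_counts <- function(c_, psms, proteome) {
  pseq <- proteome$sequence[match(c_$accession, proteome$accession)]
  covers <- vapply(seq_len(nrow(psms)), function(i) {
    if (!c_$accession %in% strsplit(psms$accessions[i], ",", fixed = TRUE)[[1]])
      return(FALSE)
    start <- as.integer(regexpr(psms$peptide[i], pseq, fixed = TRUE))
    start >= 1L && start <= c_$position &&
      c_$position <= start + nchar(psms$peptide[i]) - 1L
  }, logical(1))
  list(sc_methyl = length(c_$psm_idx), sc_total = sum(covers))
}

.candidates_to_table <- function(candidates, psms, proteome) {
  keep <- Filter(function(c_) is.na(c_$removed_at) && !c_$is_decoy, candidates)
  if (!length(keep))
    return(data.frame(
      accession = character(0), position = integer(0), residue = character(0),
      degrees = character(0), n_psms = integer(0), n_seed = integer(0),
      sc_methyl = integer(0), sc_total = integer(0),
      stoichiometry = numeric(0), localization_ambiguous = logical(0),
      alt_positions = character(0), flag_substitution = logical(0),
      flag_trimethyl_acetyl = logical(0), confirmed_trimethyl = logical(0),
      stringsAsFactors = FALSE))
  rows <- lapply(keep, function(c_) {
    sc <- .spectral_counts(c_, psms, proteome)
    data.frame(
      accession = c_$accession, position = c_$position, residue = c_$residue,
      degrees = paste0("me", paste(c_$degrees, collapse = "/")),
      n_psms = length(c_$psm_idx), n_seed = length(c_$seed_idx),
      sc_methyl = sc$sc_methyl, sc_total = sc$sc_total,
      stoichiometry = if (sc$sc_total > 0) sc$sc_methyl / sc$sc_total
                      else NA_real_,
      localization_ambiguous = c_$localization_ambiguous,
      alt_positions = paste(c_$alt_positions, collapse = ","),
      flag_substitution = c_$flag_substitution,
      flag_trimethyl_acetyl = c_$flag_trimethyl_acetyl,
      confirmed_trimethyl = c_$confirmed_trimethyl,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$accession, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full six-step methylation-site filter
#'
#' Composes the parsing filter, methyl-FDR estimation, seeding and
#' corroboration (steps 1-3), the minimum-spectra rule (step 4), and the
#' ambiguity filters (steps 5-6) into a validated site table with
#' spectral-count stoichiometry, plus an audit log of per-step counts.
#'
#' @param psms Raw PSM data.frame.
#' @param spectra Named spectrum list (by spectrum_id).
#' @param proteome Target-decoy proteome data.frame.
#' @param cfg \code{\link{pipeline_config}}.
#' @return List of class \code{methylsieve_result} with \code{sites}
#'   (data.frame), \code{fdr_initial}, \code{fdr_final} (NULL when no methyl
#'   PSM survives), \code{audit} (list incl. per-site removal records),
#'   \code{candidates}.
#' @export
run_pipeline <- function(psms, spectra, proteome, cfg = pipeline_config()) {
  audit <- list(n_input_psms = nrow(psms))
  pcfg <- parse_config(cfg$score_cutoff, cfg$require_rank1,
                       cfg$require_homology)
  psms <- parse_filter(psms, pcfg)
  audit$n_parse_filtered <- nrow(psms)
  methyl_mask <- is_methyl_psm(psms)
  audit$n_methyl_psms <- sum(methyl_mask)
  if (!any(methyl_mask)) stop("no methyl-PSMs after parsing filters")
  fdr_initial <- estimate_fdr(psms[methyl_mask, , drop = FALSE],
                              cfg$support_score_floor)
  calib <- build_calibration(psms, cfg$calibration_score_floor,
                             cfg$calibration_min_n)
  candidates <- seed_and_corroborate(psms, spectra, proteome, cfg)
  audit <- c(audit, attr(candidates, "audit"))
  candidates <- apply_min_spectra(candidates, cfg)
  audit$step4_sites <- sum(vapply(candidates, function(c_)
    is.na(c_$removed_at), logical(1)))
  candidates <- apply_ambiguity_filters(candidates, psms, spectra, calib, cfg)
  alive <- vapply(candidates, function(c_) is.na(c_$removed_at), logical(1))
  removed5 <- vapply(candidates, function(c_)
    identical(c_$removed_at, 5L), logical(1))
  audit$step5_sites <- sum(alive) + sum(vapply(candidates, function(c_)
    identical(c_$removed_at, 6L), logical(1)))
  audit$step6_sites <- sum(alive)
  audit$removed <- data.frame(
    site = names(candidates)[!alive],
    step = vapply(candidates[!alive], `[[`, integer(1), "removed_at"),
    reason = vapply(candidates[!alive], `[[`, character(1), "removal_reason"),
    stringsAsFactors = FALSE
  )
  rownames(audit$removed) <- NULL
  sites <- .candidates_to_table(candidates, psms, proteome)
  audit$validated_sites <- nrow(sites)
  final_psm_idx <- unique(unlist(lapply(
    Filter(function(c_) is.na(c_$removed_at), candidates), `[[`, "psm_idx")))
  fdr_final <- if (length(final_psm_idx))
    tryCatch(estimate_fdr(psms[final_psm_idx, , drop = FALSE], 0),
             error = function(e) NULL)
  else NULL
  structure(list(sites = sites, fdr_initial = fdr_initial,
                 fdr_final = fdr_final, audit = audit,
                 candidates = candidates, psms = psms),
            class = "methylsieve_result")
}

#' @export
print.methylsieve_result <- function(x, ...) {
  cat("methylsieve pipeline result\n")
  cat("  input PSMs:        ", x$audit$n_input_psms, "\n")
  cat("  methyl-PSMs:       ", x$audit$n_methyl_psms, "\n")
  cat("  initial methyl FDR:", signif(x$fdr_initial$fdr, 3), "\n")
  if (!is.null(x$fdr_final))
    cat("  final methyl FDR:  ", signif(x$fdr_final$fdr, 3), "\n")
  cat("  validated sites:   ", nrow(x$sites), "\n")
  invisible(x)
}
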