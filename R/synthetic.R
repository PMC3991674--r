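# Seeded generator of ground-truth datasets with the statistical structure
# the pipeline assumes: forward/decoy score separation, per-site methylation
# occupancy, ppm-scale precursor errors, spectra with or without the
# trimethylamine neutral loss, and the confounders the ambiguity filters must
# remove (acetyl mimics, exact-substitution mimics, single-PSM spurious
# sites). The planted truth is retained for recovery testing.

AA_ALPHABET <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N", "D", "Q",
                 "K", "E", "M", "H", "F", "R", "Y", "W")

# Flank alphabets that admit no exact isobaric substitution for the given
# methyl degree (so planted true sites survive filter step 5 by construction):
#   me1 excludes G,S,V,D,N (G->A, S->T, V->L/I, D->E, N->Q are exact +CH2)
#   me2 excludes A,C       (A->V, C->M are exact +C2H4)
#   me3 excludes A,G       (A->L/I, G->V are exact +C3H6)
# K/R are excluded from flanks to control the cleavage pattern; C and M are
# excluded to keep fixed/oxidation chemistry out of the planted peptides.
.safe_flank_alphabet <- function(degrees) {
  excl <- c("K", "R", "C", "M")
  if (1L %in% degrees) excl <- c(excl, "G", "S", "V", "D", "N")
  if (2L %in% degrees) excl <- c(excl, "A", "C")
  if (3L %in% degrees) excl <- c(excl, "A", "G")
  setdiff(AA_ALPHABET, excl)
}

#' Simulation configuration
#'
#' Defaults describe the reference scenario: 5 true methylation sites with at
#' least two supporting PSMs each, 2 single-PSM spurious sites, 1 acetyl
#' mimic and 1 exact D->E substitution mimic, forward scores Normal(65, 15)
#' truncated at 0 against decoy scores Normal(25, 8), precursor errors
#' Normal(0, 1.5) ppm, and certain emission of the trimethylamine neutral
#' loss from trimethyl spectra.
#'
#' @param seed Mandatory integer RNG seed.
#' @param n_proteins Number of target proteins (default 20).
#' @param protein_length Uniform length bounds (default c(150, 400)).
#' @param n_true_sites Planted true methylation sites (default 5).
#' @param occupancy_range Per-site occupancy bounds (default c(0.3, 1)).
#' @param psm_mean Poisson mean of site-covering PSMs per site (default 20).
#' @param forward_score_mean,forward_score_sd Forward score model
#'   (default 65, 15; truncated at 0).
#' @param decoy_score_mean,decoy_score_sd Decoy score model (default 25, 8).
#' @param ppm_bias,ppm_sd Precursor error model in ppm (default 0, 1.5).
#' @param p_neutral_loss Probability a trimethyl spectrum emits the -59 Da
#'   loss peaks (default 1).
#' @param n_spurious Single-PSM spurious sites (default 2).
#' @param n_acetyl_mimic Acetylated peptides reported under the trimethyl
#'   hypothesis (default 1).
#' @param n_substitution_mimic Monomethyl sites whose every supporting
#'   peptide admits an exact D->E substitution (default 1).
#' @param n_decoy_psms Decoy methyl-PSMs (default 40).
#' @param n_background_psms Unmodified target PSMs feeding the ppm
#'   calibration (default 80).
#' @param noise_peaks Uniform noise peaks per spectrum (default 10).
#' @param p_fragment Detection probability of each theoretical b/y fragment
#'   (default 0.9).
#' @return List of class \code{sim_config}.
#' @export
simulation_config <- function(seed, n_proteins = 20L,
                              protein_length = c(150L, 400L),
                              n_true_sites = 5L, occupancy_range = c(0.3, 1),
                              psm_mean = 20, forward_score_mean = 65,
                              forward_score_sd = 15, decoy_score_mean = 25,
                              decoy_score_sd = 8, ppm_bias = 0, ppm_sd = 1.5,
                              p_neutral_loss = 1, n_spurious = 2L,
                              n_acetyl_mimic = 1L, n_substitution_mimic = 1L,
                              n_decoy_psms = 40L, n_background_psms = 80L,
                              noise_peaks = 10L, p_fragment = 0.9) {
  if (missing(seed)) stop("a seed is mandatory")
  probs <- c(p_neutral_loss, p_fragment)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  structure(as.list(environment()), class = "sim_config")
}

.rand_seq <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                               collapse = "")

.trunc_norm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
  x
}

# Build a spectrum for a PSM: detected b/y fragments of the *actual* peptide
# chemistry, optional neutral-loss peaks, and noise that is kept out of the
# neutral-loss search windows so that loss detection reflects only the
# planted emission flag.
.make_spectrum <- function(id, actual_mods, psm, cfg, site, emit_loss) {
  fr <- fragment_ions(psm$peptide, actual_mods, charge = 1L)
  det <- stats::runif(nrow(fr)) <= cfg$p_fragment
  mz <- fr$mz[det]
  inten <- stats::runif(sum(det), 10, 100)
  loss <- trimethylamine_mass()
  covering <- fr[fr$start <= site & site <= fr$end, , drop = FALSE]
  forbidden <- c(psm$obs_mz - loss / psm$charge, covering$mz - loss)
  if (emit_loss) {
    add <- c(psm$obs_mz - loss / psm$charge,
             covering$mz[seq_len(min(2L, nrow(covering)))] - loss)
    mz <- c(mz, add)
    inten <- c(inten, stats::runif(length(add), 5, 40))
  }
  if (cfg$noise_peaks > 0) {
    lo <- 100
    hi <- max(fr$mz) + 200
    noise <- numeric(0)
    while (length(noise) < cfg$noise_peaks) {
      cand <- stats::runif(cfg$noise_peaks, lo, hi)
      ok <- vapply(cand, function(m) all(abs(m - forbidden) > 1.0), logical(1))
      noise <- c(noise, cand[ok])
    }
    noise <- noise[seq_len(cfg$noise_peaks)]
    mz <- c(mz, noise)
    inten <- c(inten, stats::runif(cfg$noise_peaks, 1, 15))
  }
  o <- order(mz)
  list(spectrum_id = id, precursor_mz = psm$obs_mz, charge = psm$charge,
       mz = mz[o], intensity = inten[o])
}

#' Simulate a ground-truth methylproteome dataset
#'
#' Builds a random target proteome with planted methylation cassettes,
#' reverses it into decoys, and emits the PSM table and MGF-style spectra the
#' pipeline consumes, together with the planted truth. Byte-identical output
#' for identical configuration (the seed is part of the configuration).
#'
#' @param cfg \code{\link{simulation_config}}.
#' @return List of class \code{sim_dataset} with \code{proteome}
#'   (targets + decoys), \code{psms}, \code{spectra} (named list),
#'   \code{truth} (list with \code{events} data.frame and \code{provenance}
#'   data.frame mapping each PSM spectrum_id to a label).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_events <- cfg$n_true_sites + cfg$n_spurious + cfg$n_acetyl_mimic +
    cfg$n_substitution_mimic
  if (n_events > cfg$n_proteins)
    stop("infeasible config: ", n_events, " planted events need at least ",
         n_events, " proteins (have ", cfg$n_proteins, ")")
  set.seed(cfg$seed)

  # --- event plan -------------------------------------------------------------
  types <- c(rep("true_methyl", cfg$n_true_sites),
             rep("spurious", cfg$n_spurious),
             rep("acetyl_mimic", cfg$n_acetyl_mimic),
             rep("substitution_mimic", cfg$n_substitution_mimic))
  plan <- vector("list", length(types))
  for (e in seq_along(types)) {
    ty <- types[e]
    if (ty == "acetyl_mimic") {
      residue <- "K"; degree <- 3L
    } else if (ty == "substitution_mimic") {
      residue <- "K"; degree <- 1L
    } else if (e == 1L) {
      residue <- "K"; degree <- 3L  # always exercise the trimethyl route
    } else {
      residue <- sample(c("K", "R"), 1, prob = c(0.8, 0.2))
      degree <- if (residue == "K") sample(1:3, 1) else sample(1:2, 1)
    }
    plan[[e]] <- list(type = ty, residue = residue, degree = degree,
                      occupancy = stats::runif(1, cfg$occupancy_range[1],
                                               cfg$occupancy_range[2]))
  }

  # --- proteome with planted cassettes ---------------------------------------
  lens <- sample(cfg$protein_length[1]:cfg$protein_length[2], cfg$n_proteins,
                 replace = TRUE)
  sequences <- vapply(lens, .rand_seq, character(1))
  accessions <- sprintf("SYN%03d", seq_len(cfg$n_proteins))
  event_protein <- sample(cfg$n_proteins, n_events)
  for (e in seq_along(plan)) {
    ev <- plan[[e]]
    alpha <- .safe_flank_alphabet(ev$degree)
    repeat {
      lf <- paste(sample(alpha, 3, replace = TRUE), collapse = "")
      rf <- paste(sample(alpha, 3, replace = TRUE), collapse = "")
      if (ev$type == "substitution_mimic")
        substr(rf, 2, 2) <- "D"  # guarantees the exact D->E ambiguity
      term <- sample(c("K", "R"), 1)
      pep <- paste0(lf, ev$residue, rf, term)
      p <- event_protein[e]
      base <- sequences[p]
      ins <- sample(20:(nchar(base) - 20), 1)
      candidate <- paste0(substr(base, 1, ins), "R", pep,
                          substr(base, ins + 1, nchar(base)))
      # cassette peptide must occur exactly once for unambiguous mapping
      if (lengths(gregexpr(pep, candidate, fixed = TRUE)) == 1L) {
        sequences[p] <- candidate
        plan[[e]]$accession <- accessions[p]
        plan[[e]]$peptide <- pep
        plan[[e]]$pep_site <- 4L
        plan[[e]]$position <- ins + 1L + 4L
        break
      }
    }
  }
  proteome <- data.frame(accession = accessions,
                         description = "synthetic protein",
                         sequence = sequences, is_decoy = FALSE,
                         stringsAsFactors = FALSE)
  proteome <- make_target_decoy(proteome)

  # --- PSMs and spectra -------------------------------------------------------
  psm_rows <- list()
  spectra <- list()
  provenance <- list()
  spec_no <- 0L
  next_id <- function() {
    spec_no <<- spec_no + 1L
    sprintf("run1.%05d", spec_no)
  }
  add_psm <- function(peptide, mods, charge, obs_mz, score, accession,
                      is_decoy, label, ppm_true = NA_real_) {
    id <- next_id()
    psm_rows[[length(psm_rows) + 1L]] <<- data.frame(
      spectrum_id = id, run_id = "run1", peptide = peptide, mods = mods,
      charge = charge, obs_mz = obs_mz, score = score, rank = 1L,
      homology_pass = TRUE, accessions = accession, is_decoy = is_decoy,
      stringsAsFactors = FALSE)
    provenance[[length(provenance) + 1L]] <<- data.frame(
      spectrum_id = id, label = label, ppm_true = ppm_true,
      stringsAsFactors = FALSE)
    id
  }
  last_eps <- NA_real_
  observed_mz <- function(mass, charge) {
    last_eps <<- stats::rnorm(1, cfg$ppm_bias, cfg$ppm_sd)
    mass_to_mz(mass, charge) * (1 + last_eps * 1e-6)
  }

  for (e in seq_along(plan)) {
    ev <- plan[[e]]
    mod_name <- methyl_mod_name(ev$degree)
    mods <- sprintf("%s@%d", mod_name, ev$pep_site)
    m_methyl <- peptide_mass(ev$peptide, mods)
    m_plain <- peptide_mass(ev$peptide)
    if (ev$type == "spurious") {
      n_methyl <- 1L
      n_plain <- max(0L, stats::rpois(1, cfg$psm_mean) - 1L)
    } else if (ev$type %in% c("acetyl_mimic", "substitution_mimic")) {
      n_methyl <- 2L
      n_plain <- max(0L, stats::rpois(1, cfg$psm_mean) - 2L)
    } else {
      n_cover <- max(3L, stats::rpois(1, cfg$psm_mean))
      n_methyl <- max(2L, stats::rbinom(1, n_cover, ev$occupancy))
      n_plain <- n_cover - n_methyl
    }
    scores <- .trunc_norm_pos(n_methyl, cfg$forward_score_mean,
                              cfg$forward_score_sd)
    # guarantee one seed-capable PSM per planted site
    if (scores[1] < 50) {
      s <- .trunc_norm_pos(1, cfg$forward_score_mean, cfg$forward_score_sd)
      while (s < 50) s <- .trunc_norm_pos(1, cfg$forward_score_mean,
                                          cfg$forward_score_sd)
      scores[1] <- s
    }
    if (ev$type %in% c("acetyl_mimic", "substitution_mimic", "spurious"))
      scores <- pmax(scores, 55)  # confounders must reach their removal step
    for (k in seq_len(n_methyl)) {
      charge <- 2L
      if (ev$type == "acetyl_mimic") {
        actual_mods <- sprintf("acetyl@%d", ev$pep_site)
        obs <- observed_mz(peptide_mass(ev$peptide, actual_mods), charge)
        emit_loss <- FALSE
      } else {
        actual_mods <- mods
        obs <- observed_mz(m_methyl, charge)
        emit_loss <- ev$degree == 3L &&
          stats::runif(1) <= cfg$p_neutral_loss
      }
      id <- add_psm(ev$peptide, mods, charge, obs, scores[k], ev$accession,
                    FALSE, ev$type, ppm_true = last_eps)
      psm <- psm_rows[[length(psm_rows)]]
      spectra[[id]] <- .make_spectrum(id, actual_mods, psm, cfg,
                                      ev$pep_site, emit_loss)
    }
    for (k in seq_len(n_plain)) {
      obs <- observed_mz(m_plain, 2L)
      add_psm(ev$peptide, "", 2L, obs,
              .trunc_norm_pos(1, cfg$forward_score_mean,
                              cfg$forward_score_sd),
              ev$accession, FALSE, paste0(ev$type, "_unmodified"),
              ppm_true = last_eps)
    }
  }

  # background unmodified PSMs (calibration population)
  target_digest <- digest_proteome(proteome[!proteome$is_decoy, ],
                                   max_missed = 0L)
  bg_pool <- target_digest[nchar(target_digest$sequence) >= 6 &
                             nchar(target_digest$sequence) <= 25, ,
                           drop = FALSE]
  bg_pick <- sample(nrow(bg_pool), cfg$n_background_psms, replace = TRUE)
  for (i in bg_pick) {
    pep <- bg_pool$sequence[i]
    obs <- observed_mz(peptide_mass(pep), 2L)
    add_psm(pep, "", 2L, obs,
            .trunc_norm_pos(1, cfg$forward_score_mean, cfg$forward_score_sd),
            bg_pool$accession[i], FALSE, "background", ppm_true = last_eps)
  }

  # decoy methyl-PSMs
  decoy_digest <- digest_proteome(proteome[proteome$is_decoy, ],
                                  max_missed = 1L)
  decoy_pool <- decoy_digest[nchar(decoy_digest$sequence) >= 6 &
                               nchar(decoy_digest$sequence) <= 25, ,
                             drop = FALSE]
  has_internal_kr <- vapply(decoy_pool$sequence, function(s) {
    inner <- substr(s, 1, nchar(s) - 1L)
    grepl("[KR]", inner)
  }, logical(1))
  decoy_pool <- decoy_pool[has_internal_kr, , drop = FALSE]
  dec_pick <- sample(nrow(decoy_pool), cfg$n_decoy_psms, replace = TRUE)
  for (i in dec_pick) {
    pep <- decoy_pool$sequence[i]
    inner <- substr(pep, 1, nchar(pep) - 1L)
    kr <- gregexpr("[KR]", inner)[[1]]
    pos <- kr[sample(length(kr), 1)]
    res <- substr(pep, pos, pos)
    degree <- if (res == "K") sample(1:3, 1) else sample(1:2, 1)
    mods <- sprintf("%s@%d", methyl_mod_name(degree), pos)
    obs <- observed_mz(peptide_mass(pep, mods), 2L)
    add_psm(pep, mods, 2L, obs,
            .trunc_norm_pos(1, cfg$decoy_score_mean, cfg$decoy_score_sd),
            decoy_pool$accession[i], TRUE, "decoy", ppm_true = last_eps)
  }

  psms <- do.call(rbind, psm_rows)
  rownames(psms) <- NULL
  events <- do.call(rbind, lapply(plan, function(ev) data.frame(
    accession = ev$accession, position = ev$position, residue = ev$residue,
    degree = ev$degree, occupancy = ev$occupancy, type = ev$type,
    peptide = ev$peptide, stringsAsFactors = FALSE)))
  structure(list(
    proteome = proteome, psms = psms, spectra = spectra,
    truth = list(events = events,
                 provenance = do.call(rbind, provenance)),
    config = cfg
  ), class = "sim_dataset")
}

#' Write a simulated dataset to disk
#'
#' Emits the standard plain-text formats the pipeline consumes: target-decoy
#' FASTA, PSM TSV, MGF, and the ground truth as TSV.
#'
#' @param ds \code{\link{simulate_dataset}} result.
#' @param outdir Output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
write_dataset <- function(ds, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(outdir, "target_decoy.fasta"),
    psms = file.path(outdir, "psms.tsv"),
    mgf = file.path(outdir, "spectra.mgf"),
    truth = file.path(outdir, "truth.tsv")
  )
  write_fasta(ds$proteome, paths[["fasta"]])
  write_psm_table(ds$psms, paths[["psms"]])
  write_mgf(ds$spectra, paths[["mgf"]])
  utils::write.table(ds$truth$events, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

#' Compare validated sites against the planted truth
#'
#' Exact set comparison on (accession, position, residue).
#'
#' @param sites Validated site data.frame (from \code{\link{run_pipeline}}).
#' @param truth Truth list from \code{\link{simulate_dataset}}.
#' @return List with \code{precision}, \code{recall}, \code{n_true},
#'   \code{n_validated}, and \code{confounders} (data.frame of non-true
#'   planted events with a \code{validated} flag).
#' @export
truth_eval <- function(sites, truth) {
  key <- function(df) paste(df$accession, df$position, df$residue, sep = ":")
  ev <- truth$events
  true_keys <- key(ev[ev$type == "true_methyl", , drop = FALSE])
  got_keys <- if (nrow(sites)) key(sites) else character(0)
  tp <- length(intersect(got_keys, true_keys))
  conf <- ev[ev$type != "true_methyl", , drop = FALSE]
  conf$validated <- key(conf) %in% got_keys
  list(
    precision = if (length(got_keys)) tp / length(got_keys) else NA_real_,
    recall = if (length(true_keys)) tp / length(true_keys) else NA_real_,
    n_true = length(true_keys),
    n_validated = length(got_keys),
    confounders = conf
  )
}
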