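# Readers/writers for PSM tables (TSV), MGF peak lists, plus the pre-pipeline
# parsing filters (score cutoff, rank-1, homology threshold) and multi-run
# compilation into peptides and non-redundant protein groups.

PSM_COLUMNS <- c("spectrum_id", "run_id", "peptide", "mods", "charge",
                 "obs_mz", "score", "rank", "homology_pass", "accessions",
                 "is_decoy")

#' An empty PSM table
#' @return Zero-row data.frame with the canonical PSM columns.
#' @export
empty_psm_table <- function() {
  data.frame(
    spectrum_id = character(0), run_id = character(0), peptide = character(0),
    mods = character(0), charge = integer(0), obs_mz = numeric(0),
    score = numeric(0), rank = integer(0), homology_pass = logical(0),
    accessions = character(0), is_decoy = logical(0),
    stringsAsFactors = FALSE
  )
}

.validate_psm_table <- function(psms) {
  missing <- setdiff(PSM_COLUMNS, names(psms))
  if (length(missing))
    stop("PSM table is missing required column(s): ",
         paste(missing, collapse = ", "))
  for (i in seq_len(nrow(psms))) {
    mods <- tryCatch(parse_mods(psms$mods[i]),
                     error = function(e) stop("row ", i, ": ", conditionMessage(e)))
    if (nrow(mods) && max(mods$position) > nchar(psms$peptide[i]))
      stop("row ", i, ": modification position exceeds peptide length")
  }
  if (any(psms$charge < 1)) stop("PSM charge must be >= 1")
  if (any(psms$rank < 1)) stop("PSM rank must be >= 1")
  if (any(!is.finite(psms$score))) stop("PSM scores must be finite")
  invisible(psms)
}

#' Read a PSM table from TSV
#'
#' Expects the canonical header: spectrum_id, run_id, peptide, mods, charge,
#' obs_mz, score, rank, homology_pass, accessions, is_decoy. Modifications are
#' serialized as \code{"name@position"} tokens joined by semicolons;
#' accessions are comma-separated.
#'
#' @param path TSV file path.
#' @return data.frame of PSMs.
#' @export
read_psm_table <- function(path) {
  psms <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  missing <- setdiff(PSM_COLUMNS, names(psms))
  if (length(missing))
    stop("PSM table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  psms <- psms[, PSM_COLUMNS]
  psms$charge <- as.integer(psms$charge)
  psms$obs_mz <- as.numeric(psms$obs_mz)
  psms$score <- as.numeric(psms$score)
  psms$rank <- as.integer(psms$rank)
  psms$homology_pass <- as.logical(psms$homology_pass)
  psms$is_decoy <- as.logical(psms$is_decoy)
  psms$mods[is.na(psms$mods)] <- ""
  .validate_psm_table(psms)
  psms
}

#' Write a PSM table to TSV
#' @param psms data.frame of PSMs.
#' @param path Output path.
#' @export
write_psm_table <- function(psms, path) {
  .validate_psm_table(psms)
  utils::write.table(psms[, PSM_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Theoretical precursor ppm error of each PSM
#'
#' Recomputes the signed precursor error of every PSM from its peptide,
#' modifications, charge and observed m/z.
#'
#' @param psms PSM data.frame.
#' @return Numeric vector of ppm errors.
#' @export
psm_ppm_errors <- function(psms) {
  vapply(seq_len(nrow(psms)), function(i) {
    theo <- peptide_mass(psms$peptide[i], psms$mods[i])
    obs <- mz_to_mass(psms$obs_mz[i], psms$charge[i])
    ppm_error(obs, theo)
  }, numeric(1))
}

#' Does a PSM carry a methyl-class modification?
#' @param psms PSM data.frame.
#' @return Logical vector.
#' @export
is_methyl_psm <- function(psms) {
  grepl("(monomethyl|dimethyl|trimethyl)@", psms$mods)
}

# --- MGF ----------------------------------------------------------------------

#' Read an MGF peak-list file
#'
#' Parses BEGIN IONS / END IONS blocks with TITLE, PEPMASS and CHARGE headers.
#'
#' @param path MGF file path.
#' @return Named list of spectra (by TITLE); each spectrum is a list with
#'   \code{spectrum_id}, \code{precursor_mz}, \code{charge}, \code{mz},
#'   \code{intensity}.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("corrupt MGF: unbalanced BEGIN IONS/END IONS in ", path)
  spectra <- vector("list", length(begins))
  ids <- character(length(begins))
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[hdr], "=", fixed = TRUE)
    keys <- vapply(kv, `[`, character(1), 1L)
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
    title <- vals[match("TITLE", keys)]
    pepmass <- as.numeric(strsplit(vals[match("PEPMASS", keys)], " ")[[1]][1])
    charge <- as.integer(sub("\\+$", "", vals[match("CHARGE", keys)]))
    if (is.na(title) || is.na(pepmass))
      stop("corrupt MGF: spectrum ", k, " missing TITLE or PEPMASS (near line ",
           begins[k], ")")
    peaks <- block[!hdr]
    peaks <- peaks[nzchar(peaks)]
    if (length(peaks)) {
      mat <- do.call(rbind, strsplit(peaks, "[ \t]+"))
      mz <- as.numeric(mat[, 1]); inten <- as.numeric(mat[, 2])
      if (anyNA(mz) || anyNA(inten))
        stop("corrupt MGF: unreadable peak line near line ", begins[k])
      o <- order(mz)
      mz <- mz[o]; inten <- inten[o]
    } else {
      mz <- numeric(0); inten <- numeric(0)
    }
    spectra[[k]] <- list(spectrum_id = title, precursor_mz = pepmass,
                         charge = charge, mz = mz, intensity = inten)
    ids[k] <- title
  }
  names(spectra) <- ids
  spectra
}

#' Write spectra to MGF
#' @param spectra Named list of spectra as returned by \code{\link{read_mgf}}.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", sp$spectrum_id),
      sprintf("PEPMASS=%.5f", sp$precursor_mz),
      sprintf("CHARGE=%d+", sp$charge),
      if (length(sp$mz)) sprintf("%.5f %.2f", sp$mz, sp$intensity),
      "END IONS"
    ), con)
  }
  invisible(path)
}

# --- parsing filters and compilation -----------------------------------------

#' Parsing-filter configuration
#'
#' Mirrors the automatic result-parsing step applied upstream of the methyl
#' filter: peptide score cutoff (inclusive), rank-1 requirement, and the
#' engine's homology threshold flag.
#'
#' @param peptide_score_cutoff Minimum retained score (default 20, inclusive).
#' @param require_rank1 Keep only rank-1 PSMs (default TRUE).
#' @param require_homology Keep only PSMs passing the homology threshold
#'   (default TRUE).
#' @return A list of class \code{parse_config}.
#' @export
parse_config <- function(peptide_score_cutoff = 20, require_rank1 = TRUE,
                         require_homology = TRUE) {
  stopifnot(is.finite(peptide_score_cutoff))
  structure(list(peptide_score_cutoff = peptide_score_cutoff,
                 require_rank1 = require_rank1,
                 require_homology = require_homology),
            class = "parse_config")
}

#' Apply the parsing filters to a PSM table
#'
#' Retains PSMs with score >= cutoff, rank 1 (if required) and a passing
#' homology flag (if required). Duplicated peptide sequences are deliberately
#' conserved; the filter is order-preserving and idempotent.
#'
#' @param psms PSM data.frame.
#' @param cfg \code{\link{parse_config}} object.
#' @return Filtered PSM data.frame.
#' @export
parse_filter <- function(psms, cfg = parse_config()) {
  keep <- psms$score >= cfg$peptide_score_cutoff
  if (cfg$require_rank1) keep <- keep & psms$rank == 1L
  if (cfg$require_homology) keep <- keep & psms$homology_pass
  out <- psms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compile per-run PSM lists and build non-redundant protein groups
#'
#' Pools PSMs from several runs (run_id preserved) and merges proteins that
#' are matched by exactly the same set of peptide sequences into one group
#' whose representative is the lexicographically smallest accession.
#'
#' @param per_run_psms List of PSM data.frames, one per run.
#' @return List with \code{psms} (pooled data.frame) and \code{groups}
#'   (data.frame with \code{representative}, \code{accessions}
#'   (comma-joined), \code{peptides} (comma-joined), \code{n_psms}).
#' @export
compile_runs <- function(per_run_psms) {
  if (!length(per_run_psms))
    return(list(psms = empty_psm_table(),
                groups = data.frame(representative = character(0),
                                    accessions = character(0),
                                    peptides = character(0),
                                    n_psms = integer(0),
                                    stringsAsFactors = FALSE)))
  psms <- do.call(rbind, per_run_psms)
  rownames(psms) <- NULL
  key <- paste(psms$run_id, psms$spectrum_id, psms$rank, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (run_id, spectrum_id, rank) across runs: ",
         key[duplicated(key)][1])
  # accession -> peptide-sequence set
  acc_pep <- new.env(parent = emptyenv())
  acc_n <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(psms))) {
    for (acc in strsplit(psms$accessions[i], ",", fixed = TRUE)[[1]]) {
      acc_pep[[acc]] <- union(acc_pep[[acc]], psms$peptide[i])
      acc_n[[acc]] <- (if (is.null(acc_n[[acc]])) 0L else acc_n[[acc]]) + 1L
    }
  }
  accs <- sort(ls(acc_pep))
  if (!length(accs))
    return(list(psms = psms,
                groups = data.frame(representative = character(0),
                                    accessions = character(0),
                                    peptides = character(0),
                                    n_psms = integer(0),
                                    stringsAsFactors = FALSE)))
  sig <- vapply(accs, function(a)
    paste(sort(acc_pep[[a]]), collapse = "\r"), character(1))
  groups <- lapply(split(accs, sig), function(members) {
    data.frame(
      representative = min(members),
      accessions = paste(sort(members), collapse = ","),
      peptides = paste(sort(acc_pep[[members[1]]]), collapse = ","),
      n_psms = acc_n[[members[1]]],
      stringsAsFactors = FALSE
    )
  })
  groups <- do.call(rbind, groups)
  groups <- groups[order(groups$representative), , drop = FALSE]
  rownames(groups) <- NULL
  list(psms = psms, groups = groups)
}
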