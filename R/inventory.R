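# Site-level inventory: stoichiometry, motif windows, the packaged curated
# methylprotein inventory, and summary counts.

CHLOROPLAST_LOCATIONS <- c("stroma", "thylakoid", "envelope")

#' Spectral-count stoichiometry
#'
#' Rough site-occupancy proxy: methylated spectral counts over all spectral
#' counts covering the site (methylated and unmodified peptides).
#'
#' @param sc_methyl Methylated spectral count.
#' @param sc_total Total spectral count covering the site.
#' @return Fraction in [0, 1]; NA when \code{sc_total} is 0.
#' @examples
#' stoichiometry(2, 45)  # the largely unmodified ATP-B Arg52 situation
#' @export
stoichiometry <- function(sc_methyl, sc_total) {
  if (any(sc_methyl < 0) || any(sc_total < 0))
    stop("spectral counts must be non-negative")
  if (any(sc_methyl > sc_total, na.rm = TRUE))
    stop("sc_methyl cannot exceed sc_total")
  ifelse(sc_total > 0, sc_methyl / sc_total, NA_real_)
}

#' Extract the +/-6 residue motif window around a site
#'
#' Returns the exact 13-mer centered on the methylated residue, padded with
#' '-' beyond the protein termini; the format consumed by sequence-logo tools.
#'
#' @param sequence Full protein sequence.
#' @param position 1-based site position; residue there must be K or R.
#' @param flank Number of residues on each side (default 6).
#' @return Character scalar of length \code{2 * flank + 1}.
#' @export
sequence_window <- function(sequence, position, flank = 6L) {
  n <- nchar(sequence)
  if (position < 1 || position > n)
    stop("position ", position, " outside sequence of length ", n)
  center <- substr(sequence, position, position)
  if (!center %in% c("K", "R"))
    stop("residue at position ", position, " is ", center, ", not K or R")
  lo <- position - flank; hi <- position + flank
  left_pad <- max(0L, 1L - lo)
  right_pad <- max(0L, hi - n)
  core <- substr(sequence, max(1L, lo), min(n, hi))
  paste0(strrep("-", left_pad), core, strrep("-", right_pad))
}

INVENTORY_COLUMNS <- c("accession", "symbol", "description", "category",
                       "location", "position", "residue", "degrees", "flags",
                       "alt_positions", "sc_methyl", "sc_total")

# md5 of the packaged inventory fixture; guards against silent edits.
INVENTORY_MD5 <- "302e02debe80ad521218de7300f560ff"

#' Load the packaged curated methylation-site inventory
#'
#' The curated site-level inventory shipped with the package: one row per
#' methylation site (a localization-ambiguous site such as "K140 or K147" is
#' one row with \code{alt_positions} filled), with curated subcellular
#' location, observed methyl degrees, and the trimethyl/acetyl status flags
#' ("c" = trimethylation confirmed by accurate mass and/or neutral loss,
#' "a" = ambiguity unresolved). Spectral counts are populated only where
#' known (the ATP-B Arg52 site, 2/45).
#'
#' @param check_md5 Verify the fixture checksum (default TRUE).
#' @return data.frame with columns accession, symbol, description, category,
#'   location, position, residue, degrees (e.g. "me1/2"), flags, alt_positions,
#'   sc_methyl, sc_total.
#' @export
load_packaged_inventory <- function(check_md5 = TRUE) {
  path <- system.file("extdata", "methylsite_inventory.tsv",
                      package = "methylsieve", mustWork = TRUE)
  if (check_md5) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, INVENTORY_MD5))
      stop("inventory fixture checksum mismatch: ", md5)
  }
  inv <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  missing <- setdiff(INVENTORY_COLUMNS, names(inv))
  if (length(missing))
    stop("inventory fixture missing column(s): ",
         paste(missing, collapse = ", "))
  inv$position <- as.integer(inv$position)
  inv$sc_methyl <- suppressWarnings(as.integer(inv$sc_methyl))
  inv$sc_total <- suppressWarnings(as.integer(inv$sc_total))
  if (!all(inv$residue %in% c("K", "R")))
    stop("inventory fixture contains a residue other than K or R")
  inv
}

#' Parse a degree string like "me1/2/3" into an integer set
#' @param degrees Character vector of degree strings.
#' @return List of integer vectors.
#' @export
parse_degrees <- function(degrees) {
  lapply(strsplit(sub("^me", "", degrees), "/", fixed = TRUE),
         as.integer)
}

#' Summary counts over a site inventory
#'
#' Deterministic counts of sites and proteins, by residue and by location,
#' plus the number of single-site proteins by residue. A
#' localization-ambiguous site and a multi-degree site each count once.
#'
#' @param records Inventory data.frame (see
#'   \code{\link{load_packaged_inventory}}).
#' @param chloroplast_only Restrict to sites whose curated location is one of
#'   stroma, thylakoid, envelope (default FALSE).
#' @return List with \code{n_sites}, \code{n_proteins}, \code{by_residue}
#'   (named integer vector), \code{by_location},
#'   \code{single_site_proteins_by_residue}.
#' @export
count_summary <- function(records, chloroplast_only = FALSE) {
  if (!"location" %in% names(records))
    records$location <- "unassigned"
  if (chloroplast_only)
    records <- records[records$location %in% CHLOROPLAST_LOCATIONS, ,
                       drop = FALSE]
  by_res <- vapply(c(K = "K", R = "R"), function(r)
    sum(records$residue == r), integer(1))
  per_protein <- table(records$accession)
  singles <- names(per_protein)[per_protein == 1L]
  single_rows <- records[records$accession %in% singles, , drop = FALSE]
  single_by_res <- vapply(c(K = "K", R = "R"), function(r)
    sum(single_rows$residue == r), integer(1))
  list(
    n_sites = nrow(records),
    n_proteins = length(unique(records$accession)),
    by_residue = by_res,
    by_location = vapply(split(records, records$location), nrow, integer(1)),
    single_site_proteins_by_residue = single_by_res
  )
}

#' Motif windows for every site of an inventory
#'
#' @param records Inventory or validated-site data.frame with
#'   \code{accession}, \code{position}, \code{residue}.
#' @param proteome Proteome data.frame with matching accessions.
#' @return data.frame with \code{accession}, \code{position}, \code{residue},
#'   \code{window} (13-mer).
#' @export
inventory_windows <- function(records, proteome) {
  seqs <- stats::setNames(proteome$sequence, proteome$accession)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    pseq <- seqs[[records$accession[i]]]
    if (is.null(pseq)) return(NULL)
    data.frame(
      accession = records$accession[i], position = records$position[i],
      residue = records$residue[i],
      window = sequence_window(pseq, records$position[i]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(accession = character(0), position = integer(0),
                      residue = character(0), window = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
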