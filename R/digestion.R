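# In-silico Trypsin/P digestion with missed cleavages and reversed-decoy
# database construction, plus FASTA IO.

#' In-silico Trypsin/P digestion
#'
#' Cleaves after every K or R, including before proline (the Trypsin/P rule),
#' and returns every contiguous union of up to \code{max_missed + 1} adjacent
#' fragments. Coordinates are 1-based inclusive on the full-length sequence;
#' the initiator methionine is not removed, so positions are directly
#' comparable to full-precursor site numbering.
#'
#' @param sequence Protein sequence (uppercase one-letter codes).
#' @param max_missed Maximum number of missed cleavages (default 3).
#' @return data.frame with columns \code{sequence}, \code{start}, \code{end},
#'   \code{missed_cleavages}, ordered by start then end.
#' @examples
#' digest("AKGR", max_missed = 1)
#' @export
digest <- function(sequence, max_missed = 3L) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("cannot digest an empty sequence")
  if (max_missed < 0) stop("max_missed must be >= 0")
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  # cleavage boundaries: after each K/R (Trypsin/P ignores a following proline)
  cut_after <- which(res %in% c("K", "R"))
  bounds <- unique(c(0L, cut_after, n))  # fragment boundaries
  nfrag <- length(bounds) - 1L
  out <- vector("list", nfrag * (max_missed + 1L))
  k <- 0L
  for (i in seq_len(nfrag)) {
    jmax <- min(nfrag, i + max_missed)
    for (j in i:jmax) {
      k <- k + 1L
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      out[[k]] <- data.frame(
        sequence = substr(sequence, s, e),
        start = s, end = e, missed_cleavages = j - i,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Digest every protein of a proteome table
#'
#' @param proteome data.frame with columns \code{accession} and
#'   \code{sequence} (as returned by \code{\link{read_fasta}}).
#' @param max_missed Maximum missed cleavages.
#' @return data.frame of digest peptides with an extra \code{accession} column.
#' @export
digest_proteome <- function(proteome, max_missed = 3L) {
  pieces <- lapply(seq_len(nrow(proteome)), function(i) {
    d <- digest(proteome$sequence[i], max_missed)
    d$accession <- proteome$accession[i]
    d
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Build a reversed-decoy protein entry
#'
#' Reverses the sequence end-to-end and prefixes the accession. A palindromic
#' sequence (identical to its own reversal) is flagged with a warning since
#' such a decoy cannot calibrate false matches.
#'
#' @param protein One-row data.frame (or list) with \code{accession},
#'   \code{description}, \code{sequence}, \code{is_decoy}.
#' @param prefix Decoy accession prefix (default "rev_").
#' @return A one-row data.frame with the decoy entry.
#' @export
reverse_decoy <- function(protein, prefix = "rev_") {
  if (isTRUE(protein$is_decoy)) stop("input entry is already a decoy")
  rev_seq <- paste(rev(strsplit(protein$sequence, "", fixed = TRUE)[[1]]),
                   collapse = "")
  if (identical(rev_seq, protein$sequence))
    warning("palindromic sequence: decoy identical to target (",
            protein$accession, ")")
  data.frame(
    accession = paste0(prefix, protein$accession),
    description = paste("reversed decoy of", protein$accession),
    sequence = rev_seq,
    is_decoy = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Build a target-decoy database
#'
#' Appends a reversed decoy for every target entry.
#'
#' @param proteome data.frame of target entries.
#' @param prefix Decoy accession prefix.
#' @return data.frame with targets followed by their decoys.
#' @export
make_target_decoy <- function(proteome, prefix = "rev_") {
  decoys <- do.call(rbind, lapply(seq_len(nrow(proteome)), function(i)
    reverse_decoy(proteome[i, ], prefix)))
  out <- rbind(proteome, decoys)
  rownames(out) <- NULL
  out
}

#' Read a protein FASTA file
#'
#' @param path FASTA file path.
#' @param decoy_prefix Accessions starting with this prefix are marked decoy.
#' @return data.frame with columns \code{accession}, \code{description},
#'   \code{sequence}, \code{is_decoy}.
#' @export
read_fasta <- function(path, decoy_prefix = "rev_") {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  acc <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  data.frame(
    accession = acc,
    description = desc,
    sequence = as.character(aa),
    is_decoy = startsWith(acc, decoy_prefix),
    stringsAsFactors = FALSE
  )
}

#' Write a protein FASTA file (60-column wrap)
#'
#' @param proteome data.frame with \code{accession}, \code{description},
#'   \code{sequence}.
#' @param path Output path.
#' @export
write_fasta <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(proteome$sequence)
  names(aa) <- ifelse(nzchar(proteome$description),
                      paste(proteome$accession, proteome$description),
                      proteome$accession)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}
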