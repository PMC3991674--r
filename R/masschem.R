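# Monoisotopic mass bookkeeping: residues, modifications, peptides, fragment
# ions, ppm errors. Everything downstream (digestion, simulation, filtering)
# computes masses through this file so that a single atomic-mass table governs
# the whole package.

# Atomic monoisotopic masses (Da). Fixed constants so results are
# bit-reproducible; no runtime dependency on an external element table.
ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

#' Proton mass used for m/z conversion
#'
#' The proton mass convention (1.00727646677 Da) used throughout for converting
#' neutral monoisotopic masses to m/z and back.
#'
#' @return Proton mass in Da.
#' @export
proton_mass <- function() 1.00727646677

.formula_mass <- function(counts) {
  sum(ATOMIC_MASS[names(counts)] * counts)
}

WATER_MASS <- .formula_mass(c(H = 2, O = 1))

# Residue (= amino acid minus water) elemental compositions.
RESIDUE_FORMULA <- list(
  G = c(C = 2,  H = 3,  N = 1, O = 1),
  A = c(C = 3,  H = 5,  N = 1, O = 1),
  S = c(C = 3,  H = 5,  N = 1, O = 2),
  P = c(C = 5,  H = 7,  N = 1, O = 1),
  V = c(C = 5,  H = 9,  N = 1, O = 1),
  T = c(C = 4,  H = 7,  N = 1, O = 2),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6,  H = 11, N = 1, O = 1),
  I = c(C = 6,  H = 11, N = 1, O = 1),
  N = c(C = 4,  H = 6,  N = 2, O = 2),
  D = c(C = 4,  H = 5,  N = 1, O = 3),
  Q = c(C = 5,  H = 8,  N = 2, O = 2),
  K = c(C = 6,  H = 12, N = 2, O = 1),
  E = c(C = 5,  H = 7,  N = 1, O = 3),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6,  H = 7,  N = 3, O = 1),
  F = c(C = 9,  H = 9,  N = 1, O = 1),
  R = c(C = 6,  H = 12, N = 4, O = 1),
  Y = c(C = 9,  H = 9,  N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

RESIDUE_MASS <- vapply(RESIDUE_FORMULA, .formula_mass, numeric(1))

#' Monoisotopic residue mass table
#'
#' Masses of the 20 standard amino-acid residues (amino acid minus water),
#' computed from the package's atomic monoisotopic mass constants.
#'
#' @return Named numeric vector, one-letter residue code to mass in Da.
#' @examples
#' residue_masses()[["K"]]  # 128.09496
#' @export
residue_masses <- function() RESIDUE_MASS

#' Monoisotopic mass of water
#' @return Mass of H2O in Da.
#' @export
water_mass <- function() WATER_MASS

#' Monoisotopic mass of trimethylamine
#'
#' Mass of the neutral-loss species C3H9N expelled during fragmentation of
#' trimethylated lysine, computed from atomic masses (nominally "-59 Da").
#'
#' @return Mass in Da (59.07350).
#' @export
trimethylamine_mass <- function() .formula_mass(c(C = 3, H = 9, N = 1))

# Modification registry. Variable set mirrors the search configuration this
# pipeline consumes (Lys me1/me2/me3, Arg me1/me2, Met ox/diox, Cys trioxidation,
# protein N-terminal acetyl) plus fixed carbamidomethyl-Cys. Lys acetyl is
# present as a competing hypothesis for the trimethyl/acetyl disambiguation
# step even though it is not a search modification.
.build_mod_registry <- function() {
  d <- function(...) .formula_mass(c(...))
  reg <- data.frame(
    name = c("monomethyl", "dimethyl", "trimethyl", "acetyl",
             "oxidation", "dioxidation", "trioxidation", "carbamidomethyl"),
    delta_mass = c(
      d(C = 1, H = 2),
      d(C = 2, H = 4),
      d(C = 3, H = 6),
      d(C = 2, H = 2, O = 1),
      d(O = 1),
      d(O = 2),
      d(O = 3),
      d(C = 2, H = 3, N = 1, O = 1)
    ),
    targets = c("K,R", "K,R", "K", "K,Nterm", "M", "M", "C", "C"),
    fixed = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  rownames(reg) <- reg$name
  reg
}

MOD_REGISTRY <- .build_mod_registry()

#' Modification registry
#'
#' The registry of post-translational modifications the pipeline knows about,
#' with monoisotopic mass deltas computed from atomic masses and permitted
#' target residues ("Nterm" marks the peptide/protein N-terminus).
#'
#' @return A data.frame with columns \code{name}, \code{delta_mass},
#'   \code{targets} (comma-separated one-letter codes), \code{fixed}.
#' @export
modification_registry <- function() MOD_REGISTRY

#' Mass delta of a named modification
#'
#' @param name Modification name present in \code{\link{modification_registry}}.
#' @return Monoisotopic mass delta in Da.
#' @examples
#' mod_delta("trimethyl")  # 42.04695
#' mod_delta("acetyl")     # 42.01056
#' @export
mod_delta <- function(name) {
  if (length(name) != 1L || is.na(name) || !name %in% MOD_REGISTRY$name)
    stop("unknown modification name: ", name)
  MOD_REGISTRY[name, "delta_mass"]
}

METHYL_MODS <- c("monomethyl", "dimethyl", "trimethyl")

#' Methyl modification name for a degree
#' @param degree Integer 1, 2 or 3.
#' @return "monomethyl", "dimethyl" or "trimethyl".
#' @export
methyl_mod_name <- function(degree) {
  if (!degree %in% 1:3) stop("methyl degree must be 1, 2 or 3")
  METHYL_MODS[degree]
}

#' Methyl degree of a modification name
#' @param name Modification name.
#' @return Integer degree (1-3) or NA if not a methyl-class modification.
#' @export
methyl_degree <- function(name) {
  m <- match(name, METHYL_MODS)
  as.integer(m)
}

# --- modification string handling ---------------------------------------------

#' Parse a serialized modification string
#'
#' Modifications on a peptide are serialized as \code{"name@position"} tokens
#' joined by semicolons; position is 1-based within the peptide, 0 denotes the
#' N-terminus. An empty string means an unmodified peptide.
#'
#' @param mods Character scalar, e.g. \code{"trimethyl@7;oxidation@3"}.
#' @return data.frame with columns \code{name} (character), \code{position}
#'   (integer), ordered by position.
#' @export
parse_mods <- function(mods) {
  if (length(mods) != 1L) stop("parse_mods expects a single string")
  if (is.na(mods) || !nzchar(mods))
    return(data.frame(name = character(0), position = integer(0),
                      stringsAsFactors = FALSE))
  toks <- strsplit(mods, ";", fixed = TRUE)[[1]]
  parts <- regmatches(toks, regexec("^([A-Za-z]+)@([0-9]+)$", toks))
  bad <- vapply(parts, length, integer(1)) != 3L
  if (any(bad))
    stop("malformed modification token: ", toks[bad][1])
  out <- data.frame(
    name = vapply(parts, `[`, character(1), 2L),
    position = as.integer(vapply(parts, `[`, character(1), 3L)),
    stringsAsFactors = FALSE
  )
  out[order(out$position), , drop = FALSE]
}

#' Serialize a modification table back to a string
#' @param mods data.frame as returned by \code{\link{parse_mods}}.
#' @return Character scalar ("" when no modifications).
#' @export
format_mods <- function(mods) {
  if (is.null(mods) || nrow(mods) == 0L) return("")
  mods <- mods[order(mods$position), , drop = FALSE]
  paste(sprintf("%s@%d", mods$name, mods$position), collapse = ";")
}

.check_peptide <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("peptide sequence must be a non-empty string")
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  unknown <- setdiff(res, names(RESIDUE_MASS))
  if (length(unknown))
    stop("unknown residue letter(s): ", paste(unknown, collapse = ", "))
  res
}

#' Validate modifications against a peptide sequence
#'
#' Checks that every modification position is within the peptide, that the
#' residue at each position is a permitted target, and that at most one
#' methyl-class modification sits on any residue.
#'
#' @param sequence Peptide sequence.
#' @param mods Modification string or parsed data.frame.
#' @return Invisibly, the parsed modification data.frame.
#' @export
validate_mods <- function(sequence, mods) {
  res <- .check_peptide(sequence)
  if (is.character(mods)) mods <- parse_mods(mods)
  if (nrow(mods) == 0L) return(invisible(mods))
  n <- length(res)
  for (i in seq_len(nrow(mods))) {
    nm <- mods$name[i]; p <- mods$position[i]
    if (!nm %in% MOD_REGISTRY$name) stop("unknown modification name: ", nm)
    if (p > n) stop("modification position ", p, " exceeds peptide length ", n)
    targets <- strsplit(MOD_REGISTRY[nm, "targets"], ",", fixed = TRUE)[[1]]
    if (p == 0L) {
      if (!"Nterm" %in% targets)
        stop("modification ", nm, " does not target the N-terminus")
    } else if (!res[p] %in% targets) {
      stop("modification ", nm, " does not target residue ", res[p],
           " at position ", p)
    }
  }
  methylpos <- mods$position[mods$name %in% METHYL_MODS]
  if (anyDuplicated(methylpos))
    stop("more than one methyl-class modification on one residue")
  invisible(mods)
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus water plus modification deltas.
#'
#' @param sequence Peptide sequence (uppercase one-letter codes).
#' @param mods Modification string (\code{"name@pos;..."}) or parsed
#'   data.frame; default unmodified.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("AK")  # 217.14264
#' @export
peptide_mass <- function(sequence, mods = "") {
  res <- .check_peptide(sequence)
  if (is.character(mods)) mods <- parse_mods(mods)
  validate_mods(sequence, mods)
  m <- sum(RESIDUE_MASS[res]) + WATER_MASS
  if (nrow(mods))
    m <- m + sum(MOD_REGISTRY[mods$name, "delta_mass"])
  unname(m)
}

#' Convert neutral mass to m/z
#' @param mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge state.
#' @return m/z in Thomson.
#' @export
mass_to_mz <- function(mass, charge) {
  if (any(charge < 1)) stop("charge must be >= 1")
  (mass + charge * proton_mass()) / charge
}

#' Convert observed m/z to neutral mass
#' @param mz Observed m/z (Th).
#' @param charge Positive integer charge state.
#' @return Neutral mass in Da.
#' @export
mz_to_mass <- function(mz, charge) {
  if (any(charge < 1)) stop("charge must be >= 1")
  mz * charge - charge * proton_mass()
}

#' Signed precursor mass error in ppm
#'
#' @param observed_mass Observed neutral mass (Da).
#' @param theoretical_mass Theoretical neutral mass (Da); must be positive.
#' @return 1e6 * (observed - theoretical) / theoretical.
#' @export
ppm_error <- function(observed_mass, theoretical_mass) {
  if (any(theoretical_mass <= 0)) stop("theoretical mass must be positive")
  1e6 * (observed_mass - theoretical_mass) / theoretical_mass
}

#' Theoretical b/y fragment ions of a modified peptide
#'
#' Singly or doubly protonated b and y ions. A modification's delta is carried
#' by every fragment that covers its residue (N-terminal modifications ride on
#' all b ions and on the full-length y ion).
#'
#' @param sequence Peptide sequence, length >= 2.
#' @param mods Modification string or data.frame.
#' @param series Character vector, subset of c("b", "y").
#' @param charge Fragment charge, 1 or 2.
#' @return data.frame with columns \code{ion} (label, e.g. "b3"),
#'   \code{series}, \code{index}, \code{start}, \code{end} (peptide positions
#'   covered), \code{mz}.
#' @export
fragment_ions <- function(sequence, mods = "", series = c("b", "y"), charge = 1L) {
  res <- .check_peptide(sequence)
  n <- length(res)
  if (n < 2L) stop("peptide must have at least 2 residues")
  if (!charge %in% 1:2) stop("fragment charge must be 1 or 2")
  series <- match.arg(series, c("b", "y"), several.ok = TRUE)
  if (is.character(mods)) mods <- parse_mods(mods)
  validate_mods(sequence, mods)
  delta_at <- numeric(n + 1L)  # index 1 = N-terminus (pos 0), 1+p = residue p
  if (nrow(mods)) {
    for (i in seq_len(nrow(mods)))
      delta_at[mods$position[i] + 1L] <-
        delta_at[mods$position[i] + 1L] + MOD_REGISTRY[mods$name[i], "delta_mass"]
  }
  cum_res <- cumsum(RESIDUE_MASS[res])
  cum_mod <- cumsum(delta_at)  # cum_mod[1+p] = mods on N-term..p
  out <- list()
  if ("b" %in% series) {
    i <- seq_len(n - 1L)
    neutral <- cum_res[i] + cum_mod[i + 1L]  # b_i neutral = prefix residues+mods
    out$b <- data.frame(
      ion = paste0("b", i), series = "b", index = i,
      start = 1L, end = i,
      mz = (neutral + charge * proton_mass()) / charge,
      stringsAsFactors = FALSE
    )
  }
  if ("y" %in% series) {
    i <- seq_len(n - 1L)
    suffix_res <- cum_res[n] - cum_res[n - i]
    suffix_mod <- cum_mod[n + 1L] - cum_mod[n - i + 1L]
    neutral <- suffix_res + suffix_mod + WATER_MASS
    out$y <- data.frame(
      ion = paste0("y", i), series = "y", index = i,
      start = n - i + 1L, end = n,
      mz = (neutral + charge * proton_mass()) / charge,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
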