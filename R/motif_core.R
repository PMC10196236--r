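# Pocket-position maps for the two MHC classes. Positions are 1-based
# within the 9mer (class I) or the 15mer (class II); the class II core
# 9mer occupies 15mer positions 4-12 and core pocket p of the 15mer is
# 15mer position p + 3.
TCEM_I_POSITIONS <- 4:8                     # p4-p8 of the 9mer
GEM_I_POSITIONS <- c(1L, 2L, 3L, 9L)        # anchor tetramer
TCEM_II_POSITIONS_15 <- c(5L, 6L, 8L, 10L, 11L)  # = core p2,p3,p5,p7,p8
GEM_II_POSITIONS_15 <- c(4L, 7L, 9L, 12L)        # = core p1,p4,p6,p9
TCEM_II_CORE_POCKETS <- c(2L, 3L, 5L, 7L, 8L)

#' Construct a protein record
#'
#' @param protein_id Identifier, unique within a dataset.
#' @param sequence Residue string; canonical letters plus ambiguity codes.
#' @param is_mutant Logical flag.
#' @param mutation Optional [mutation()] that produced a mutant record.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(protein_id, sequence, is_mutant = FALSE, mutation = NULL) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) < 1L) stop("sequence must have length >= 1", call. = FALSE)
  structure(list(protein_id = protein_id, sequence = sequence,
                 is_mutant = isTRUE(is_mutant), mutation = mutation),
            class = "protein_record")
}

#' Construct a missense mutation
#'
#' Single amino-acid substitutions only: both residues must be canonical
#' and must differ.
#'
#' @param case_id Case identifier.
#' @param protein_id Protein carrying the mutation.
#' @param position 1-based residue index.
#' @param ref_aa,alt_aa Single reference/alternate residues.
#' @return An object of class `mutation`.
#' @export
mutation <- function(case_id, protein_id, position, ref_aa, alt_aa) {
  position <- as.integer(position)
  stopifnot(length(position) == 1L, position >= 1L)
  if (!ref_aa %in% aa_alphabet() || !alt_aa %in% aa_alphabet())
    stop("ref_aa and alt_aa must be canonical residues", call. = FALSE)
  if (ref_aa == alt_aa)
    stop("ref_aa and alt_aa must differ (missense only)", call. = FALSE)
  structure(list(case_id = as.character(case_id),
                 protein_id = as.character(protein_id),
                 position = position, ref_aa = ref_aa, alt_aa = alt_aa),
            class = "mutation")
}

#' Slide clean peptide windows over a protein
#'
#' Breaks the sequence into successive windows displaced by one residue.
#' Windows containing any non-canonical letter (X, U, B, Z, J, O, `*`, or
#' anything else outside the 20-letter alphabet) are dropped, as are
#' terminal fragments shorter than the window width.
#'
#' @param protein A [protein_record()].
#' @param width Window width, 9 (MHC I) or 15 (MHC II).
#' @return A data.frame with columns `protein_id`, `start` (1-based),
#'   `width`, `peptide`, one row per clean window in ascending start order.
#' @export
#' @examples
#' p <- protein_record("p1", "ACDEFGHIKLMNPQ")
#' window_peptides(p, 9)
window_peptides <- function(protein, width) {
  stopifnot(inherits(protein, "protein_record"))
  width <- as.integer(width)
  if (!width %in% c(9L, 15L)) stop("width must be 9 or 15", call. = FALSE)
  L <- nchar(protein$sequence)
  empty <- data.frame(protein_id = character(), start = integer(),
                      width = integer(), peptide = character(),
                      stringsAsFactors = FALSE)
  if (L < width) return(empty)
  starts <- seq_len(L - width + 1L)
  codes <- aa_codes(protein$sequence)
  # A window is clean iff no NA code falls inside it; cumulative NA
  # counts give an O(L) check over all starts.
  bad <- cumsum(c(0L, is.na(codes)))
  clean <- (bad[starts + width] - bad[starts]) == 0L
  starts <- starts[clean]
  if (length(starts) == 0L) return(empty)
  data.frame(protein_id = protein$protein_id, start = starts, width = width,
             peptide = substring(protein$sequence, starts, starts + width - 1L),
             stringsAsFactors = FALSE)
}

#' Extract the class I T cell exposed motif
#'
#' The TCEM I pentamer is positions p4-p8 of a 9mer bound in MHC I, the
#' residues whose side chains face the T cell receptor.
#'
#' @param nine_mer Unambiguous 9-residue string.
#' @return The 5-residue TCEM pentamer.
#' @export
#' @examples
#' extract_tcem_i("ACDEFGHIK")  # "EFGHI"
extract_tcem_i <- function(nine_mer) {
  assert_peptide(nine_mer, 9L, "nine_mer")
  substring(nine_mer, 4L, 8L)
}

#' Extract the class II T cell exposed motif
#'
#' The TCEM II is the discontinuous pentamer at 15mer positions
#' 5, 6, 8, 10, 11, i.e. p2, p3, p5, p7, p8 of the central 9mer that
#' starts at 15mer position 4.
#'
#' @param fifteen_mer Unambiguous 15-residue string.
#' @return The 5-residue TCEM pentamer.
#' @export
#' @examples
#' extract_tcem_ii("ACDEFGHIKLMNPQR")  # "FGILM"
extract_tcem_ii <- function(fifteen_mer) {
  assert_peptide(fifteen_mer, 15L, "fifteen_mer")
  paste(strsplit(fifteen_mer, "", fixed = TRUE)[[1]][TCEM_II_POSITIONS_15],
        collapse = "")
}

#' Extract the class I groove exposed (anchor) motif
#'
#' The GEM I tetramer is positions p1, p2, p3, p9 of the 9mer: the anchor
#' residues buried in the MHC groove and hidden from the TCR.
#'
#' @param nine_mer Unambiguous 9-residue string.
#' @return The 4-residue GEM tetramer.
#' @export
extract_gem_i <- function(nine_mer) {
  assert_peptide(nine_mer, 9L, "nine_mer")
  paste(strsplit(nine_mer, "", fixed = TRUE)[[1]][GEM_I_POSITIONS], collapse = "")
}

#' Extract the class II groove exposed (anchor) motif
#'
#' The GEM II tetramer is taken at 15mer positions 4, 7, 9, 12
#' (core p1, p4, p6, p9), the anchor complement of the TCEM II positions.
#'
#' @param fifteen_mer Unambiguous 15-residue string.
#' @return The 4-residue GEM tetramer.
#' @export
extract_gem_ii <- function(fifteen_mer) {
  assert_peptide(fifteen_mer, 15L, "fifteen_mer")
  paste(strsplit(fifteen_mer, "", fixed = TRUE)[[1]][GEM_II_POSITIONS_15], collapse = "")
}

#' Apply and verify a missense mutation
#'
#' Substitutes the alternate residue at the mutation position after
#' verifying that the reference residue matches the sequence; mismatches
#' (for example isoform disagreements) raise an error naming the protein
#' and position so callers can report and skip them.
#'
#' @param protein A wildtype [protein_record()].
#' @param mut A [mutation()] on that protein.
#' @return The mutant `protein_record` (with `is_mutant = TRUE`).
#' @export
apply_mutation <- function(protein, mut) {
  stopifnot(inherits(protein, "protein_record"), inherits(mut, "mutation"))
  if (protein$protein_id != mut$protein_id)
    stop("mutation protein_id '", mut$protein_id, "' does not match protein '",
         protein$protein_id, "'", call. = FALSE)
  L <- nchar(protein$sequence)
  if (mut$position > L)
    stop("mutation position ", mut$position, " beyond protein ",
         protein$protein_id, " length ", L, call. = FALSE)
  found <- substring(protein$sequence, mut$position, mut$position)
  if (found != mut$ref_aa) {
    cond <- simpleError(sprintf(
      "mutation verification failed for %s position %d: expected %s, found %s",
      protein$protein_id, mut$position, mut$ref_aa, found))
    class(cond) <- c("tcemscan_verification_error", class(cond))
    stop(cond)
  }
  seq <- protein$sequence
  substring(seq, mut$position, mut$position) <- mut$alt_aa
  protein_record(protein$protein_id, seq, is_mutant = TRUE, mutation = mut)
}

#' Mutant-relative window offset
#'
#' Offset of a window start relative to the mutation position (mutant
#' position set at zero), used to align per-window profiles across
#' mutations.
#'
#' @param window One-row data.frame as produced by [window_peptides()].
#' @param mut A [mutation()].
#' @return Integer offset `start - position`.
#' @export
mutant_relative_index <- function(window, mut) {
  stopifnot(inherits(mut, "mutation"))
  if (!identical(unique(window$protein_id), mut$protein_id))
    stop("window and mutation refer to different proteins", call. = FALSE)
  as.integer(window$start - mut$position)
}

#' Enumerate the binding registers of a mutant residue
#'
#' Lists every clean window of the given width that contains the mutated
#' residue, together with the pocket position the register assigns to it,
#' whether that pocket is T-cell exposed, and the TCEM/GEM motifs of the
#' window. An interior mutation (at least `width - 1` residues from both
#' termini) has exactly 9 registers at width 9 and 15 at width 15, of
#' which 5 expose the mutant in each class.
#'
#' For width 15 the pocket refers to the core 9mer (15mer positions
#' 4-12); a mutant in the 15mer flanks (positions 1-3 or 13-15) has
#' `mutant_pocket = NA` ("outside core") and is never exposed.
#'
#' @param protein The verified mutant [protein_record()].
#' @param mut The [mutation()] it carries.
#' @param width 9 or 15.
#' @return A data.frame with columns `protein_id`, `start`, `width`,
#'   `peptide`, `offset`, `mutant_pocket` (integer, NA = outside core),
#'   `exposed`, `tcem`, `gem`.
#' @export
enumerate_mutant_registers <- function(protein, mut, width) {
  stopifnot(inherits(protein, "protein_record"), inherits(mut, "mutation"))
  if (!isTRUE(protein$is_mutant))
    stop("protein must be the verified mutant (is_mutant = TRUE)", call. = FALSE)
  if (substring(protein$sequence, mut$position, mut$position) != mut$alt_aa)
    stop("mutant residue not found at mutation position", call. = FALSE)
  width <- as.integer(width)
  win <- window_peptides(protein, width)
  keep <- win$start <= mut$position & win$start + width - 1L >= mut$position
  win <- win[keep, , drop = FALSE]
  if (nrow(win) == 0L) {
    win$offset <- integer(); win$mutant_pocket <- integer()
    win$exposed <- logical(); win$tcem <- character(); win$gem <- character()
    return(win)
  }
  pos_in_window <- mut$position - win$start + 1L
  if (width == 9L) {
    pocket <- pos_in_window
    exposed <- pocket %in% TCEM_I_POSITIONS
    win$tcem <- vapply(win$peptide, extract_tcem_i, character(1), USE.NAMES = FALSE)
    win$gem <- vapply(win$peptide, extract_gem_i, character(1), USE.NAMES = FALSE)
  } else {
    pocket <- ifelse(pos_in_window >= 4L & pos_in_window <= 12L,
                     pos_in_window - 3L, NA_integer_)
    exposed <- !is.na(pocket) & pocket %in% TCEM_II_CORE_POCKETS
    win$tcem <- vapply(win$peptide, extract_tcem_ii, character(1), USE.NAMES = FALSE)
    win$gem <- vapply(win$peptide, extract_gem_ii, character(1), USE.NAMES = FALSE)
  }
  win$offset <- as.integer(win$start - mut$position)
  win$mutant_pocket <- as.integer(pocket)
  win$exposed <- exposed
  win[, c("protein_id", "start", "width", "peptide", "offset",
          "mutant_pocket", "exposed", "tcem", "gem")]
}
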