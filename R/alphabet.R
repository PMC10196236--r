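#' Canonical amino-acid alphabet
#'
#' The 20 canonical residues in the fixed order used for pentamer key
#' encoding (A = 0 ... Y = 19, alphabetical one-letter codes).
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Letters that disqualify a window: ambiguity codes, rare non-canonical
# residues, and the stop symbol. Any character outside the canonical 20
# is treated the same way, so this set is informational.
AMBIGUITY_LETTERS <- c("X", "U", "B", "Z", "J", "O", "*")

#' Split a sequence into residue codes
#'
#' Maps a residue string to 0-based integer codes over the canonical
#' alphabet; non-canonical letters (ambiguity codes, stop) become NA.
#'
#' @param sequence Residue string.
#' @return Integer vector, one element per residue; NA marks a
#'   non-canonical letter.
#' @keywords internal
aa_codes <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  match(chars, aa_alphabet()) - 1L
}

#' @keywords internal
is_valid_peptide <- function(peptide) {
  nzchar(peptide) & !grepl(sprintf("[^%s]", paste(aa_alphabet(), collapse = "")), peptide)
}

#' @keywords internal
assert_peptide <- function(peptide, width = NULL, what = "peptide") {
  if (!is.character(peptide) || length(peptide) != 1L)
    stop(what, " must be a single string", call. = FALSE)
  if (!is.null(width) && nchar(peptide) != width)
    stop(what, " must have length ", width, ", got ", nchar(peptide), call. = FALSE)
  if (!is_valid_peptide(peptide))
    stop(what, " contains non-canonical letters: ", peptide, call. = FALSE)
  invisible(peptide)
}
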