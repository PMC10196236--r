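PENTAMER_SPACE <- 20L^5L  # 3,200,000 possible pentamers

#' Encode pentamers as base-20 integer keys
#'
#' Keys are 0-based: `A=0 ... Y=19` per [aa_alphabet()], most significant
#' digit first, so key order equals lexicographic pentamer order.
#'
#' @param pentamer Character vector of 5-residue strings.
#' @return Integer keys in `0 .. 20^5 - 1`.
#' @export
pentamer_index <- function(pentamer) {
  if (any(nchar(pentamer) != 5L))
    stop("pentamers must have length 5", call. = FALSE)
  chars <- matrix(unlist(strsplit(pentamer, "", fixed = TRUE)), nrow = 5L)
  codes <- matrix(match(chars, aa_alphabet()) - 1L, nrow = 5L)
  if (anyNA(codes))
    stop("pentamer contains non-canonical letters", call. = FALSE)
  as.integer(colSums(codes * c(160000L, 8000L, 400L, 20L, 1L)))
}

#' Decode base-20 integer keys to pentamers
#'
#' @param index Integer keys in `0 .. 20^5 - 1`.
#' @return Character vector of pentamers.
#' @export
pentamer_from_index <- function(index) {
  stopifnot(all(index >= 0L), all(index < PENTAMER_SPACE))
  alpha <- aa_alphabet()
  out <- character(length(index))
  rem <- as.integer(index)
  digits <- matrix("", nrow = 5L, ncol = length(index))
  for (p in 5:1) {
    digits[p, ] <- alpha[rem %% 20L + 1L]
    rem <- rem %/% 20L
  }
  apply(digits, 2L, paste, collapse = "")
}

# Vectorized TCEM pentamer keys for all clean windows of one protein.
# Returns integer keys; ambiguous windows are dropped.
protein_tcem_keys <- function(sequence, motif_class) {
  codes <- aa_codes(sequence)
  L <- length(codes)
  width <- if (motif_class == "I") 9L else 15L
  if (L < width) return(integer())
  starts <- seq_len(L - width + 1L)
  bad <- cumsum(c(0L, is.na(codes)))
  starts <- starts[(bad[starts + width] - bad[starts]) == 0L]
  if (length(starts) == 0L) return(integer())
  offs <- if (motif_class == "I") 3:7 else c(4L, 5L, 7L, 9L, 10L)
  w <- c(160000L, 8000L, 400L, 20L, 1L)
  key <- integer(length(starts))
  for (j in 1:5) key <- key + codes[starts + offs[j]] * w[j]
  key
}

#' Build a pentamer frequency table
#'
#' Tallies the TCEM pentamer of every clean window across a proteome into
#' a table over the complete `20^5` key space (zeros included). Class I
#' tallies the p4-p8 pentamer of 9mer windows; class II the discontinuous
#' pentamer of 15mer windows. This is the hPPF/giPPF construction: the
#' count for a pentamer is the number of reference windows whose
#' T-cell-exposed positions spell it.
#'
#' @param proteome List of [protein_record()]s with unique ids.
#' @param motif_class `"I"` or `"II"`.
#' @param reference_name Label stored in the table.
#' @return An object of class `pentamer_table` with fields `motif_class`,
#'   `reference_name`, `counts` (integer vector of length 3,200,000
#'   indexed by key + 1), `n_windows`, `metadata`.
#' @export
build_ppf <- function(proteome, motif_class = c("I", "II"),
                      reference_name = "reference") {
  motif_class <- match.arg(motif_class)
  if (length(proteome) == 0L) stop("proteome is empty", call. = FALSE)
  ids <- vapply(proteome, function(p) p$protein_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate protein_id in proteome: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  keys <- unlist(lapply(proteome, function(p)
    protein_tcem_keys(p$sequence, motif_class)), use.names = FALSE)
  n_windows <- length(keys)
  counts <- tabulate(keys + 1L, nbins = PENTAMER_SPACE)
  structure(list(motif_class = motif_class, reference_name = reference_name,
                 counts = counts, n_windows = n_windows,
                 metadata = list(n_proteins = length(proteome),
                                 built = format(Sys.time(), "%Y-%m-%d"))),
            class = "pentamer_table")
}

#' @export
print.pentamer_table <- function(x, ...) {
  nz <- sum(x$counts > 0L)
  cat(sprintf("pentamer_table [%s] class %s: %d windows, %d/%d pentamers observed\n",
              x$reference_name, x$motif_class, x$n_windows, nz, PENTAMER_SPACE))
  invisible(x)
}

#' Look up pentamer counts
#'
#' Every possible pentamer is a key, so a motif absent from the reference
#' returns 0, never a missing-key failure.
#'
#' @param table A `pentamer_table`.
#' @param pentamer Character vector of 5-residue strings.
#' @return Integer counts.
#' @export
lookup <- function(table, pentamer) {
  stopifnot(inherits(table, "pentamer_table"))
  table$counts[pentamer_index(pentamer) + 1L]
}

#' Classify a pentamer frequency count
#'
#' @param count Non-negative integer vector.
#' @return Factor with levels `absent` (0), `singleton` (1),
#'   `doubleton` (2), `3+`.
#' @export
frequency_class <- function(count) {
  if (any(count < 0)) stop("counts must be non-negative", call. = FALSE)
  cls <- ifelse(count == 0, "absent",
         ifelse(count == 1, "singleton",
         ifelse(count == 2, "doubleton", "3+")))
  factor(cls, levels = c("absent", "singleton", "doubleton", "3+"))
}

#' Persist a pentamer table
#'
#' Writes a one-line JSON metadata header followed by a TSV of
#' pentamer/count pairs in lexicographic order; zero counts are omitted
#' on disk and restored on load. The header records an MD5 digest of the
#' body so truncation or edits are detected at load time.
#'
#' @param table A `pentamer_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_ppf <- function(table, path) {
  stopifnot(inherits(table, "pentamer_table"))
  nz <- which(table$counts > 0L)
  body <- if (length(nz))
    paste(pentamer_from_index(nz - 1L), table$counts[nz], sep = "\t")
  else character()
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(body, tmp)
  digest <- unname(tools::md5sum(tmp))
  header <- jsonlite::toJSON(list(
    format = "tcemscan-ppf", version = 1L,
    motif_class = table$motif_class, reference_name = table$reference_name,
    n_windows = table$n_windows, n_nonzero = length(nz),
    body_md5 = digest, metadata = table$metadata), auto_unbox = TRUE)
  writeLines(c(as.character(header), body), path)
  invisible(path)
}

#' Load a persisted pentamer table
#'
#' @param path File written by [save_ppf()].
#' @return The restored `pentamer_table`.
#' @export
load_ppf <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty PPF file: ", path, call. = FALSE)
  header <- tryCatch(jsonlite::fromJSON(lines[1L]),
                     error = function(e) NULL)
  if (is.null(header) || !identical(header$format, "tcemscan-ppf") ||
      !identical(as.integer(header$version), 1L))
    stop("unrecognized PPF file header in ", path, call. = FALSE)
  body <- lines[-1L]
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(body, tmp)
  if (!identical(unname(tools::md5sum(tmp)), header$body_md5))
    stop("PPF file integrity check failed (digest mismatch): ", path,
         call. = FALSE)
  if (length(body) != header$n_nonzero)
    stop("PPF file truncated: expected ", header$n_nonzero, " rows, found ",
         length(body), call. = FALSE)
  counts <- integer(PENTAMER_SPACE)
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    pent <- vapply(parts, `[[`, character(1), 1L)
    val <- as.integer(vapply(parts, `[[`, character(1), 2L))
    counts[pentamer_index(pent) + 1L] <- val
  }
  structure(list(motif_class = header$motif_class,
                 reference_name = header$reference_name,
                 counts = counts, n_windows = as.integer(header$n_windows),
                 metadata = header$metadata),
            class = "pentamer_table")
}
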