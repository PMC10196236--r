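#' Read a proteome from FASTA
#'
#' Protein ids are the first whitespace-delimited token of each header;
#' duplicate ids are an error (isoform selection is the data supplier's
#' job -- one sequence per protein).
#'
#' @param path FASTA file.
#' @return List of [protein_record()]s.
#' @export
read_proteome_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate protein ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  lapply(seq_along(seqs), function(i)
    protein_record(ids[i], as.character(seqs[[i]])))
}

#' Write a proteome to FASTA
#'
#' @param proteome List of [protein_record()]s.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  seqs <- Biostrings::AAStringSet(vapply(proteome, `[[`, character(1),
                                         "sequence"))
  names(seqs) <- vapply(proteome, `[[`, character(1), "protein_id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a missense mutation table
#'
#' Tab-separated, header required, columns `case_id`, `protein_id`,
#' `position` (1-based), `ref_aa`, `alt_aa`. Rows that duplicate the
#' same amino-acid change -- identical `(case_id, protein_id, position,
#' alt_aa)`, as arises from different codon mutations -- are dropped.
#'
#' @param path TSV file.
#' @return Data frame of mutations.
#' @export
read_mutations_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("case_id", "protein_id", "position", "ref_aa", "alt_aa")
  if (!all(req %in% names(d)))
    stop("mutation table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  d$position <- as.integer(d$position)
  d[!duplicated(d[, c("case_id", "protein_id", "position", "alt_aa")]), req]
}

#' Write a mutation table
#' @param mutations Data frame of mutations.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_mutations_tsv <- function(mutations, path) {
  utils::write.table(mutations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a genotype table
#'
#' Tab-separated with columns `case_id`, `A1`, `A2`, `B1`, `B2`, `C1`,
#' `C2`, `DRB1_1`, `DRB1_2`. Allele names are taken verbatim.
#'
#' @param path TSV file.
#' @return Data frame of genotypes.
#' @export
read_genotypes_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("case_id", CLASS_I_SLOTS, CLASS_II_SLOTS)
  if (!all(req %in% names(d)))
    stop("genotype table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  d[, req]
}

#' Write a genotype table
#' @param genotypes Data frame of genotypes.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  utils::write.table(genotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a peptide-ic50 training table
#'
#' Tab-separated with columns `allele`, `peptide`, `ic50_nM`.
#'
#' @param path TSV file.
#' @return Data frame of training examples.
#' @export
read_training_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("allele", "peptide", "ic50_nM")
  if (!all(req %in% names(d)))
    stop("training table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  d$ic50_nM <- as.numeric(d$ic50_nM)
  if (any(!is.finite(d$ic50_nM)) || any(d$ic50_nM <= 0))
    stop("ic50_nM must be positive and finite", call. = FALSE)
  d[, req]
}
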