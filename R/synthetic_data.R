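#' Residue composition presets
#'
#' `"human"` approximates the bulk amino-acid composition of the human
#' proteome, in which tryptophan, cysteine, methionine and histidine are
#' the rarest residues -- the property that makes mutations toward those
#' residues generate rare T cell exposed pentamers. `"uniform"` gives
#' each residue probability 1/20.
#'
#' @param name `"human"` or `"uniform"`, or a named numeric vector of
#'   probabilities over [aa_alphabet()] (normalized internally).
#' @return Named probability vector over the 20 canonical residues.
#' @export
residue_composition <- function(name = "human") {
  if (is.numeric(name)) {
    if (!all(aa_alphabet() %in% names(name)))
      stop("composition must name all 20 residues", call. = FALSE)
    p <- name[aa_alphabet()]
  } else if (identical(name, "uniform")) {
    p <- stats::setNames(rep(1, 20), aa_alphabet())
  } else if (identical(name, "human")) {
    p <- c(A = 0.070, C = 0.023, D = 0.047, E = 0.071, F = 0.037, G = 0.066,
           H = 0.026, I = 0.044, K = 0.057, L = 0.100, M = 0.021, N = 0.036,
           P = 0.063, Q = 0.048, R = 0.056, S = 0.083, T = 0.053, V = 0.060,
           W = 0.012, Y = 0.027)[aa_alphabet()]
  } else stop("unknown composition preset: ", name, call. = FALSE)
  if (any(p < 0) || sum(p) <= 0) stop("invalid composition", call. = FALSE)
  p / sum(p)
}

#' Generate a synthetic proteome
#'
#' Draws independent residues from the given composition; lengths are
#' uniform on `[min_length, max_length]`. Reproducible given `seed`.
#'
#' @param n_proteins Number of proteins.
#' @param min_length,max_length Protein length range (defaults 60-300;
#'   both at least 9).
#' @param composition Passed to [residue_composition()].
#' @param seed Integer RNG seed.
#' @param id_prefix Prefix for protein ids.
#' @return List of [protein_record()]s.
#' @export
gen_proteome <- function(n_proteins, min_length = 60L, max_length = 300L,
                         composition = "human", seed = 1L,
                         id_prefix = "prot") {
  if (n_proteins < 1L) stop("n_proteins must be >= 1", call. = FALSE)
  if (min_length < 9L || max_length < min_length)
    stop("need 9 <= min_length <= max_length", call. = FALSE)
  p <- residue_composition(composition)
  set.seed(as.integer(seed))
  lens <- if (min_length == max_length) rep(min_length, n_proteins) else
    sample(min_length:max_length, n_proteins, replace = TRUE)
  lapply(seq_len(n_proteins), function(i) {
    protein_record(sprintf("%s%05d", id_prefix, i),
                   paste(sample(aa_alphabet(), lens[i], replace = TRUE,
                                prob = p), collapse = ""))
  })
}

#' Generate a synthetic microbiome reference
#'
#' Emulates a gastrointestinal-microbiome reference roughly `scale`
#' times larger (in window count) than a paired proteome of
#' `n_proteins` proteins, with a residue composition that overlaps the
#' human-like composition by `overlap` (the remainder is uniform), so
#' its pentamer population overlaps but differs from the human one.
#'
#' @param n_proteins Size of the paired human-like proteome.
#' @param scale Window-count multiplier (default 10).
#' @param overlap Fraction of the composition shared with the human
#'   preset (default 0.7).
#' @inheritParams gen_proteome
#' @return List of [protein_record()]s with ids prefixed `micro`.
#' @export
gen_microbiome <- function(n_proteins, min_length = 60L, max_length = 300L,
                           scale = 10, overlap = 0.7, seed = 1L) {
  if (overlap < 0 || overlap > 1) stop("overlap must be in [0, 1]", call. = FALSE)
  comp <- overlap * residue_composition("human") +
    (1 - overlap) * residue_composition("uniform")
  gen_proteome(round(n_proteins * scale), min_length, max_length,
               composition = comp, seed = seed, id_prefix = "micro")
}

#' Generate interior missense mutations
#'
#' Samples single-residue substitutions at interior positions (at least
#' 14 residues from both termini, so that all nine 9mer and fifteen
#' 15mer registers exist). The reference residue always matches the
#' sequence and the alternate differs from it. With `rare_bias = TRUE`
#' the alternate residue is drawn preferentially from tryptophan,
#' cysteine, histidine and methionine, emulating the enrichment of rare
#' residues among tumor mutations.
#'
#' @param proteome List of [protein_record()]s.
#' @param n Number of mutations.
#' @param seed Integer RNG seed.
#' @param rare_bias Bias alternates toward W, C, H, M (default FALSE).
#' @param one_per_protein Place at most one mutation per protein
#'   (default TRUE).
#' @param case_id Case label for all rows (default `"case001"`, matching
#'   the first case of [gen_genotypes()]).
#' @param rare_weight Sampling weight of W/C/H/M relative to other
#'   residues when `rare_bias` is on (default 6).
#' @return Data frame with columns `case_id`, `protein_id`, `position`,
#'   `ref_aa`, `alt_aa`.
#' @export
gen_mutations <- function(proteome, n, seed = 1L, rare_bias = FALSE,
                          one_per_protein = TRUE, case_id = "case001",
                          rare_weight = 6) {
  lens <- vapply(proteome, function(p) nchar(p$sequence), integer(1))
  eligible <- which(lens >= 29L)  # interior: positions 15 .. L - 14
  if (length(eligible) == 0L)
    stop("proteome too small: no protein admits an interior mutation",
         call. = FALSE)
  set.seed(as.integer(seed))
  if (one_per_protein) {
    if (n > length(eligible))
      stop("requested ", n, " mutations but only ", length(eligible),
           " proteins admit an interior mutation", call. = FALSE)
    prot_idx <- sample(eligible, n)
    pos <- vapply(prot_idx, function(i)
      sample(15:(lens[i] - 14L), 1L), integer(1))
  } else {
    pool_n <- sum(lens[eligible] - 28L)
    if (n > pool_n)
      stop("requested ", n, " mutations but only ", pool_n,
           " interior positions exist", call. = FALSE)
    prot_idx <- sample(eligible, n, replace = TRUE,
                       prob = lens[eligible] - 28L)
    pos <- vapply(prot_idx, function(i)
      sample(15:(lens[i] - 14L), 1L), integer(1))
    dup <- duplicated(paste(prot_idx, pos))
    while (any(dup)) {
      pos[dup] <- vapply(prot_idx[dup], function(i)
        sample(15:(lens[i] - 14L), 1L), integer(1))
      dup <- duplicated(paste(prot_idx, pos))
    }
  }
  alpha <- aa_alphabet()
  wts <- stats::setNames(rep(1, 20), alpha)
  if (rare_bias) wts[c("W", "C", "H", "M")] <- rare_weight
  ref <- substring(vapply(proteome[prot_idx], `[[`, character(1), "sequence"),
                   pos, pos)
  alt <- vapply(seq_along(pos), function(i) {
    opts <- setdiff(alpha, ref[i])
    sample(opts, 1L, prob = wts[opts])
  }, character(1))
  data.frame(case_id = case_id,
             protein_id = vapply(proteome[prot_idx], `[[`, character(1),
                                 "protein_id"),
             position = pos, ref_aa = ref, alt_aa = alt,
             stringsAsFactors = FALSE)
}

#' Default HLA allele pool
#'
#' Common alleles per locus used by [gen_genotypes()].
#'
#' @return Named list with components `A`, `B`, `C`, `DRB1`.
#' @export
default_allele_pool <- function() {
  list(A = c("A*02:01", "A*03:01", "A*01:01", "A*24:02"),
       B = c("B*07:02", "B*08:01", "B*44:02", "B*35:01"),
       C = c("C*04:01", "C*07:02", "C*07:01", "C*03:04"),
       DRB1 = c("DRB1*01:01", "DRB1*04:01", "DRB1*07:01", "DRB1*15:01"))
}

#' Generate synthetic HLA genotypes
#'
#' Draws two alleles per locus from the pool; with probability
#' `homozygosity_rate` a locus is made homozygous by copying the first
#' allele. Slot order follows the draw order (first A allele = A1).
#'
#' @param n_cases Number of cases.
#' @param allele_pool Named list with components `A`, `B`, `C`, `DRB1`
#'   (default [default_allele_pool()]).
#' @param homozygosity_rate Per-locus homozygosity probability
#'   (default 0.1).
#' @param seed Integer RNG seed.
#' @return Data frame with columns `case_id`, `A1`, `A2`, `B1`, `B2`,
#'   `C1`, `C2`, `DRB1_1`, `DRB1_2`.
#' @export
gen_genotypes <- function(n_cases, allele_pool = default_allele_pool(),
                          homozygosity_rate = 0.1, seed = 1L) {
  loci <- c("A", "B", "C", "DRB1")
  if (!all(loci %in% names(allele_pool)) ||
      any(vapply(allele_pool[loci], length, integer(1)) < 1L))
    stop("allele_pool needs at least 1 allele per locus A, B, C, DRB1",
         call. = FALSE)
  if (homozygosity_rate < 0 || homozygosity_rate > 1)
    stop("homozygosity_rate must be in [0, 1]", call. = FALSE)
  set.seed(as.integer(seed))
  draw_locus <- function(pool, n) {
    a1 <- sample(pool, n, replace = TRUE)
    a2 <- sample(pool, n, replace = TRUE)
    hom <- stats::runif(n) < homozygosity_rate
    a2[hom] <- a1[hom]
    list(a1, a2)
  }
  A <- draw_locus(allele_pool$A, n_cases)
  B <- draw_locus(allele_pool$B, n_cases)
  C <- draw_locus(allele_pool$C, n_cases)
  D <- draw_locus(allele_pool$DRB1, n_cases)
  data.frame(case_id = sprintf("case%03d", seq_len(n_cases)),
             A1 = A[[1]], A2 = A[[2]], B1 = B[[1]], B2 = B[[2]],
             C1 = C[[1]], C2 = C[[2]], DRB1_1 = D[[1]], DRB1_2 = D[[2]],
             stringsAsFactors = FALSE)
}

#' Generate an anchor-dominated binding ground truth
#'
#' Builds a deterministic additive binding-energy function for one
#' allele: per-position, per-residue energy contributions drawn from a
#' normal law whose spread at the anchor positions is
#' `anchor_dominance` times the spread elsewhere, so binding is
#' dominated by the groove-facing anchors (p2/p9 for a 9mer; core p1,
#' p4, p6, p9 for the 15mer core, with weak flanks). Predicted
#' Ln(ic50) = `base_ln_ic50` + energy.
#'
#' @param allele Allele label.
#' @param seed Integer RNG seed.
#' @param width Peptide width, 9 (MHC I) or 15 (MHC II).
#' @param anchor_dominance Anchor-to-non-anchor spread ratio
#'   (default 5, must be >= 1).
#' @param noise_sd Lognormal noise, in Ln(ic50) units, applied when
#'   sampling training ic50s (default 0.3).
#' @param base_ln_ic50 Baseline Ln(ic50) (default 8, about 3 micromolar).
#' @return An object of class `binding_truth`, usable directly as a
#'   predictor via [predict_binding()].
#' @export
gen_binding_truth <- function(allele, seed = 1L, width = 9L,
                              anchor_dominance = 5, noise_sd = 0.3,
                              base_ln_ic50 = 8) {
  if (anchor_dominance < 1) stop("anchor_dominance must be >= 1", call. = FALSE)
  width <- as.integer(width)
  if (!width %in% c(9L, 15L)) stop("width must be 9 or 15", call. = FALSE)
  set.seed(as.integer(seed))
  sd_pos <- if (width == 9L) {
    ifelse(1:9 %in% c(2L, 9L), 1, 1 / anchor_dominance)
  } else {
    s <- rep(1 / (2 * anchor_dominance), 15)       # flanks
    s[4:12] <- 1 / anchor_dominance                # core TCEM positions
    s[GEM_II_POSITIONS_15] <- 1                    # core anchors
    s
  }
  # Per-position residue weights are linear combinations of the packaged
  # physicochemical descriptors, so the energy surface lives in the same
  # feature space the ensemble learns in and noiseless ranking is
  # recoverable exactly.
  desc <- compute_descriptors(aa_property_table(), 3L)
  d <- ncol(desc)
  beta <- matrix(stats::rnorm(width * d), nrow = width) * (sd_pos / sqrt(d))
  w <- beta %*% t(unclass(desc)[aa_alphabet(), , drop = FALSE])
  colnames(w) <- aa_alphabet()
  structure(list(allele = allele, width = width, weights = w,
                 anchor_dominance = anchor_dominance, noise_sd = noise_sd,
                 base_ln_ic50 = base_ln_ic50, seed = as.integer(seed)),
            class = "binding_truth")
}

#' Evaluate the deterministic truth energy
#'
#' @param truth A [gen_binding_truth()] object.
#' @param peptides Character vector of peptides of the truth's width.
#' @return Numeric Ln(ic50) values (base + additive energy, no noise).
#' @export
truth_ln_ic50 <- function(truth, peptides) {
  stopifnot(inherits(truth, "binding_truth"))
  if (any(nchar(peptides) != truth$width))
    stop("peptides must have width ", truth$width, call. = FALSE)
  chars <- matrix(unlist(strsplit(peptides, "", fixed = TRUE)),
                  nrow = truth$width)
  idx <- match(chars, aa_alphabet())
  if (anyNA(idx)) stop("peptides contain non-canonical letters", call. = FALSE)
  e <- matrix(truth$weights[cbind(rep(seq_len(truth$width), ncol(chars)),
                                  idx)],
              nrow = truth$width)
  truth$base_ln_ic50 + colSums(e)
}

#' @export
predict_binding.binding_truth <- function(predictor, peptides) {
  data.frame(allele = predictor$allele, peptide = peptides,
             mean_ln_ic50 = truth_ln_ic50(predictor, peptides),
             sd_ln_ic50 = 0, stringsAsFactors = FALSE)
}

#' Sample a peptide-ic50 training table from a truth function
#'
#' Pairs random peptides (human-like composition) with
#' `ic50 = exp(truth energy + Gaussian noise)`; always positive.
#'
#' @param truth A [gen_binding_truth()] object.
#' @param n Number of examples (the working floor for
#'   [train_ensemble()] is 200).
#' @param seed Integer RNG seed.
#' @param composition Residue composition for the random peptides.
#' @return Data frame with columns `allele`, `peptide`, `ic50_nM`.
#' @export
gen_training_set <- function(truth, n, seed = 1L, composition = "human") {
  stopifnot(inherits(truth, "binding_truth"))
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  p <- residue_composition(composition)
  set.seed(as.integer(seed))
  peptides <- vapply(seq_len(n), function(i)
    paste(sample(aa_alphabet(), truth$width, replace = TRUE, prob = p),
          collapse = ""), character(1))
  ln <- truth_ln_ic50(truth, peptides) +
    stats::rnorm(n, 0, truth$noise_sd)
  data.frame(allele = truth$allele, peptide = peptides, ic50_nM = exp(ln),
             stringsAsFactors = FALSE)
}
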