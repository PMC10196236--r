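CLASS_I_SLOTS <- c("A1", "A2", "B1", "B2", "C1", "C2")
CLASS_II_SLOTS <- c("DRB1_1", "DRB1_2")

#' Construct an HLA genotype
#'
#' Six class I allele slots in fixed order A1, A2, B1, B2, C1, C2 plus
#' two DRB1 slots. Slot assignment follows the input order (the first A
#' allele listed is A1); homozygous loci repeat the allele name.
#'
#' @param case_id Case identifier.
#' @param class_i Character vector of 6 class I alleles.
#' @param class_ii Character vector of 2 DRB1 alleles.
#' @return An object of class `genotype`.
#' @export
genotype <- function(case_id, class_i, class_ii) {
  if (length(class_i) != 6L) stop("class_i must have exactly 6 alleles", call. = FALSE)
  if (length(class_ii) != 2L) stop("class_ii must have exactly 2 alleles", call. = FALSE)
  structure(list(case_id = as.character(case_id),
                 class_i = stats::setNames(as.character(class_i), CLASS_I_SLOTS),
                 class_ii = stats::setNames(as.character(class_ii), CLASS_II_SLOTS)),
            class = "genotype")
}

#' Class I genotype bitmap for one register
#'
#' Encodes, per class I allele slot in the fixed order A1 A2 B1 B2 C1 C2,
#' whether the peptide both binds at the Zscale threshold and exposes
#' the mutant residue to the TCR: bit = 1 iff
#' `zscore <= threshold` AND `exposed`.
#'
#' @param zscores Numeric vector of 6 finite Zscale values in slot order.
#' @param exposed Logical: is the mutant residue in a TCEM position of
#'   this register?
#' @param threshold Zscale cut point (default -1).
#' @return A 6-character binary string, e.g. `"001000"`.
#' @export
bitmap_class_i <- function(zscores, exposed, threshold = -1) {
  if (length(zscores) != 6L || any(!is.finite(zscores)))
    stop("zscores must be 6 finite values (A1,A2,B1,B2,C1,C2)", call. = FALSE)
  if (!is.logical(exposed) || anyNA(exposed) ||
      !length(exposed) %in% c(1L, 6L))
    stop("exposed must be a non-NA logical of length 1 or 6", call. = FALSE)
  paste(as.integer(zscores <= threshold & exposed), collapse = "")
}

#' Class II genotype bitmap for one register
#'
#' Two-bit analogue of [bitmap_class_i()] over the DRB1 slots.
#'
#' @param zscores Numeric vector of 2 finite Zscale values (DRB1_1, DRB1_2).
#' @inheritParams bitmap_class_i
#' @return A 2-character binary string.
#' @export
bitmap_class_ii <- function(zscores, exposed, threshold = -1) {
  if (length(zscores) != 2L || any(!is.finite(zscores)))
    stop("zscores must be 2 finite values (DRB1_1, DRB1_2)", call. = FALSE)
  if (!is.logical(exposed) || anyNA(exposed) ||
      !length(exposed) %in% c(1L, 2L))
    stop("exposed must be a non-NA logical of length 1 or 2", call. = FALSE)
  paste(as.integer(zscores <= threshold & exposed), collapse = "")
}

#' Enumerate the full bitmap pattern space
#'
#' @param n_bits Number of bits (6 for class I, 2 for DRB1).
#' @return Character vector of all `2^n_bits` binary strings.
#' @export
#' @examples
#' length(all_bitmap_patterns(6))  # 64
all_bitmap_patterns <- function(n_bits = 6L) {
  apply(expand.grid(rep(list(0:1), n_bits))[, n_bits:1, drop = FALSE],
        1L, paste, collapse = "")
}

#' Classify the binding change caused by a mutation
#'
#' At threshold `t`: `Lost` when binding at or below `t` before mutation
#' is lost after (`wt <= t < mut`); `Gained` when it is acquired
#' (`wt > t >= mut`); otherwise `Retained`.
#'
#' @param wt_z,mut_z Finite wildtype and mutant Zscale values
#'   (vectorized).
#' @param threshold Zscale cut point (default -1).
#' @return Factor with levels `Lost`, `Gained`, `Retained`.
#' @export
classify_binding_change <- function(wt_z, mut_z, threshold = -1) {
  if (any(!is.finite(wt_z)) || any(!is.finite(mut_z)))
    stop("zscores must be finite", call. = FALSE)
  lab <- ifelse(wt_z <= threshold & mut_z > threshold, "Lost",
         ifelse(wt_z > threshold & mut_z <= threshold, "Gained", "Retained"))
  factor(lab, levels = c("Lost", "Gained", "Retained"))
}

#' Minimum-Zscale register matrix
#'
#' For one mutation, the 6 (class I allele slots) x 5 (TCEM-exposing
#' registers) grid of mutant Zscale values identifies the most probable
#' presenting combination: the minimum Zscale (highest predicted
#' affinity). Registers truncated at protein termini are undefined cells
#' (NA) and excluded. Ties within `tol` are all listed; the dominant
#' cell is the first in slot order (A1..C2), then ascending register.
#'
#' @param values Numeric 6 x 5 matrix (rows = A1..C2, columns =
#'   exposing registers 1..5); NA marks undefined cells.
#' @param tol Tie tolerance (default 1e-9).
#' @return An object of class `register_matrix` with `values`,
#'   `min_value`, `argmin` (data frame of slot/register pairs) and
#'   `dominant`.
#' @export
register_matrix <- function(values, tol = 1e-9) {
  values <- as.matrix(values)
  if (!all(dim(values) == c(6L, 5L)))
    stop("values must be a 6 x 5 matrix", call. = FALSE)
  rownames(values) <- CLASS_I_SLOTS
  colnames(values) <- paste0("R", 1:5)
  if (all(is.na(values))) stop("no defined cells in register matrix", call. = FALSE)
  mn <- min(values, na.rm = TRUE)
  hits <- which(!is.na(values) & values <= mn + tol, arr.ind = TRUE)
  argmin <- data.frame(slot = CLASS_I_SLOTS[hits[, 1]],
                       register = as.integer(hits[, 2]),
                       stringsAsFactors = FALSE)
  # slot-major order: A1..C2 outer, ascending register inner
  argmin <- argmin[order(match(argmin$slot, CLASS_I_SLOTS), argmin$register), ,
                   drop = FALSE]
  rownames(argmin) <- NULL
  structure(list(values = values, min_value = mn, argmin = argmin,
                 dominant = argmin[1, ]),
            class = "register_matrix")
}

# Collapse long per-slot annotations to one row per mutant 9mer window,
# with binding = any class I slot at or below threshold.
window_level_class_i <- function(annotations, threshold) {
  a9 <- annotations[annotations$width == 9L, , drop = FALSE]
  if (nrow(a9) == 0L) return(NULL)
  missing_slots <- setdiff(CLASS_I_SLOTS, unique(a9$allele_slot))
  if (length(missing_slots))
    stop("missing class I allele predictions for slot(s): ",
         paste(missing_slots, collapse = ", "), call. = FALSE)
  key <- paste(a9$case_id, a9$protein_id, a9$position, a9$alt_aa, a9$start,
               sep = "\r")
  bound <- tapply(a9$z_mut <= threshold, key, any)
  first <- a9[!duplicated(key), , drop = FALSE]
  ord <- match(names(bound), paste(first$case_id, first$protein_id,
                                   first$position, first$alt_aa, first$start,
                                   sep = "\r"))
  out <- first[ord, , drop = FALSE]
  out$bound <- as.logical(bound)
  out
}

#' Down-selection cascade for one case
#'
#' Tallies the nested filtering from all mutant peptides down to those
#' both bound and TCEM-presenting. A 9mer is "binding" when any class I
#' allele slot has mutant Zscale at or below the threshold; it is "TCEM
#' presenting" when it binds and its register exposes the mutant. The
#' dual-class row additionally requires a DRB1-bound, mutant-exposing
#' 15mer for the same mutation (`dual_rule = "mutation"`) or a bound
#' exposing 15mer that contains the scored 9mer (`dual_rule = "nested"`).
#'
#' @param annotations Long annotation table from [annotate_mutations()].
#' @param threshold Zscale cut point (default -1).
#' @param dual_rule Linkage rule for the both-classes row.
#' @return An object of class `downselect_table` (one-row data frame
#'   with the cascade tallies).
#' @export
downselect <- function(annotations, threshold = -1,
                       dual_rule = c("mutation", "nested")) {
  dual_rule <- match.arg(dual_rule)
  w9 <- window_level_class_i(annotations, threshold)
  if (is.null(w9)) stop("no width-9 annotations", call. = FALSE)
  a15 <- annotations[annotations$width == 15L, , drop = FALSE]
  if (nrow(a15)) {
    missing_ii <- setdiff(CLASS_II_SLOTS, unique(a15$allele_slot))
    if (length(missing_ii))
      stop("missing DRB1 allele predictions for slot(s): ",
           paste(missing_ii, collapse = ", "), call. = FALSE)
  }
  mut_key9 <- paste(w9$case_id, w9$protein_id, w9$position, w9$alt_aa, sep = "\r")
  n_mutations <- length(unique(mut_key9))
  n_9 <- nrow(w9)
  n_15 <- if (nrow(a15)) {
    length(unique(paste(a15$case_id, a15$protein_id, a15$position, a15$alt_aa,
                        a15$start, sep = "\r")))
  } else 0L
  n_binding <- sum(w9$bound)
  present9 <- w9$bound & w9$exposed
  # 15mers both DRB1-bound (either slot) and exposing the mutant
  good15 <- a15[a15$z_mut <= threshold & a15$exposed, , drop = FALSE]
  dual <- if (nrow(good15) == 0L) rep(FALSE, n_9) else if (dual_rule == "mutation") {
    mut_key15 <- unique(paste(good15$case_id, good15$protein_id,
                              good15$position, good15$alt_aa, sep = "\r"))
    present9 & (mut_key9 %in% mut_key15)
  } else {
    vapply(seq_len(n_9), function(i) {
      if (!present9[i]) return(FALSE)
      m <- good15$case_id == w9$case_id[i] &
        good15$protein_id == w9$protein_id[i] &
        good15$position == w9$position[i] & good15$alt_aa == w9$alt_aa[i] &
        good15$start <= w9$start[i] & good15$start + 14L >= w9$start[i] + 8L
      any(m)
    }, logical(1))
  }
  out <- data.frame(
    n_mutations = n_mutations,
    n_peptides_9_15 = n_9 + n_15,
    n_9mers = n_9,
    n_nonbinding_9mers = n_9 - n_binding,
    n_nonbinding_or_nonTCEM = n_9 - sum(present9),
    n_binding = n_binding,
    n_binding_and_TCEM_exposed = sum(present9),
    n_binding_TCEM_I_and_II = sum(dual))
  class(out) <- c("downselect_table", "data.frame")
  out
}

#' Fraction of bound registers exposing the mutant
#'
#' Over all (window, class I allele) binding events at the threshold,
#' the fraction in which the register places the mutant residue in a
#' TCEM position. Under register-uniform binding the expectation is 5/9
#' (five exposing registers out of nine). The peptide-level variant --
#' among 9mers bound by at least one allele, the fraction whose register
#' exposes the mutant -- is returned alongside.
#'
#' @param annotations Long annotation table (width-9 rows used).
#' @param threshold Zscale cut point (default -1).
#' @return List with `event_fraction`, `peptide_fraction`, `n_events`,
#'   `n_bound_peptides`; fractions are NA (flagged via `defined`) when
#'   nothing binds.
#' @export
exposure_fraction <- function(annotations, threshold = -1) {
  a9 <- annotations[annotations$width == 9L, , drop = FALSE]
  if (nrow(a9) == 0L) stop("no width-9 annotations", call. = FALSE)
  ev <- a9$z_mut <= threshold
  n_events <- sum(ev)
  w9 <- window_level_class_i(annotations, threshold)
  n_bound <- sum(w9$bound)
  list(event_fraction = if (n_events) mean(a9$exposed[ev]) else NA_real_,
       peptide_fraction = if (n_bound) mean(w9$exposed[w9$bound]) else NA_real_,
       n_events = n_events, n_bound_peptides = n_bound,
       defined = n_events > 0L)
}

#' Diversity of genotype binding patterns
#'
#' Counts the distinct bitmap patterns among peptides of a case and
#' their Shannon entropy in bits.
#'
#' @param bitmaps Character vector of bitmap strings (one per peptide).
#' @return List with `n_distinct_patterns` and `shannon_entropy_bits`.
#' @export
#' @examples
#' pattern_diversity(c("000001", "000001", "100000", "010000", "001000"))
pattern_diversity <- function(bitmaps) {
  if (length(bitmaps) < 1L) stop("need at least one bitmap", call. = FALSE)
  p <- table(bitmaps) / length(bitmaps)
  list(n_distinct_patterns = length(p),
       shannon_entropy_bits = -sum(p * log2(p)))
}

#' Cumulative bound-and-exposed fraction by pentamer frequency
#'
#' For mutant 9mers that are bound (any class I allele at the threshold)
#' and expose the mutant, tallies the cumulative fraction by the hPPF
#' count of the mutant TCEM, over integer hPPF 0..`ppf_cap`. The curve
#' is nondecreasing and saturates at 1 at the cap; it is the input for
#' [fit_weibull_growth()].
#'
#' @param annotations Long annotation table.
#' @param ppf_cap Largest hPPF value on the curve (default 10).
#' @param threshold Zscale cut point (default -1).
#' @return Data frame with columns `hppf` (0..cap) and
#'   `cumulative_fraction`.
#' @export
cumulative_fraction_by_ppf <- function(annotations, ppf_cap = 10L,
                                       threshold = -1) {
  w9 <- window_level_class_i(annotations, threshold)
  if (is.null(w9) || nrow(w9) == 0L) stop("empty annotations", call. = FALSE)
  sel <- w9$bound & w9$exposed & w9$hppf_mut <= ppf_cap
  if (!any(sel))
    stop("no bound, exposed peptides with hPPF <= ", ppf_cap, call. = FALSE)
  h <- w9$hppf_mut[sel]
  grid <- 0:ppf_cap
  data.frame(hppf = grid,
             cumulative_fraction = vapply(grid, function(g) mean(h <= g),
                                          numeric(1)))
}
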