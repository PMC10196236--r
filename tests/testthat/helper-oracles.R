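# Independent brute-force oracles used to check vectorized implementations.
# Each oracle deliberately uses a different algorithm (character loops,
# string tables) from the code under test.

# All clean windows of a sequence, by per-character loop.
oracle_windows <- function(sequence, width) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  ok <- chars %in% aa_alphabet()
  out <- character()
  starts <- integer()
  for (s in seq_len(max(0L, length(chars) - width + 1L))) {
    if (all(ok[s:(s + width - 1L)])) {
      out <- c(out, paste(chars[s:(s + width - 1L)], collapse = ""))
      starts <- c(starts, s)
    }
  }
  data.frame(start = starts, peptide = out, stringsAsFactors = FALSE)
}

# TCEM by direct character indexing (independent of substring()).
oracle_tcem_i <- function(nine_mer) {
  paste(strsplit(nine_mer, "", fixed = TRUE)[[1]][4:8], collapse = "")
}

# TCEM II via the double-index route: first cut the core 9mer
# (15mer positions 4-12), then take core pockets 2,3,5,7,8.
oracle_tcem_ii <- function(fifteen_mer) {
  core <- strsplit(fifteen_mer, "", fixed = TRUE)[[1]][4:12]
  paste(core[c(2, 3, 5, 7, 8)], collapse = "")
}

# Pentamer tally as a named string table (no integer keys).
oracle_ppf_table <- function(proteome, motif_class) {
  width <- if (motif_class == "I") 9L else 15L
  extractor <- if (motif_class == "I") oracle_tcem_i else oracle_tcem_ii
  motifs <- character()
  for (p in proteome) {
    w <- oracle_windows(p$sequence, width)
    if (nrow(w)) motifs <- c(motifs, vapply(w$peptide, extractor, character(1)))
  }
  table(motifs)
}

# Exhaustive per-peptide reclassification of the down-selection cascade,
# all plain loops over window-level records.
oracle_downselect <- function(annotations, threshold = -1,
                              dual_rule = "mutation") {
  a9 <- annotations[annotations$width == 9L, ]
  a15 <- annotations[annotations$width == 15L, ]
  wkey <- function(a) paste(a$case_id, a$protein_id, a$position, a$alt_aa,
                            a$start)
  mkey <- function(a) paste(a$case_id, a$protein_id, a$position, a$alt_aa)
  keys9 <- unique(wkey(a9))
  n_binding <- 0L; n_present <- 0L; n_dual <- 0L
  good15 <- a15[a15$z_mut <= threshold & a15$exposed, ]
  for (k in keys9) {
    rows <- a9[wkey(a9) == k, ]
    bound <- any(rows$z_mut <= threshold)
    present <- bound && rows$exposed[1]
    n_binding <- n_binding + bound
    n_present <- n_present + present
    if (present) {
      dual <- if (dual_rule == "mutation") {
        mkey(rows)[1] %in% mkey(good15)
      } else {
        any(mkey(good15) == mkey(rows)[1] &
              good15$start <= rows$start[1] &
              good15$start + 14L >= rows$start[1] + 8L)
      }
      n_dual <- n_dual + dual
    }
  }
  list(n_mutations = length(unique(mkey(a9))),
       n_9mers = length(keys9),
       n_15mers = length(unique(wkey(a15))),
       n_binding = as.integer(n_binding),
       n_binding_and_TCEM_exposed = as.integer(n_present),
       n_binding_TCEM_I_and_II = as.integer(n_dual))
}

# Full scan of a register matrix for its minimum and first argmin in
# slot-major order.
oracle_register_min <- function(values, tol = 1e-9) {
  slots <- c("A1", "A2", "B1", "B2", "C1", "C2")
  best <- Inf; arg <- NULL
  for (r in 1:6) for (cc in 1:5) {
    v <- values[r, cc]
    if (!is.na(v) && v < best - tol) {
      best <- v; arg <- c(slots[r], cc)
    }
  }
  list(min = best, slot = arg[1], register = as.integer(arg[2]))
}

# Small standard fixtures shared across tests.
make_toy_proteome <- function(n = 8, seed = 11, min_len = 40, max_len = 80) {
  gen_proteome(n, min_length = min_len, max_length = max_len, seed = seed)
}
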