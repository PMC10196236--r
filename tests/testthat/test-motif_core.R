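test_that("class I TCEM is the p4-p8 pentamer facing the TCR", {
  expect_identical(extract_tcem_i("ACDEFGHIK"), "EFGHI")
  expect_identical(extract_tcem_i("VGADGVGKS"), "DGVGK")
  expect_identical(extract_tcem_i("HMTEVVRHC"), "EVVRH")
})

test_that("class II TCEM takes 15mer positions 5,6,8,10,11", {
  expect_identical(extract_tcem_ii("ACDEFGHIKLMNPQR"), "FGILM")
  # double-index oracle: core 9mer then core pockets 2,3,5,7,8
  set.seed(21)
  for (i in 1:25) {
    pep <- paste(sample(aa_alphabet(), 15, replace = TRUE), collapse = "")
    expect_identical(extract_tcem_ii(pep), oracle_tcem_ii(pep))
  }
})

test_that("GEM motifs are the anchor complements of the TCEM positions", {
  expect_identical(extract_gem_i("ACDEFGHIK"), "ACDK")
  expect_identical(extract_gem_ii("ACDEFGHIKLMNPQR"), "EHKN")
  # every 9mer position is either TCEM I, GEM I, or neither -- and the
  # class I TCEM/GEM sets are disjoint and cover p1,p2,p3,p4..p8,p9
  pep <- "ACDEFGHIK"
  tc <- strsplit(extract_tcem_i(pep), "")[[1]]
  gm <- strsplit(extract_gem_i(pep), "")[[1]]
  expect_length(intersect(which(strsplit(pep, "")[[1]] %in% tc),
                          which(strsplit(pep, "")[[1]] %in% gm)), 0)
})

test_that("motif extraction rejects wrong widths and ambiguity codes", {
  expect_error(extract_tcem_i("ACDEFGHI"), "9")
  expect_error(extract_tcem_i("ACDEXGHIK"), "canonical")
  expect_error(extract_tcem_ii("ACDEFGHIK"), "15")
  expect_error(extract_gem_ii("ACDEFGHIKLMNPXR"), "canonical")
})

test_that("window_peptides matches the brute-force oracle on ambiguous sequences", {
  seqs <- c("ACDEFGHIKLMNPQ",           # clean
            "ACDEFXGHIKLMNPQ",          # one X
            "XXACDEFGHIKXXLMNPQRSTVWY", # leading/interior runs
            "ACDEFGH",                  # shorter than width
            "ACDU*FGHIKLMNPQRSTV")      # U and stop
  for (s in seqs) {
    got <- window_peptides(protein_record("p", s), 9)
    want <- oracle_windows(s, 9)
    expect_identical(got$start, want$start, info = s)
    expect_identical(got$peptide, want$peptide, info = s)
  }
})

test_that("windows advance by one residue and cover L - w + 1 starts when clean", {
  p <- protein_record("p", paste(rep("ACDEFGHIKL", 4), collapse = ""))
  w <- window_peptides(p, 9)
  expect_identical(w$start, 1:(40 - 9 + 1))
  expect_true(all(nchar(w$peptide) == 9))
  w15 <- window_peptides(p, 15)
  expect_identical(w15$start, 1:(40 - 15 + 1))
})

test_that("apply_mutation verifies the reference residue and flags mismatches", {
  p <- protein_record("p1", "ACDEFGHIKLMNPQR")
  m <- mutation("c1", "p1", 5, "F", "W")
  pm <- apply_mutation(p, m)
  expect_true(pm$is_mutant)
  expect_identical(substring(pm$sequence, 5, 5), "W")
  expect_identical(nchar(pm$sequence), nchar(p$sequence))
  bad <- mutation("c1", "p1", 5, "G", "W")
  expect_error(apply_mutation(p, bad), class = "tcemscan_verification_error")
  expect_error(apply_mutation(p, mutation("c1", "p1", 99, "A", "G")), "beyond")
  expect_error(mutation("c1", "p1", 5, "F", "F"), "differ")
  expect_error(mutation("c1", "p1", 5, "X", "W"), "canonical")
})

test_that("interior mutation has 9 registers at width 9, 5 exposing", {
  p <- protein_record("p1", paste(rep("ACDEFGHIKL", 6), collapse = ""))
  m <- mutation("c1", "p1", 30, "L", "W")
  pm <- apply_mutation(p, m)
  regs <- enumerate_mutant_registers(pm, m, 9)
  expect_identical(nrow(regs), 9L)
  expect_identical(sum(regs$exposed), 5L)
  expect_identical(regs$mutant_pocket, 9:1)
  expect_identical(regs$offset, -8:0)
  expect_true(all(regs$exposed == (regs$mutant_pocket %in% 4:8)))
  # the mutant letter really sits at the claimed pocket
  at <- substring(regs$peptide, 10 - seq_len(9), 10 - seq_len(9))
  expect_true(all(substring(regs$peptide, regs$mutant_pocket,
                            regs$mutant_pocket) == "W"))
})

test_that("interior mutation has 15 registers at width 15, 5 exposing, 6 outside core", {
  p <- protein_record("p1", paste(rep("ACDEFGHIKL", 6), collapse = ""))
  m <- mutation("c1", "p1", 30, "L", "W")
  pm <- apply_mutation(p, m)
  regs <- enumerate_mutant_registers(pm, m, 15)
  expect_identical(nrow(regs), 15L)
  expect_identical(sum(regs$exposed), 5L)
  expect_identical(sum(is.na(regs$mutant_pocket)), 6L)
  expect_identical(sum(!is.na(regs$mutant_pocket) & !regs$exposed), 4L)
  # flank registers never count as exposed
  expect_true(all(!regs$exposed[is.na(regs$mutant_pocket)]))
})

test_that("terminal mutations have truncated register sets", {
  p <- protein_record("p1", paste(rep("ACDEFGHIKL", 3), collapse = ""))
  m <- mutation("c1", "p1", 2, "C", "W")
  pm <- apply_mutation(p, m)
  regs <- enumerate_mutant_registers(pm, m, 9)
  expect_identical(nrow(regs), 2L)  # windows starting at 1 and 2 only
  expect_true(all(regs$start %in% 1:2))
})

test_that("exposed registers change the TCEM, hidden registers do not", {
  p <- protein_record("p1", paste(rep("ACDEFGHIKL", 6), collapse = ""))
  m <- mutation("c1", "p1", 30, "L", "W")
  pm <- apply_mutation(p, m)
  regs <- enumerate_mutant_registers(pm, m, 9)
  wt_pep <- substring(p$sequence, regs$start, regs$start + 8)
  wt_tcem <- vapply(wt_pep, extract_tcem_i, character(1), USE.NAMES = FALSE)
  expect_identical(regs$tcem != wt_tcem, regs$exposed)
})

test_that("mutant_relative_index is start minus mutation position", {
  p <- protein_record("p1", paste(rep("ACDEFGHIKL", 4), collapse = ""))
  m <- mutation("c1", "p1", 20, "L", "K")
  w <- window_peptides(apply_mutation(p, m), 9)
  expect_identical(mutant_relative_index(w, m), as.integer(w$start - 20L))
  m2 <- mutation("c1", "other", 20, "L", "K")
  expect_error(mutant_relative_index(w, m2), "different proteins")
})
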