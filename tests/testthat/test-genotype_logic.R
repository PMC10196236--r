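test_that("genotype construction enforces slot counts", {
  g <- genotype("c1", c("A*02:01", "A*03:01", "B*07:02", "B*08:01",
                        "C*04:01", "C*07:02"),
                c("DRB1*01:01", "DRB1*04:01"))
  expect_named(g$class_i, c("A1", "A2", "B1", "B2", "C1", "C2"))
  expect_named(g$class_ii, c("DRB1_1", "DRB1_2"))
  expect_error(genotype("c1", c("A*02:01"), c("x", "y")), "6 alleles")
  expect_error(genotype("c1", letters[1:6], "x"), "2 alleles")
})

test_that("bitmaps set a bit only when bound AND exposed", {
  z <- c(-2, -0.5, -1.5, 0, -1, 3)
  expect_identical(bitmap_class_i(z, TRUE), "101010")   # -1 is inclusive
  expect_identical(bitmap_class_i(z, FALSE), "000000")
  expect_identical(bitmap_class_i(z, c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)),
                   "100010")
  expect_identical(bitmap_class_ii(c(-3, 0), TRUE), "10")
  expect_error(bitmap_class_i(z[1:5], TRUE), "6 finite")
  expect_error(bitmap_class_i(z, NA), "non-NA")
  expect_error(bitmap_class_ii(c(NA, 1), TRUE), "finite")
})

test_that("the bitmap pattern space has 64 class I and 4 DRB1 patterns", {
  p6 <- all_bitmap_patterns(6)
  expect_length(p6, 64)
  expect_identical(anyDuplicated(p6), 0L)
  expect_true(all(nchar(p6) == 6))
  expect_length(all_bitmap_patterns(2), 4)
})

test_that("binding changes classify as Lost, Gained, or Retained", {
  got <- classify_binding_change(c(-2, 0, -2, 0, -1), c(0, -2, -1.5, 0.5, -1))
  expect_identical(as.character(got),
                   c("Lost", "Gained", "Retained", "Retained", "Retained"))
  expect_identical(levels(got), c("Lost", "Gained", "Retained"))
  expect_error(classify_binding_change(NA, 1), "finite")
})

test_that("register_matrix matches a full scan and orders ties slot-major", {
  set.seed(201)
  for (i in 1:10) {
    v <- matrix(stats::rnorm(30), 6, 5)
    v[sample(30, 4)] <- NA
    rm_ <- register_matrix(v)
    want <- oracle_register_min(v)
    expect_equal(rm_$min_value, want$min)
    expect_identical(rm_$dominant$slot, want$slot)
    expect_identical(rm_$dominant$register, want$register)
  }
  tie <- matrix(5, 6, 5)
  rt <- register_matrix(tie)
  expect_identical(rt$dominant$slot, "A1")
  expect_identical(rt$dominant$register, 1L)
  expect_identical(nrow(rt$argmin), 30L)
  expect_error(register_matrix(matrix(NA_real_, 6, 5)), "no defined")
  expect_error(register_matrix(matrix(1, 3, 5)), "6 x 5")
})

test_that("near-ties within tolerance are all reported as argmin", {
  v <- matrix(10, 6, 5)
  v[2, 3] <- 1
  v[5, 4] <- 1 + 1e-12
  rm_ <- register_matrix(v)
  expect_identical(nrow(rm_$argmin), 2L)
  expect_identical(rm_$dominant$slot, "A2")
})

test_that("pattern_diversity counts patterns and Shannon bits", {
  pd <- pattern_diversity(c("000001", "000001", "100000", "010000", "001000"))
  expect_identical(pd$n_distinct_patterns, 4L)
  expect_equal(pd$shannon_entropy_bits,
               -sum(c(2, 1, 1, 1) / 5 * log2(c(2, 1, 1, 1) / 5)))
  uni <- pattern_diversity(rep("111111", 10))
  expect_identical(uni$n_distinct_patterns, 1L)
  expect_equal(uni$shannon_entropy_bits, 0)
  expect_error(pattern_diversity(character()), "at least one")
})

# A small synthetic annotated case shared by the cascade tests.
make_annotated_case <- function(seed = 301, n_prot = 12, n_mut = 8) {
  prot <- gen_proteome(n_prot, min_length = 50, max_length = 90, seed = seed)
  muts <- gen_mutations(prot, n_mut, seed = seed + 1)
  geno <- gen_genotypes(1, seed = seed + 2)
  run_case(list(proteome = prot, mutations = muts, genotypes = geno,
                truth_seed = seed + 3))
}

test_that("downselect matches the exhaustive per-peptide oracle", {
  res <- make_annotated_case()
  for (rule in c("mutation", "nested")) {
    ds <- downselect(res$annotations, dual_rule = rule)
    want <- oracle_downselect(res$annotations, dual_rule = rule)
    expect_identical(ds$n_mutations, want$n_mutations)
    expect_identical(ds$n_9mers, want$n_9mers)
    expect_identical(ds$n_peptides_9_15, want$n_9mers + want$n_15mers)
    expect_identical(ds$n_binding, want$n_binding)
    expect_identical(ds$n_binding_and_TCEM_exposed,
                     want$n_binding_and_TCEM_exposed)
    expect_identical(ds$n_binding_TCEM_I_and_II,
                     want$n_binding_TCEM_I_and_II)
  }
})

test_that("downselect tallies are internally consistent", {
  res <- make_annotated_case(seed = 311)
  ds <- downselect(res$annotations)
  expect_identical(ds$n_nonbinding_9mers + ds$n_binding, ds$n_9mers)
  expect_identical(ds$n_nonbinding_or_nonTCEM + ds$n_binding_and_TCEM_exposed,
                   ds$n_9mers)
  expect_lte(ds$n_binding_TCEM_I_and_II, ds$n_binding_and_TCEM_exposed)
  expect_lte(ds$n_binding_and_TCEM_exposed, ds$n_binding)
  # the nested rule is at least as strict as the per-mutation rule
  ds_nested <- downselect(res$annotations, dual_rule = "nested")
  expect_lte(ds_nested$n_binding_TCEM_I_and_II, ds$n_binding_TCEM_I_and_II)
})

test_that("downselect reports which allele slots are missing", {
  res <- make_annotated_case(seed = 321)
  a <- res$annotations
  expect_error(downselect(a[a$allele_slot != "B1", ]), "B1")
  expect_error(downselect(a[a$width == 15, ]), "no width-9")
})

test_that("exposure_fraction flags the no-binding case instead of failing", {
  res <- make_annotated_case(seed = 331)
  a <- res$annotations
  ef <- exposure_fraction(a, threshold = -50)   # nothing binds
  expect_false(ef$defined)
  expect_true(is.na(ef$event_fraction))
  ef2 <- exposure_fraction(a, threshold = 50)   # everything binds
  expect_true(ef2$defined)
  expect_equal(ef2$event_fraction, mean(a$exposed[a$width == 9]))
})

test_that("cumulative_fraction_by_ppf is nondecreasing and reaches 1", {
  res <- make_annotated_case(seed = 341)
  curve <- cumulative_fraction_by_ppf(res$annotations, ppf_cap = 10)
  expect_identical(curve$hppf, 0:10)
  expect_true(all(diff(curve$cumulative_fraction) >= 0))
  expect_equal(curve$cumulative_fraction[11], 1)
})
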