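# One mid-sized annotated case reused by several tests (built once).
pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      prot <- gen_proteome(25, min_length = 60, max_length = 110, seed = 61)
      muts <- gen_mutations(prot, 15, seed = 62)
      geno <- gen_genotypes(1, seed = 63)
      cache <<- list(prot = prot, muts = muts, geno = geno,
                     res = run_case(list(proteome = prot, mutations = muts,
                                         genotypes = geno, truth_seed = 64)))
    }
    cache
  }
})

test_that("annotate_mutations emits one row per mutation-width-register-slot", {
  fx <- pipeline_fixture()
  a <- fx$res$annotations
  # interior mutations: 9 registers x 6 slots + 15 registers x 2 slots
  per_mut <- table(paste(a$protein_id, a$position))
  expect_true(all(per_mut == 9 * 6 + 15 * 2))
  expect_identical(nrow(a), 15L * (9L * 6L + 15L * 2L))
  expect_true(all(c("tcem_wt", "tcem_mut", "hppf_wt", "hppf_mut",
                    "z_wt", "z_mut", "change_class") %in% names(a)))
  expect_identical(nrow(fx$res$exclusions), 0L)
})

test_that("hidden registers keep the wildtype TCEM, exposed registers change it", {
  fx <- pipeline_fixture()
  a <- fx$res$annotations
  a9 <- a[a$width == 9, ]
  expect_true(all(a9$tcem_wt[!a9$exposed] == a9$tcem_mut[!a9$exposed]))
  expect_true(all(a9$tcem_wt[a9$exposed] != a9$tcem_mut[a9$exposed]))
})

test_that("wildtype motifs of clean windows are present in the hPPF they built", {
  fx <- pipeline_fixture()
  a <- fx$res$annotations
  expect_true(all(a$hppf_wt[a$width == 9] >= 1))
  expect_true(all(a$hppf_wt[a$width == 15] >= 1))
})

test_that("problem mutations are excluded with reasons, not dropped silently", {
  fx <- pipeline_fixture()
  muts <- rbind(fx$muts,
                data.frame(case_id = "case001", protein_id = "prot00001",
                           position = 20L, ref_aa = "W", alt_aa = "A"),
                data.frame(case_id = "ghost", protein_id = "prot00001",
                           position = 20L, ref_aa = "A", alt_aa = "V"),
                data.frame(case_id = "case001", protein_id = "nope",
                           position = 20L, ref_aa = "A", alt_aa = "V"))
  # make the first added row a guaranteed reference mismatch (ref must
  # differ from both the true residue and the alternate "A")
  seqs <- vapply(fx$prot, `[[`, character(1), "sequence")
  real <- substring(seqs[1], 20, 20)
  muts$ref_aa[nrow(fx$muts) + 1L] <- setdiff(aa_alphabet(), c(real, "A"))[1]
  alleles <- unique(unlist(fx$geno[1, -1]))
  preds <- stats::setNames(lapply(seq_along(alleles), function(i)
    gen_binding_truth(alleles[i], seed = 900 + i,
                      width = if (grepl("DRB1", alleles[i])) 15L else 9L)),
    alleles)
  ppf_i <- build_ppf(fx$prot, "I"); ppf_ii <- build_ppf(fx$prot, "II")
  ann <- annotate_mutations(fx$prot, muts, fx$geno, preds, ppf_i, ppf_ii)
  excl <- attr(ann, "exclusions")
  expect_identical(nrow(excl), 3L)
  expect_setequal(excl$reason, c("verification_failed", "missing_genotype",
                                 "missing_protein"))
})

test_that("annotation validates predictors up front", {
  fx <- pipeline_fixture()
  ppf_i <- build_ppf(fx$prot, "I"); ppf_ii <- build_ppf(fx$prot, "II")
  expect_error(annotate_mutations(fx$prot, fx$muts, fx$geno,
                                  list(), ppf_i, ppf_ii),
               "no predictor")
})

test_that("compare_mut_wt fits ZIP models on exposed registers by default", {
  fx <- pipeline_fixture()
  cmp <- compare_mut_wt(fx$res$annotations, "I", "hppf")
  expect_s3_class(cmp$zip_wt, "zip_fit")
  expect_s3_class(cmp$zip_mut, "zip_fit")
  expect_identical(cmp$n, 15L * 5L)   # exposed registers only
  expect_true(all(c("absent", "singleton") %in%
                    names(cmp$class_tally_mut)))
  cmp_all <- compare_mut_wt(fx$res$annotations, "I", "hppf", subset = "all")
  expect_identical(cmp_all$n, 15L * 9L)
  expect_error(compare_mut_wt(fx$res$annotations[0, ], "I", "hppf"),
               "at least")
})

test_that("mutant motifs are rarer than wildtype motifs in the reference", {
  # wildtype TCEMs come from the reference proteome itself (count >= 1);
  # mutant TCEMs are novel pentamers, mostly absent
  fx <- pipeline_fixture()
  cmp <- compare_mut_wt(fx$res$annotations, "I", "hppf")
  tally_frac <- function(t, lvl) unname(t[lvl]) / sum(t)
  expect_gt(tally_frac(cmp$class_tally_mut, "absent"),
            tally_frac(cmp$class_tally_wt, "absent"))
  expect_identical(tally_frac(cmp$class_tally_wt, "absent"), 0)
  if (!cmp$zip_mut$degenerate) {
    expect_gt(cmp$delta_lambda, 0)
  } else {
    # on a tiny reference every novel mutant pentamer can be absent;
    # the degenerate flag (pi = 1) is the correct, explicit answer
    expect_identical(cmp$zip_mut$pi_hat, 1)
  }
})

test_that("mutant-aligned profiles are depressed only at mutant-containing offsets", {
  fx <- pipeline_fixture()
  prof <- mutant_alignment_profile(fx$res$annotations, "I", "hppf")
  delta <- prof$mean_z_mut - prof$mean_z_wt
  exposed_offsets <- prof$offset %in% (-7:-3)  # mutant at p8..p4
  expect_true(all(delta[exposed_offsets] < 0))
  expect_true(all(abs(delta[!exposed_offsets]) < 1e-9))
})

test_that("run_case writes deterministic outputs and a machine-readable summary", {
  fx <- pipeline_fixture()
  outdir <- tempfile("caserun")
  on.exit(unlink(outdir, recursive = TRUE), add = TRUE)
  res <- run_case(list(proteome = fx$prot, mutations = fx$muts,
                       genotypes = fx$geno, truth_seed = 64,
                       outdir = outdir))
  expect_identical(res$annotations, fx$res$annotations)
  expect_true(all(file.exists(file.path(outdir,
    c("annotations.tsv", "windows.tsv", "downselect.tsv", "summary.json")))))
  summ <- jsonlite::fromJSON(file.path(outdir, "summary.json"))
  expect_identical(summ$cases$case001$downselect$n_mutations, 15L)
  back <- utils::read.delim(file.path(outdir, "downselect.tsv"))
  expect_identical(back$n_9mers, res$downselect$n_9mers)
})

test_that("run_case resolves file-based inputs identically to in-memory ones", {
  fx <- pipeline_fixture()
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  gtsv <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(fa, tsv, gtsv)), add = TRUE)
  write_proteome_fasta(fx$prot, fa)
  write_mutations_tsv(fx$muts, tsv)
  write_genotypes_tsv(fx$geno, gtsv)
  res <- run_case(list(proteome = fa, mutations = tsv, genotypes = gtsv,
                       truth_seed = 64))
  expect_identical(res$annotations, fx$res$annotations)
})

test_that("run_case rejects incomplete or inconsistent configs up front", {
  fx <- pipeline_fixture()
  expect_error(run_case(list(mutations = fx$muts, genotypes = fx$geno)),
               "proteome")
  expect_error(run_case(list(proteome = fx$prot, mutations = fx$muts,
                             genotypes = fx$geno)),
               "truth_seed")
  bad_muts <- fx$muts
  bad_muts$case_id <- "unknown_case"
  expect_error(run_case(list(proteome = fx$prot, mutations = bad_muts,
                             genotypes = fx$geno, truth_seed = 1)),
               "unknown case")
  expect_error(run_case(42), "list or a file path")
})

test_that("per-case summaries carry the cascade, exposure, diversity and fits", {
  fx <- pipeline_fixture()
  s <- fx$res$case_summaries[["case001"]]
  expect_identical(s$downselect$n_mutations, 15L)
  expect_true(s$exposure$n_events > 0)
  expect_gte(s$diversity$n_distinct_patterns, 1L)
  expect_lte(s$diversity$n_distinct_patterns, 64L)
  if (!is.null(s$cumulative_curve)) {
    expect_true(all(diff(s$cumulative_curve$cumulative_fraction) >= 0))
  }
})
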