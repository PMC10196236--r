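# Cached within-protein Zscale lookup: predicts over every clean window
# of the protein for one allele and standardizes, returning start -> z.
zscale_map <- function(predictor, protein, width, min_group) {
  pred <- predict_protein(predictor, protein, width)
  if (nrow(pred) == 0L) return(NULL)
  pred <- zscale_within_protein(pred, min_group = min_group)
  stats::setNames(pred$zscore, pred$start)
}

#' Annotate mutations with motif frequencies and genotype binding
#'
#' For every verified mutation, enumerates its 9mer and 15mer binding
#' registers, extracts wildtype and mutant TCEM with their reference
#' pentamer counts (hPPF, and giPPF when microbiome tables are given),
#' and scores wildtype and mutant peptides against every allele slot of
#' the case genotype on the within-protein Zscale. Mutations whose
#' reference residue cannot be verified, or whose protein or case
#' genotype is missing, are reported in the `exclusions` attribute and
#' skipped, never silently dropped.
#'
#' @param proteome List of wildtype [protein_record()]s.
#' @param mutations Mutation data frame (`case_id`, `protein_id`,
#'   `position`, `ref_aa`, `alt_aa`).
#' @param genotypes Genotype data frame (see [read_genotypes_tsv()]).
#' @param predictors Named list mapping every allele name appearing in
#'   `genotypes` to a predictor accepted by [predict_binding()]
#'   (width 9 for class I alleles, width 15 for DRB1).
#' @param ppf_i,ppf_ii Class I / class II `pentamer_table`s (hPPF).
#' @param ppf_i_micro,ppf_ii_micro Optional microbiome tables (giPPF).
#' @param min_group Minimum group size for the SHASH Zscale fit.
#' @return Long data frame, one row per
#'   (mutation x width x register x allele slot), with columns
#'   `case_id`, `protein_id`, `position`, `ref_aa`, `alt_aa`, `width`,
#'   `start`, `offset`, `mutant_pocket`, `exposed`, `tcem_wt`,
#'   `tcem_mut`, `gem_mut`, `hppf_wt`, `hppf_mut`, `gippf_wt`,
#'   `gippf_mut`, `allele_slot`, `allele`, `z_wt`, `z_mut`,
#'   `change_class`. Attribute `exclusions` lists skipped mutations
#'   with reason codes.
#' @export
annotate_mutations <- function(proteome, mutations, genotypes, predictors,
                               ppf_i, ppf_ii, ppf_i_micro = NULL,
                               ppf_ii_micro = NULL, min_group = 8L) {
  prot_ids <- vapply(proteome, `[[`, character(1), "protein_id")
  if (anyDuplicated(prot_ids)) stop("duplicate protein ids", call. = FALSE)
  prot_index <- stats::setNames(seq_along(proteome), prot_ids)
  alleles_used <- unique(unlist(genotypes[, c(CLASS_I_SLOTS, CLASS_II_SLOTS)]))
  missing_pred <- setdiff(alleles_used, names(predictors))
  if (length(missing_pred))
    stop("no predictor for allele(s): ", paste(missing_pred, collapse = ", "),
         call. = FALSE)
  geno_index <- stats::setNames(seq_len(nrow(genotypes)), genotypes$case_id)
  wt_cache <- new.env(parent = emptyenv())
  wt_z <- function(allele, protein, width) {
    key <- paste(protein$protein_id, allele, width, sep = "\r")
    if (is.null(wt_cache[[key]]))
      wt_cache[[key]] <- zscale_map(predictors[[allele]], protein, width,
                                    min_group)
    wt_cache[[key]]
  }
  rows <- list()
  excl <- list()
  for (i in seq_len(nrow(mutations))) {
    m <- mutations[i, ]
    note_excl <- function(reason) {
      excl[[length(excl) + 1L]] <<- data.frame(
        case_id = m$case_id, protein_id = m$protein_id,
        position = m$position, alt_aa = m$alt_aa, reason = reason,
        stringsAsFactors = FALSE)
    }
    if (is.na(geno_index[m$case_id])) { note_excl("missing_genotype"); next }
    if (is.na(prot_index[m$protein_id])) { note_excl("missing_protein"); next }
    wt_prot <- proteome[[prot_index[m$protein_id]]]
    mut <- tryCatch(mutation(m$case_id, m$protein_id, m$position,
                             m$ref_aa, m$alt_aa),
                    error = function(e) NULL)
    if (is.null(mut)) { note_excl("invalid_mutation"); next }
    mut_prot <- tryCatch(apply_mutation(wt_prot, mut),
                         error = function(e) e)
    if (inherits(mut_prot, "error")) {
      note_excl(if (inherits(mut_prot, "tcemscan_verification_error"))
        "verification_failed" else "invalid_mutation")
      next
    }
    geno <- genotypes[geno_index[m$case_id], ]
    for (width in c(9L, 15L)) {
      regs <- enumerate_mutant_registers(mut_prot, mut, width)
      if (nrow(regs) == 0L) next
      wt_pep <- substring(wt_prot$sequence, regs$start,
                          regs$start + width - 1L)
      if (width == 9L) {
        tcem_wt <- vapply(wt_pep, extract_tcem_i, character(1),
                          USE.NAMES = FALSE)
        ppf <- ppf_i; ppf_m <- ppf_i_micro
        slots <- CLASS_I_SLOTS
      } else {
        tcem_wt <- vapply(wt_pep, extract_tcem_ii, character(1),
                          USE.NAMES = FALSE)
        ppf <- ppf_ii; ppf_m <- ppf_ii_micro
        slots <- CLASS_II_SLOTS
      }
      base <- data.frame(
        case_id = m$case_id, protein_id = m$protein_id,
        position = m$position, ref_aa = m$ref_aa, alt_aa = m$alt_aa,
        width = width, start = regs$start, offset = regs$offset,
        mutant_pocket = regs$mutant_pocket, exposed = regs$exposed,
        tcem_wt = tcem_wt, tcem_mut = regs$tcem, gem_mut = regs$gem,
        hppf_wt = lookup(ppf, tcem_wt), hppf_mut = lookup(ppf, regs$tcem),
        gippf_wt = if (is.null(ppf_m)) NA_integer_ else lookup(ppf_m, tcem_wt),
        gippf_mut = if (is.null(ppf_m)) NA_integer_ else
          lookup(ppf_m, regs$tcem),
        stringsAsFactors = FALSE)
      for (slot in slots) {
        allele <- as.character(geno[[slot]])
        zw <- wt_z(allele, wt_prot, width)
        zm <- zscale_map(predictors[[allele]], mut_prot, width, min_group)
        b <- base
        b$allele_slot <- slot
        b$allele <- allele
        b$z_wt <- unname(zw[as.character(regs$start)])
        b$z_mut <- unname(zm[as.character(regs$start)])
        rows[[length(rows) + 1L]] <- b
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stop("no mutations could be annotated", call. = FALSE)
  out$change_class <- classify_binding_change(out$z_wt, out$z_mut)
  rownames(out) <- NULL
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(case_id = character(), protein_id = character(),
               position = integer(), alt_aa = character(),
               reason = character(), stringsAsFactors = FALSE)
  out
}

# One row per distinct register window (drops the per-allele expansion).
distinct_windows <- function(annotations, width) {
  a <- annotations[annotations$width == width, , drop = FALSE]
  key <- paste(a$case_id, a$protein_id, a$position, a$alt_aa, a$start,
               sep = "\r")
  a[!duplicated(key), , drop = FALSE]
}

#' Compare mutant and wildtype TCEM frequencies
#'
#' Zero-inflated Poisson fits of the reference pentamer counts of
#' wildtype vs mutant TCEM, with absent/singleton/doubleton tallies.
#' By default only registers exposing the mutant are used (where the
#' motif actually changes); `subset = "all"` fits every register.
#'
#' @param annotations Long annotation table.
#' @param motif_class `"I"` (width 9) or `"II"` (width 15).
#' @param reference `"hppf"` or `"gippf"` counts.
#' @param subset `"exposed"` (default) or `"all"` registers.
#' @param min_records Minimum number of records (default 10).
#' @return List with `zip_wt`, `zip_mut`, `delta_lambda`
#'   (wildtype - mutant), `class_tally_wt`, `class_tally_mut`, `n`.
#' @export
compare_mut_wt <- function(annotations, motif_class = c("I", "II"),
                           reference = c("hppf", "gippf"),
                           subset = c("exposed", "all"),
                           min_records = 10L) {
  motif_class <- match.arg(motif_class)
  reference <- match.arg(reference)
  subset <- match.arg(subset)
  width <- if (motif_class == "I") 9L else 15L
  w <- distinct_windows(annotations, width)
  if (subset == "exposed") w <- w[w$exposed, , drop = FALSE]
  if (nrow(w) < min_records)
    stop("need at least ", min_records, " records, got ", nrow(w),
         call. = FALSE)
  cw <- w[[paste0(reference, "_wt")]]
  cm <- w[[paste0(reference, "_mut")]]
  if (anyNA(cw) || anyNA(cm))
    stop("reference counts unavailable: ", reference, call. = FALSE)
  zw <- fit_zip(cw, min_n = min_records)
  zm <- fit_zip(cm, min_n = min_records)
  list(zip_wt = zw, zip_mut = zm,
       delta_lambda = if (zw$degenerate || zm$degenerate) NA_real_ else
         zw$lambda_hat - zm$lambda_hat,
       class_tally_wt = table(frequency_class(cw)),
       class_tally_mut = table(frequency_class(cm)),
       n = nrow(w))
}

#' Mutant-aligned frequency profile
#'
#' Standardized (SHASH of log2(1 + count)) reference frequencies of the
#' mutant TCEM at each window offset relative to the mutation (offset 0
#' = window starting at the mutant). Offsets where the TCEM excludes
#' the mutant reproduce the wildtype profile exactly, so depression of
#' the mean at mutant-containing offsets isolates the effect of the
#' mutation. Offsets with no data are absent from the output, not zero.
#'
#' @inheritParams compare_mut_wt
#' @return Data frame with `offset`, `n`, `mean_z_mut`, `mean_z_wt`.
#' @export
mutant_alignment_profile <- function(annotations, motif_class = c("I", "II"),
                                     reference = c("hppf", "gippf")) {
  motif_class <- match.arg(motif_class)
  reference <- match.arg(reference)
  width <- if (motif_class == "I") 9L else 15L
  w <- distinct_windows(annotations, width)
  if (nrow(w) == 0L) {
    return(data.frame(offset = integer(), n = integer(),
                      mean_z_mut = numeric(), mean_z_wt = numeric()))
  }
  vw <- log2(1 + w[[paste0(reference, "_wt")]])
  vm <- log2(1 + w[[paste0(reference, "_mut")]])
  fit <- tryCatch(fit_shash(vw, fitted_on = "log2(1+count)"),
                  error = function(e) NULL)
  if (is.null(fit)) {
    # Degenerate wildtype distribution (e.g. every count identical on a
    # tiny reference): center on the wildtype value so depressions at
    # mutant offsets remain visible in raw log2 units.
    zw <- vw - mean(vw)
    zm <- vm - mean(vw)
  } else {
    zw <- standardize(vw, fit)
    zm <- standardize(vm, fit)
  }
  offs <- sort(unique(w$offset))
  data.frame(offset = offs,
             n = vapply(offs, function(o) sum(w$offset == o), integer(1)),
             mean_z_mut = vapply(offs, function(o) mean(zm[w$offset == o]),
                                 numeric(1)),
             mean_z_wt = vapply(offs, function(o) mean(zw[w$offset == o]),
                                numeric(1)))
}

# Window-level table with per-slot zscores widened into bitmap strings.
window_bitmaps <- function(annotations, threshold) {
  w9 <- window_level_class_i(annotations, threshold)
  a9 <- annotations[annotations$width == 9L, , drop = FALSE]
  key_all <- paste(a9$case_id, a9$protein_id, a9$position, a9$alt_aa,
                   a9$start, sep = "\r")
  key_w <- paste(w9$case_id, w9$protein_id, w9$position, w9$alt_aa, w9$start,
                 sep = "\r")
  w9$bitmap_mut <- vapply(key_w, function(k) {
    rowsk <- a9[key_all == k, ]
    z <- rowsk$z_mut[match(CLASS_I_SLOTS, rowsk$allele_slot)]
    bitmap_class_i(z, rowsk$exposed[1], threshold)
  }, character(1), USE.NAMES = FALSE)
  w9$bitmap_wt <- vapply(key_w, function(k) {
    rowsk <- a9[key_all == k, ]
    z <- rowsk$z_wt[match(CLASS_I_SLOTS, rowsk$allele_slot)]
    bitmap_class_i(z, rowsk$exposed[1], threshold)
  }, character(1), USE.NAMES = FALSE)
  w9
}

#' Run a full per-case analysis
#'
#' Orchestrates the pipeline on resolved inputs: annotates every
#' mutation against the PPF tables and genotype binding predictors,
#' then produces per-case down-selection tables, exposure fractions,
#' bitmap pattern diversity, mutant-vs-wildtype ZIP fits, and
#' cumulative binding curves with Weibull growth fits. All inputs are
#' validated before any computation. When `outdir` is given, writes
#' `annotations.tsv`, `windows.tsv`, `downselect.tsv` and
#' `summary.json`; outputs are deterministic for a fixed config.
#'
#' @param config Named list (or path to a YAML/JSON file) with entries:
#'   `proteome` (list of records or FASTA path), `mutations` (data
#'   frame or TSV path), `genotypes` (data frame or TSV path),
#'   `ppf_i`, `ppf_ii` (tables or [save_ppf()] paths; built from the
#'   proteome when omitted), optional `ppf_i_micro`/`ppf_ii_micro`,
#'   `predictors` (named list) or `truth_seed` (integer: deterministic
#'   synthetic truth functions are generated per allele),
#'   `zscale_threshold` (default -1), `dual_class_rule` (default
#'   `"mutation"`), `ppf_cap` (default 10), `outdir` (optional).
#' @return An object of class `case_run`: list with `annotations`,
#'   `windows`, `downselect`, `case_summaries`, `exclusions`, `config_used`.
#' @export
run_case <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the yaml package", call. = FALSE)
      yaml::read_yaml(config)
    } else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a file path", call. = FALSE)
  need <- function(name) {
    if (is.null(config[[name]]))
      stop("config error: missing required entry '", name, "'", call. = FALSE)
    config[[name]]
  }
  proteome <- need("proteome")
  if (is.character(proteome)) proteome <- read_proteome_fasta(proteome)
  mutations <- need("mutations")
  if (is.character(mutations)) mutations <- read_mutations_tsv(mutations)
  genotypes <- need("genotypes")
  if (is.character(genotypes)) genotypes <- read_genotypes_tsv(genotypes)
  resolve_ppf <- function(x, cls) {
    if (is.null(x)) return(build_ppf(proteome, cls, "config-proteome"))
    if (is.character(x)) return(load_ppf(x))
    stopifnot(inherits(x, "pentamer_table"))
    x
  }
  ppf_i <- resolve_ppf(config$ppf_i, "I")
  ppf_ii <- resolve_ppf(config$ppf_ii, "II")
  ppf_i_micro <- if (is.null(config$ppf_i_micro)) NULL else
    resolve_ppf(config$ppf_i_micro, "I")
  ppf_ii_micro <- if (is.null(config$ppf_ii_micro)) NULL else
    resolve_ppf(config$ppf_ii_micro, "II")
  threshold <- if (is.null(config$zscale_threshold)) -1 else
    config$zscale_threshold
  dual_rule <- if (is.null(config$dual_class_rule)) "mutation" else
    config$dual_class_rule
  ppf_cap <- if (is.null(config$ppf_cap)) 10L else as.integer(config$ppf_cap)
  predictors <- config$predictors
  alleles_used <- unique(unlist(genotypes[, c(CLASS_I_SLOTS, CLASS_II_SLOTS)]))
  if (is.null(predictors)) {
    seed0 <- as.integer(need("truth_seed"))
    is_drb <- grepl("^DRB", alleles_used)
    predictors <- stats::setNames(lapply(seq_along(alleles_used), function(i)
      gen_binding_truth(alleles_used[i], seed = seed0 + i,
                        width = if (is_drb[i]) 15L else 9L)),
      alleles_used)
  }
  missing_pred <- setdiff(alleles_used, names(predictors))
  if (length(missing_pred))
    stop("config error: no predictor for allele(s): ",
         paste(missing_pred, collapse = ", "), call. = FALSE)
  bad_cases <- setdiff(unique(mutations$case_id), genotypes$case_id)
  if (length(bad_cases))
    stop("config error: mutations reference unknown case(s): ",
         paste(bad_cases, collapse = ", "), call. = FALSE)

  ann <- annotate_mutations(proteome, mutations, genotypes, predictors,
                            ppf_i, ppf_ii, ppf_i_micro, ppf_ii_micro)
  windows <- window_bitmaps(ann, threshold)
  cases <- unique(ann$case_id)
  ds_rows <- list()
  summaries <- list()
  for (cs in cases) {
    a_case <- ann[ann$case_id == cs, , drop = FALSE]
    w_case <- windows[windows$case_id == cs, , drop = FALSE]
    ds <- downselect(a_case, threshold, dual_rule)
    expo <- exposure_fraction(a_case, threshold)
    div <- pattern_diversity(w_case$bitmap_mut)
    zips <- tryCatch(compare_mut_wt(a_case, "I", "hppf"),
                     error = function(e) NULL)
    curve <- tryCatch(cumulative_fraction_by_ppf(a_case, ppf_cap, threshold),
                      error = function(e) NULL)
    wb <- if (!is.null(curve) && stats::sd(curve$cumulative_fraction) > 0)
      tryCatch(fit_weibull_growth(curve$hppf, curve$cumulative_fraction,
                                  bound_a = TRUE),
               error = function(e) NULL) else NULL
    ds_rows[[cs]] <- cbind(data.frame(case_id = cs), as.data.frame(ds))
    summaries[[cs]] <- list(
      case_id = cs, downselect = as.list(as.data.frame(ds)),
      exposure = expo[c("event_fraction", "peptide_fraction", "n_events",
                        "n_bound_peptides")],
      diversity = div,
      zip = if (is.null(zips)) NULL else list(
        lambda_wt = zips$zip_wt$lambda_hat, pi_wt = zips$zip_wt$pi_hat,
        lambda_mut = zips$zip_mut$lambda_hat, pi_mut = zips$zip_mut$pi_hat,
        delta_lambda = zips$delta_lambda),
      weibull = if (is.null(wb)) NULL else wb[c("a", "b", "c", "rmse")],
      cumulative_curve = curve)
  }
  ds_all <- do.call(rbind, ds_rows)
  rownames(ds_all) <- NULL
  result <- list(annotations = ann, windows = windows, downselect = ds_all,
                 case_summaries = summaries,
                 exclusions = attr(ann, "exclusions"),
                 config_used = list(zscale_threshold = threshold,
                                    dual_class_rule = dual_rule,
                                    ppf_cap = ppf_cap,
                                    n_proteins = length(proteome),
                                    n_mutations = nrow(mutations),
                                    package_version =
                                      as.character(utils::packageVersion("tcemscan"))))
  class(result) <- "case_run"
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$outdir, f)
    ann_out <- ann
    attr(ann_out, "exclusions") <- NULL
    utils::write.table(ann_out, out("annotations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(windows, out("windows.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(ds_all, out("downselect.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(config = result$config_used, cases = summaries,
           exclusions = result$exclusions),
      out("summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    result$paths <- vapply(c("annotations.tsv", "windows.tsv",
                             "downselect.tsv", "summary.json"), out,
                           character(1))
  }
  result
}

#' @export
print.case_run <- function(x, ...) {
  cat(sprintf("case_run: %d cases, %d annotation rows, %d exclusions\n",
              length(x$case_summaries), nrow(x$annotations),
              nrow(x$exclusions)))
  invisible(x)
}
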