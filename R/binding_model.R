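#' Packaged amino-acid physical property table
#'
#' Eight published per-residue scales (Kyte-Doolittle hydropathy,
#' molecular weight, side-chain volume, Grantham polarity, isoelectric
#' point, Chou-Fasman helix and sheet propensities, net charge at
#' pH 7) used as the raw inputs to the principal-component descriptors.
#'
#' @return Numeric matrix, 20 residues x 8 properties, rownames are the
#'   one-letter codes.
#' @export
aa_property_table <- function() {
  path <- system.file("extdata", "aa_properties.tsv", package = "tcemscan",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$residue
  m[aa_alphabet(), , drop = FALSE]
}

#' Principal-component amino-acid descriptors
#'
#' Summarizes a per-residue physical property table into `n_components`
#' orthogonal, unit-variance descriptors by PCA of the standardized
#' properties (the Wold-style QSAR encoding). Component signs are fixed
#' so the loading with the largest magnitude is positive, making the
#' descriptors deterministic for a given table.
#'
#' @param property_table Numeric matrix, one row per canonical residue
#'   (rownames = one-letter codes). Defaults to [aa_property_table()].
#' @param n_components Number of components to keep (default 3).
#' @return An object of class `aa_descriptors`: a 20 x d score matrix
#'   with the loading matrix attached as attribute `loadings`.
#' @export
compute_descriptors <- function(property_table = aa_property_table(),
                                n_components = 3L) {
  if (!all(aa_alphabet() %in% rownames(property_table)))
    stop("property_table must contain a row for every canonical residue",
         call. = FALSE)
  property_table <- property_table[aa_alphabet(), , drop = FALSE]
  if (ncol(property_table) < n_components)
    stop("need at least n_components properties", call. = FALSE)
  sds <- apply(property_table, 2, stats::sd)
  pc <- stats::prcomp(property_table[, sds > 0, drop = FALSE],
                      center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(pc$rotation))
  if (k < n_components)
    stop("property table supports only ", k, " components", call. = FALSE)
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  # unit variance per component, deterministic sign
  for (j in seq_len(k)) {
    s <- stats::sd(scores[, j])
    if (s > 0) scores[, j] <- scores[, j] / s
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(scores, loadings = load, class = c("aa_descriptors", "matrix"))
}

#' Encode a peptide as a descriptor vector
#'
#' Concatenates the per-position descriptor vectors, giving a numeric
#' vector of length `nchar(peptide) * d`.
#'
#' @param peptide Unambiguous residue string.
#' @param descriptors An [compute_descriptors()] object.
#' @return Numeric vector.
#' @export
encode_peptide <- function(peptide, descriptors) {
  assert_peptide(peptide, NULL, "peptide")
  encode_peptides(peptide, descriptors)[1, ]
}

# Matrix encoding of many equal-length peptides: n x (width * d).
encode_peptides <- function(peptides, descriptors) {
  widths <- nchar(peptides)
  if (length(unique(widths)) != 1L)
    stop("peptides must share one width", call. = FALSE)
  width <- widths[1]
  ok <- is_valid_peptide(peptides)
  if (!all(ok))
    stop("peptide contains non-canonical letters: ",
         paste(utils::head(peptides[!ok], 3), collapse = ", "), call. = FALSE)
  d <- ncol(descriptors)
  chars <- matrix(unlist(strsplit(peptides, "", fixed = TRUE)),
                  nrow = width)
  idx <- matrix(match(chars, aa_alphabet()), nrow = width)
  out <- matrix(0, nrow = length(peptides), ncol = width * d)
  desc <- unclass(descriptors)
  for (p in seq_len(width)) {
    out[, ((p - 1L) * d + 1L):(p * d)] <- desc[idx[p, ], , drop = FALSE]
  }
  colnames(out) <- paste0("p", rep(seq_len(width), each = d), "_",
                          rep(colnames(descriptors), width))
  out
}

#' Train a bagged binding-affinity ensemble for one allele
#'
#' Trains `n_candidates` base regressors of Ln(ic50) on bootstrap
#' resamples of the training examples (n-of-n with replacement) and
#' keeps the `n_keep` members with the best out-of-bag generalization
#' (lowest OOB RMSE, ties broken by higher OOB R-squared). The default
#' base learner is a single-hidden-layer network ([nnet::nnet()]) over
#' the peptide descriptor encoding; `learner = "lm"` uses linear
#' regression instead. Training is refused below `min_examples`
#' examples. Deterministic given `seed`.
#'
#' @param examples Data frame with columns `allele`, `peptide`,
#'   `ic50_nM` (all one allele, one peptide width).
#' @param n_candidates Candidate pool size (default 300).
#' @param n_keep Ensemble size retained (default 25).
#' @param seed Integer RNG seed.
#' @param descriptors Descriptor set, default [compute_descriptors()].
#' @param learner `"nnet"` or `"lm"`.
#' @param hidden Hidden units for the network learner (default 8).
#' @param min_examples Training floor (default 200).
#' @return An object of class `ensemble_model`.
#' @export
train_ensemble <- function(examples, n_candidates = 300L, n_keep = 25L,
                           seed = 1L, descriptors = compute_descriptors(),
                           learner = c("nnet", "lm"), hidden = 8L,
                           min_examples = 200L) {
  learner <- match.arg(learner)
  req <- c("allele", "peptide", "ic50_nM")
  if (!all(req %in% names(examples)))
    stop("examples must have columns ", paste(req, collapse = ", "), call. = FALSE)
  if (any(examples$ic50_nM <= 0)) stop("ic50_nM must be positive", call. = FALSE)
  allele <- unique(examples$allele)
  if (length(allele) != 1L)
    stop("examples must cover exactly one allele", call. = FALSE)
  n <- nrow(examples)
  if (n < min_examples)
    stop("training refused: ", n, " examples for ", allele,
         " below the floor of ", min_examples, call. = FALSE)
  if (n_keep > n_candidates) stop("n_keep must not exceed n_candidates", call. = FALSE)
  width <- nchar(examples$peptide[1])
  X <- encode_peptides(examples$peptide, descriptors)
  y <- log(examples$ic50_nM)
  set.seed(as.integer(seed))
  members <- vector("list", n_candidates)
  oob_rmse <- rep(Inf, n_candidates)
  oob_r2 <- rep(-Inf, n_candidates)
  const_y <- stats::sd(y) == 0
  for (b in seq_len(n_candidates)) {
    idx <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), idx)
    if (learner == "lm") {
      df <- data.frame(y = y[idx], X[idx, , drop = FALSE])
      fit <- stats::lm(y ~ ., data = df)
      members[[b]] <- list(kind = "lm", fit = fit)
      pred_oob <- if (length(oob))
        stats::predict(fit, data.frame(X[oob, , drop = FALSE])) else numeric()
    } else {
      fit <- nnet::nnet(X[idx, , drop = FALSE], y[idx], size = hidden,
                        linout = TRUE, decay = 1e-3, maxit = 300,
                        trace = FALSE, MaxNWts = 5000)
      members[[b]] <- list(kind = "nnet", fit = fit)
      pred_oob <- if (length(oob))
        as.numeric(stats::predict(fit, X[oob, , drop = FALSE])) else numeric()
    }
    if (length(oob)) {
      res <- y[oob] - pred_oob
      oob_rmse[b] <- sqrt(mean(res^2))
      ss_tot <- sum((y[oob] - mean(y[oob]))^2)
      oob_r2[b] <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else
        (if (const_y) 1 else -Inf)
    }
  }
  keep <- order(oob_rmse, -oob_r2)[seq_len(n_keep)]
  structure(list(allele = allele, width = width,
                 members = members[keep],
                 selection_stats = data.frame(candidate = keep,
                                              oob_rmse = oob_rmse[keep],
                                              oob_r2 = oob_r2[keep]),
                 descriptors = descriptors, learner = learner,
                 seed = as.integer(seed), n_train = n),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("ensemble_model for %s: %d %s members (width %d, %d trainers)\n",
              x$allele, length(x$members), x$learner, x$width, x$n_train))
  invisible(x)
}

member_predict <- function(member, X) {
  if (member$kind == "lm") {
    as.numeric(stats::predict(member$fit, data.frame(X)))
  } else {
    as.numeric(stats::predict(member$fit, X))
  }
}

#' Predict binding affinity with an ensemble
#'
#' Ensemble mean and standard deviation of Ln(ic50) over the retained
#' members (population standard deviation over members; 0 for a
#' single-member ensemble).
#'
#' @param object An `ensemble_model`.
#' @param peptides Character vector of peptides of the model's width.
#' @param ... Unused.
#' @return Data frame with `allele`, `peptide`, `mean_ln_ic50`,
#'   `sd_ln_ic50`.
#' @export
predict.ensemble_model <- function(object, peptides, ...) {
  widths <- unique(nchar(peptides))
  if (!identical(widths, object$width))
    stop("peptide width ", paste(widths, collapse = ","),
         " does not match model width ", object$width, call. = FALSE)
  X <- encode_peptides(peptides, object$descriptors)
  preds <- vapply(object$members, function(mem) member_predict(mem, X),
                  numeric(length(peptides)))
  preds <- matrix(preds, nrow = length(peptides))
  m <- rowMeans(preds)
  k <- ncol(preds)
  sdv <- if (k > 1) sqrt(rowMeans((preds - m)^2) * k / (k - 1)) else
    rep(0, length(peptides))
  data.frame(allele = object$allele, peptide = peptides,
             mean_ln_ic50 = m, sd_ln_ic50 = sdv, stringsAsFactors = FALSE)
}

#' Predict binding over every clean window of a protein
#'
#' @param model A predictor accepted by [predict_binding()].
#' @param protein A [protein_record()].
#' @param width Window width (9 or 15).
#' @return Data frame with `protein_id`, `start`, `peptide`, `allele`,
#'   `mean_ln_ic50`, `sd_ln_ic50`, `ln_ic50` (alias of the mean, ready
#'   for [zscale_within_protein()]).
#' @export
predict_protein <- function(model, protein, width) {
  win <- window_peptides(protein, width)
  if (nrow(win) == 0L) {
    return(data.frame(protein_id = character(), start = integer(),
                      peptide = character(), allele = character(),
                      mean_ln_ic50 = numeric(), sd_ln_ic50 = numeric(),
                      ln_ic50 = numeric(), stringsAsFactors = FALSE))
  }
  pred <- predict_binding(model, win$peptide)
  data.frame(protein_id = win$protein_id, start = win$start,
             peptide = win$peptide, allele = pred$allele,
             mean_ln_ic50 = pred$mean_ln_ic50, sd_ln_ic50 = pred$sd_ln_ic50,
             ln_ic50 = pred$mean_ln_ic50, stringsAsFactors = FALSE)
}

#' Pluggable binding-predictor interface
#'
#' Any object that can map peptides to an ensemble mean and standard
#' deviation of Ln(ic50) can stand behind the pipeline: trained
#' [train_ensemble()] models, synthetic [gen_binding_truth()] energy
#' functions, or a plain function returning mean values.
#'
#' @param predictor The predictor object.
#' @param peptides Character vector of peptides.
#' @return Data frame with `allele`, `peptide`, `mean_ln_ic50`,
#'   `sd_ln_ic50`.
#' @export
predict_binding <- function(predictor, peptides) {
  UseMethod("predict_binding")
}

#' @export
predict_binding.ensemble_model <- function(predictor, peptides) {
  stats::predict(predictor, peptides)
}

#' @export
predict_binding.function <- function(predictor, peptides) {
  m <- predictor(peptides)
  data.frame(allele = "custom", peptide = peptides,
             mean_ln_ic50 = as.numeric(m), sd_ln_ic50 = 0,
             stringsAsFactors = FALSE)
}
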