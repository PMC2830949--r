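#' Rank-invariant normalisation of array intensities
#'
#' Scales every non-reference sample onto the reference sample's intensity
#' scale using a rank-invariant probe set: starting from all probes, probes
#' whose within-set rank differs between sample and reference by less than
#' `rank_tol` times the current set size are kept, and the selection is
#' iterated to a fixed point. The scaling factor is the ratio of trimmed
#' means over the final invariant set (reference over sample), so probes
#' perturbed in only one channel do not distort the fit. The reference sample
#' is returned unchanged.
#'
#' @param x An `expression_matrix` of raw intensities.
#' @param reference_sample Sample id to normalise against.
#' @param rank_tol Rank-difference tolerance as a fraction of the current
#'   invariant-set size (default 0.05).
#' @param trim Trim fraction for the trimmed means (default 0.1).
#' @param min_set Minimum invariant-set size; falling below it is a
#'   normalisation error (default 100).
#' @param max_iter Iteration cap (default 50).
#' @return An `expression_matrix` with attributes `scale_factors` (named
#'   numeric) and `invariant_sets` (named list of probe ids).
#' @export
rank_invariant_normalize <- function(x, reference_sample, rank_tol = 0.05,
                                     trim = 0.1, min_set = 100, max_iter = 50) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!reference_sample %in% colnames(x$values)) {
    stop("reference sample '", reference_sample, "' not in matrix", call. = FALSE)
  }
  ref <- x$values[, reference_sample]
  out <- x$values
  factors <- stats::setNames(rep(1, ncol(out)), colnames(out))
  sets <- stats::setNames(vector("list", ncol(out)), colnames(out))
  sets[[reference_sample]] <- rownames(out)
  for (s in setdiff(colnames(out), reference_sample)) {
    smp <- x$values[, s]
    set <- seq_along(ref)
    for (iter in seq_len(max_iter)) {
      r_ref <- rank(ref[set], ties.method = "average")
      r_smp <- rank(smp[set], ties.method = "average")
      keep <- abs(r_ref - r_smp) < rank_tol * length(set)
      if (all(keep)) break
      set <- set[keep]
      if (length(set) < min_set) {
        stop("normalisation error: rank-invariant set for sample '", s,
             "' fell below ", min_set, " probes", call. = FALSE)
      }
    }
    f <- mean(ref[set], trim = trim) / mean(smp[set], trim = trim)
    out[, s] <- smp * f
    factors[[s]] <- f
    sets[[s]] <- rownames(out)[set]
  }
  res <- expression_matrix(out, x$groups)
  attr(res, "scale_factors") <- factors
  attr(res, "invariant_sets") <- sets
  res
}

#' Empirical detection scores against negative-control probes
#'
#' For every gene and sample, the detection score is the fraction of that
#' sample's negative-control intensities lying strictly below the gene's
#' intensity, with ties counted half — a one-sided empirical exceedance
#' probability in `[0, 1]`. A gene "detected at > 0.99" therefore exceeds
#' more than 99% of background probes.
#'
#' @param x Gene x sample `expression_matrix`.
#' @param neg_controls Negative-control probe x sample `expression_matrix`
#'   over the same samples; at least `min_controls` probes per sample.
#' @param min_controls Minimum number of negative controls (default 20).
#' @return A gene x sample numeric matrix of scores in `[0, 1]`, with the
#'   control count in `attr(, "n_neg")`.
#' @export
detection_scores <- function(x, neg_controls, min_controls = 20) {
  stopifnot(inherits(x, "expression_matrix"), inherits(neg_controls, "expression_matrix"))
  samples <- colnames(x$values)
  if (!all(samples %in% colnames(neg_controls$values))) {
    stop("negative controls missing for some samples", call. = FALSE)
  }
  n_neg <- nrow(neg_controls$values)
  if (n_neg < min_controls) {
    stop("need at least ", min_controls, " negative-control probes, got ", n_neg,
         call. = FALSE)
  }
  scores <- matrix(NA_real_, nrow(x$values), length(samples),
                   dimnames = dimnames(x$values))
  for (s in samples) {
    neg <- sort(neg_controls$values[, s])
    v <- x$values[, s]
    n_leq <- findInterval(v, neg)                      # controls <= v
    n_lt <- findInterval(v, neg, left.open = TRUE)     # controls <  v
    scores[, s] <- (n_lt + 0.5 * (n_leq - n_lt)) / n_neg
  }
  attr(scores, "n_neg") <- n_neg
  scores
}

#' Technical variance model from negative-control probes
#'
#' An intensity-dependent technical variance `v(x) = sigma0^2 + (cv * x)^2`:
#' an additive background floor estimated as the mean per-sample SD of the
#' negative-control probes, plus a configurable intensity-proportional term.
#' This is the error model behind the pairwise differential-expression score
#' (the discovery design has one array per sample, so only technical
#' variation is in play).
#'
#' @param neg_controls Negative-control `expression_matrix`.
#' @param cv Intensity-proportional coefficient of variation (default 0.1).
#' @return A `variance_model`: list with `sigma0`, `cv`, and the function
#'   `v(x)`.
#' @export
fit_variance_model <- function(neg_controls, cv = 0.1) {
  stopifnot(inherits(neg_controls, "expression_matrix"))
  sigma0 <- mean(apply(neg_controls$values, 2, stats::sd))
  structure(list(sigma0 = sigma0, cv = cv,
                 v = function(x) sigma0^2 + (cv * x)^2),
            class = "variance_model")
}

#' Pairwise differential-expression score
#'
#' For one patient array against one control array, per gene:
#' `DS = 10 * sign(x_p - x_c) * (-log10 p)` where `p` is the two-sided
#' z-test p-value of the intensity difference under the technical variance
#' model, `z = (x_p - x_c) / sqrt(v(x_p) + v(x_c))`. `DS > 50` is equivalent
#' to `p < 1e-5` with the patient up; `DS > 100` to `p < 1e-10`. Computed on
#' the log scale of p throughout, so extreme scores do not underflow.
#'
#' @param patient_values,control_values Positive numeric vectors (same genes,
#'   same order).
#' @param variance_model A [fit_variance_model()] result.
#' @return Numeric vector of signed scores.
#' @export
diff_score <- function(patient_values, control_values, variance_model) {
  stopifnot(inherits(variance_model, "variance_model"),
            length(patient_values) == length(control_values))
  if (any(patient_values <= 0) || any(control_values <= 0)) {
    stop("diff_score requires positive intensities", call. = FALSE)
  }
  d <- patient_values - control_values
  z <- d / sqrt(variance_model$v(patient_values) + variance_model$v(control_values))
  log10_p <- (stats::pnorm(-abs(z), log.p = TRUE) + log(2)) / log(10)
  10 * sign(d) * (-log10_p)
}

#' Threshold set for tiered candidate selection
#'
#' @param ds Differential-expression score bound of the standard tier
#'   (default 50, i.e. p < 1e-5).
#' @param ds_strict Score bound of the strict tier (default 100, p < 1e-10).
#' @param detection Detection-score bound of the strict tier (default 0.99).
#' @param min_fold Minimum fold change, direction-adjusted (default 2; genes
#'   below twofold in either direction are excluded).
#' @param detection_max Detection bound of the standard tier. `NULL` (the
#'   default) means the empirical maximum `1 - 1/n_neg` — the only way an
#'   exceedance score reads "1" — but a numeric bound (e.g. 0.99) may be
#'   substituted to run a single-threshold detection rule across both tiers.
#' @return A `candidate_thresholds` list.
#' @export
candidate_thresholds <- function(ds = 50, ds_strict = 100, detection = 0.99,
                                 min_fold = 2, detection_max = NULL) {
  if (ds <= 0 || ds_strict <= 0 || detection <= 0 || min_fold <= 0) {
    stop("configuration error: thresholds must be positive", call. = FALSE)
  }
  structure(list(ds = ds, ds_strict = ds_strict, detection = detection,
                 min_fold = min_fold, detection_max = detection_max),
            class = "candidate_thresholds")
}

#' Tiered candidate-gene selection for a one-patient discovery design
#'
#' Compares the single patient array against each control array in turn and
#' selects genes by three tiers:
#' \describe{
#'   \item{strict}{`|DS| >` `ds_strict` and detection `>` `detection` (both
#'     samples) and direction-adjusted fold `>=` `min_fold`, in *all*
#'     comparisons, same direction throughout.}
#'   \item{standard}{`|DS| >` `ds` and detection at the standard bound (see
#'     `detection_max`) and fold `>=` `min_fold`, in all comparisons, same
#'     direction.}
#'   \item{relaxed}{the standard criteria hold in exactly
#'     `length(controls) - 1` comparisons (the "2 of 3 controls" case).}
#' }
#' A gene meeting both the strict and standard criteria reports the strict
#' tier. Down-regulated genes qualify through the reciprocal fold. Output is
#' sorted by minimum `|DS|` descending, ties broken by gene id.
#'
#' @param x Normalised `expression_matrix`.
#' @param detection Detection-score matrix from [detection_scores()].
#' @param patient Patient sample id (exactly one).
#' @param controls Character vector of control sample ids (>= 2).
#' @param thresholds A [candidate_thresholds()].
#' @param variance_model A [fit_variance_model()] result for the DS z-test.
#' @return A `data.frame` with columns `gene_id`, `tier`, `min_ds`,
#'   `min_fold`, `n_consistent`, plus per-comparison `ds_*` and `fold_*`
#'   columns.
#' @export
select_candidates <- function(x, detection, patient, controls, thresholds,
                              variance_model) {
  stopifnot(inherits(x, "expression_matrix"),
            inherits(thresholds, "candidate_thresholds"))
  if (length(patient) != 1L) stop("exactly one patient sample required", call. = FALSE)
  if (length(controls) < 2L) stop("at least two control samples required", call. = FALSE)
  n_neg <- attr(detection, "n_neg")
  det_max <- thresholds$detection_max %||%
    (if (is.null(n_neg)) stop("detection matrix lacks n_neg; pass detection_max",
                              call. = FALSE) else 1 - 1 / n_neg)
  xp <- x$values[, patient]
  per_control <- function(f) {
    m <- vapply(controls, f, numeric(nrow(x$values)))
    matrix(m, nrow = nrow(x$values), dimnames = list(rownames(x$values), controls))
  }
  ds <- per_control(function(s) diff_score(xp, x$values[, s], variance_model))
  fold <- per_control(function(s) xp / x$values[, s])
  adj_fold <- ifelse(fold >= 1, fold, 1 / fold)
  det_p <- detection[, patient]
  # standard-tier detection bound carries a tiny slack for float comparison
  pass_det_std <- (det_p >= det_max - 1e-12) &
    per_control(function(s) as.numeric(detection[, s] >= det_max - 1e-12))
  pass_det_strict <- (det_p > thresholds$detection) &
    per_control(function(s) as.numeric(detection[, s] > thresholds$detection))
  pass_fold <- adj_fold >= thresholds$min_fold
  pass_std <- (abs(ds) > thresholds$ds) & pass_det_std & pass_fold
  pass_strict <- (abs(ds) > thresholds$ds_strict) & pass_det_strict & pass_fold
  same_dir <- function(pass) {
    # all passing comparisons share the patient-vs-control direction
    up <- rowSums(pass & ds > 0)
    dn <- rowSums(pass & ds < 0)
    pmax(up, dn) == rowSums(pass)
  }
  n_std <- rowSums(pass_std)
  all_std <- n_std == length(controls) & same_dir(pass_std)
  all_strict <- rowSums(pass_strict) == length(controls) & same_dir(pass_strict)
  relaxed <- n_std == length(controls) - 1L & same_dir(pass_std)
  tier <- rep(NA_character_, nrow(x$values))
  tier[relaxed] <- "relaxed"
  tier[all_std] <- "standard"
  tier[all_strict] <- "strict"
  sel <- which(!is.na(tier))
  out <- data.frame(gene_id = rownames(x$values)[sel],
                    tier = tier[sel],
                    min_ds = apply(abs(ds[sel, , drop = FALSE]), 1, min),
                    min_fold = apply(adj_fold[sel, , drop = FALSE], 1, min),
                    n_consistent = n_std[sel],
                    stringsAsFactors = FALSE)
  for (j in seq_along(controls)) {
    out[[paste0("ds_", controls[j])]] <- ds[sel, j]
    out[[paste0("fold_", controls[j])]] <- fold[sel, j]
  }
  out <- out[order(-out$min_ds, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
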