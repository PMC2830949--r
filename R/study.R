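#' Simulate the validation cohort and quantify it
#'
#' One call reproducing the study's validation design in silico: a qPCR
#' plate for the marker panel over 8 missense + 4 truncating patients and 5
#' controls (configurable), with each gene's true fold change set to its
#' reported per-class ratio, followed by standard-curve quantification. The
#' result is the quantity matrix the group contrasts and WAPDG consume.
#'
#' @param seed Integer seed for the whole cohort.
#' @param genes Marker genes to assay (default [upregulated_panel()]).
#' @param group_sizes Cohort composition (default 8/4/5).
#' @param cv_within Within-group coefficient of variation (default 0.25).
#' @param ... Further arguments to [simulate_qpcr_experiment()].
#' @return A list: `matrix` (the `expression_matrix` of quantities),
#'   `plate`, `quantities` (long table).
#' @export
simulate_validation_cohort <- function(seed,
                                       genes = upregulated_panel(),
                                       group_sizes = c(missense = 8L,
                                                       truncating = 4L,
                                                       control = 5L),
                                       cv_within = 0.25, ...) {
  classes <- intersect(c("missense", "truncating"), names(group_sizes))
  cfg <- sim_config(n_genes = 0,
                    spike_table = marker_spike_table(genes, classes = classes),
                    group_sizes = group_sizes,
                    cv_within = cv_within,
                    seed = seed)
  plate <- simulate_qpcr_experiment(cfg, ...)
  quantities <- quantify_plate(plate)
  list(matrix = quantities_to_matrix(quantities, plate$groups),
       plate = plate, quantities = quantities)
}

#' Simulate a one-patient discovery array and select candidate genes
#'
#' The discovery design in silico: one patient array against three control
#' arrays, `n_background` unspiked genes plus `n_spikes` truly deregulated
#' genes at fold `spike_fold`, rank-invariant normalisation against the
#' first control, detection against the negative-control probes, and the
#' tiered candidate selection. Within-array variation is technical
#' (default CV 0.10), matching the variance model of the pairwise
#' differential-expression score.
#'
#' @param seed Integer seed.
#' @param n_background Background gene count (default 10000).
#' @param n_spikes Number of truly deregulated genes (default 21).
#' @param spike_fold True fold change of the spikes (default 4).
#' @param cv_within Within-array technical CV (default 0.1).
#' @param thresholds A [candidate_thresholds()]; the default applies the
#'   single-criterion chain (DS > 50, detection > 0.99 for both tiers,
#'   fold >= 2).
#' @return A list: `candidates` (the selection table), `spiked` (the true
#'   spike ids), `arr` (the simulated experiment).
#' @export
simulate_discovery_selection <- function(seed,
                                         n_background = 10000,
                                         n_spikes = 21,
                                         spike_fold = 4,
                                         cv_within = 0.1,
                                         thresholds = candidate_thresholds(detection_max = 0.99)) {
  spiked <- sprintf("SPIKE%02d", seq_len(n_spikes))
  cfg <- sim_config(n_genes = n_background, n_neg_controls = 1000,
                    spike_table = data.frame(gene_id = spiked,
                                             group = "truncating",
                                             fold = spike_fold),
                    group_sizes = c(truncating = 1L, control = 3L),
                    cv_within = cv_within, seed = seed)
  arr <- simulate_array_experiment(cfg)
  controls <- names(arr$expr$groups)[arr$expr$groups == "control"]
  patient <- names(arr$expr$groups)[arr$expr$groups == "truncating"]
  norm <- rank_invariant_normalize(arr$expr, controls[1])
  det <- detection_scores(norm, arr$neg_controls)
  vm <- fit_variance_model(arr$neg_controls, cv = cv_within)
  list(candidates = select_candidates(norm, det, patient, controls, thresholds, vm),
       spiked = spiked, arr = arr)
}

#' Replicate estimation of a marker's LS-mean expression ratio
#'
#' Repeatedly simulates a qPCR cohort with one marker spiked at its
#' reported per-class ratio, quantifies it, fits the one-way model and
#' returns the estimated patient-class/control LS-mean ratios — the Monte
#' Carlo view of how faithfully the qPCR + contrast path recovers a known
#' effect size.
#'
#' @param gene Marker gene id (must be in [kdm5c_marker_ratios()]).
#' @param class Patient class (default `"missense"`).
#' @param n_reps Number of simulation replicates (default 200).
#' @param seed Integer base seed; replicate `i` uses an independent
#'   substream.
#' @param group_sizes Cohort (default 8 patients of `class` vs 5 controls).
#' @param cv_within Within-group CV (default 0.25).
#' @return Numeric vector of `n_reps` estimated ratios, with the generator
#'   truth in `attr(, "true_fold")`.
#' @export
estimate_marker_ratio <- function(gene, class = "missense", n_reps = 200,
                                  seed = 1L,
                                  group_sizes = NULL, cv_within = 0.25) {
  m <- kdm5c_marker_ratios()
  if (!gene %in% m$gene_id) stop("unknown marker gene '", gene, "'", call. = FALSE)
  true_fold <- m[[paste0("ratio_", class)]][m$gene_id == gene]
  group_sizes <- group_sizes %||% stats::setNames(c(8L, 5L), c(class, "control"))
  ratios <- vapply(seq_len(n_reps), function(i) {
    cfg <- sim_config(n_genes = 0,
                      spike_table = data.frame(gene_id = gene, group = class,
                                               fold = true_fold),
                      group_sizes = group_sizes, cv_within = cv_within,
                      seed = stage_seed(seed, "replicate", i))
    plate <- simulate_qpcr_experiment(cfg)
    q <- quantify_plate(plate)
    fit <- fit_oneway(stats::setNames(q$quantity, q$sample_id)[names(plate$groups)],
                      plate$groups)
    contrast(fit, class, "control", gene_id = gene)$ratio
  }, numeric(1))
  attr(ratios, "true_fold") <- true_fold
  ratios
}
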