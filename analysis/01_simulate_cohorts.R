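#!/usr/bin/env Rscript

# Simulate the study's three datasets and write them under results/data/:
#   * a discovery bead-array experiment: one patient (truncating mutation)
#     vs three controls, 10,000 background genes, 21 truly deregulated
#     genes spiked at fold 4, 1,000 negative-control probes;
#   * a validation qPCR cohort: 8 missense + 4 truncating patients vs 5
#     controls, the 12 marker genes spiked at their reported per-class
#     ratios, within-group CV 0.25;
#   * four blind samples grown "elsewhere": NP1 (patient-level expression),
#     MRX13 (intermediate expression, emulating a mild mutation effect),
#     NC1 and NC2 (control-level expression).

suppressPackageStartupMessages(library(wapdgkit))

seed <- 20260929L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## discovery arrays ------------------------------------------------------------
disc_cfg <- sim_config(
  n_genes = 10000, n_neg_controls = 1000,
  spike_table = data.frame(gene_id = sprintf("SPIKE%02d", 1:21),
                           group = "truncating", fold = 4),
  group_sizes = c(truncating = 1L, control = 3L),
  cv_within = 0.1,  # technical array-to-array variation; one cell line per array
  seed = stage_seed(seed, "array"))
arr <- simulate_array_experiment(disc_cfg)
write_expression_tsv(arr$expr, file.path(out, "discovery_expr.tsv"))
write_expression_tsv(arr$neg_controls, file.path(out, "discovery_neg.tsv"))
write_sample_sheet(arr$expr, file.path(out, "discovery_samples.tsv"))
write_sim_config(disc_cfg, file.path(out, "discovery_config.yaml"))
message("discovery: ", nrow(arr$expr$values), " genes x ",
        ncol(arr$expr$values), " arrays, 21 spiked at fold 4")

## validation qPCR cohort ------------------------------------------------------
val_cfg <- sim_config(
  n_genes = 0,
  spike_table = marker_spike_table(),   # all 12 markers, both mutation classes
  group_sizes = c(missense = 8L, truncating = 4L, control = 5L),
  cv_within = 0.25,
  seed = stage_seed(seed, "qpcr"))
plate <- simulate_qpcr_experiment(val_cfg)
write_qpcr_plate(plate, file.path(out, "validation_plate.tsv"),
                 file.path(out, "validation_standards.tsv"))
write_sample_sheet(plate$groups, file.path(out, "validation_samples.tsv"))
utils::write.table(plate$truth, file.path(out, "validation_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("validation: ", length(unique(plate$measurements$gene_id)),
        " marker assays x ", length(plate$groups), " samples in triplicate")

## blind samples ---------------------------------------------------------------
# Each blind sample is simulated as its own unknown-group plate so that its
# true expression level can differ per sample; MRX13 sits at the geometric
# midpoint between patient and control levels (a mild-impairment profile).
markers <- kdm5c_marker_ratios()
blind_specs <- list(
  NP1   = markers$ratio_missense,
  MRX13 = sqrt(markers$ratio_missense),
  NC1   = rep(1, nrow(markers)),
  NC2   = rep(1, nrow(markers)))
blind_meas <- list(); blind_std <- list()
for (i in seq_along(blind_specs)) {
  id <- names(blind_specs)[i]
  cfg <- sim_config(
    n_genes = 0,
    spike_table = data.frame(gene_id = markers$gene_id, group = "unknown",
                             fold = blind_specs[[i]]),
    group_sizes = c(unknown = 1L),
    cv_within = 0.25,
    seed = stage_seed(seed, "replicate", i))
  bp <- simulate_qpcr_experiment(cfg)
  bp$measurements$sample_id <- id
  blind_meas[[id]] <- bp$measurements
  bp$standards$plate_id <- id
  blind_std[[id]] <- bp$standards
}
utils::write.table(do.call(rbind, blind_meas), file.path(out, "blind_plate.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(do.call(rbind, blind_std), file.path(out, "blind_standards.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_sample_sheet(stats::setNames(rep("unknown", 4), names(blind_specs)),
                   file.path(out, "blind_samples.tsv"))
message("blind study: ", paste(names(blind_specs), collapse = ", "))
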