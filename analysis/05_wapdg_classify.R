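#!/usr/bin/env Rscript

# WAPDG on the validation cohort and blind classification:
#   * per-gene and combined shared-value proportions for the 11-gene
#     up-regulated panel and the six-gene diagnostic subset (1,000
#     permutation draws per gene and group);
#   * blind samples NP1 / MRX13 / NC1 / NC2 classified against the trained
#     combined permutation distributions.
# Writes results/wapdg_result.json, results/wapdg_model.json and
# results/verdicts.tsv.

suppressPackageStartupMessages(library(wapdgkit))

seed <- 20260929L
q <- utils::read.delim("results/quantities.tsv", stringsAsFactors = FALSE)
sheet <- read_sample_sheet("results/data/validation_samples.tsv")
groups <- stats::setNames(sheet$group, sheet$sample_id)
mat <- quantities_to_matrix(q, groups)

res11 <- wapdg_analyze(mat, gene_set = upregulated_panel(),
                       n_draws = 1000, seed = seed)
message("per-gene shared-value proportions:")
for (i in seq_len(nrow(res11$per_gene))) {
  message(sprintf("  %-9s %.3f", res11$per_gene$gene_id[i],
                  res11$per_gene$proportion[i]))
}
message(sprintf("combined, 11 up-regulated genes: proportion %.4g -> P < %.4g",
                res11$combined_proportion, res11$combined_p_bound))

res6 <- wapdg_analyze(mat, gene_set = diagnostic_subset(),
                      n_draws = 1000, seed = seed)
message(sprintf("combined, six-gene subset:      proportion %.4g -> P < %.4g",
                res6$combined_proportion, res6$combined_p_bound))

jsonlite::write_json(
  list(seed = seed, n_draws = 1000,
       panel11 = list(per_gene = res11$per_gene,
                      combined_proportion = res11$combined_proportion,
                      combined_p_bound = res11$combined_p_bound),
       panel6 = list(combined_proportion = res6$combined_proportion,
                     combined_p_bound = res6$combined_p_bound)),
  "results/wapdg_result.json", auto_unbox = TRUE, digits = NA, dataframe = "rows")
write_wapdg_model(res11, "results/wapdg_model.json")

## blind classification --------------------------------------------------------
blind_q <- utils::read.delim("results/blind_quantities.tsv", stringsAsFactors = FALSE)
verdicts <- do.call(rbind, lapply(unique(blind_q$sample_id), function(id) {
  v <- blind_q[blind_q$sample_id == id & blind_q$status == "ok", ]
  classify_sample(stats::setNames(v$quantity, v$gene_id), res11, sample_id = id)
}))
utils::write.table(verdicts, "results/verdicts.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("\nblind classification (alpha = 0.005 per side):")
for (i in seq_len(nrow(verdicts))) {
  message(sprintf("  %-6s combined value %.3f -> %s", verdicts$sample_id[i],
                  verdicts$combined_value[i], verdicts$verdict[i]))
}
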