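#!/usr/bin/env Rscript

# Per-marker group statistics on the validation cohort: one-way
# fixed-effect model per gene (classes missense / truncating / control),
# LS-mean patient-class/control ratios, Student t tests of the LS-mean
# differences and significance codes. Writes results/contrasts.tsv and
# prints the estimated vs generator-true ratios.

suppressPackageStartupMessages(library(wapdgkit))

q <- utils::read.delim("results/quantities.tsv", stringsAsFactors = FALSE)
sheet <- read_sample_sheet("results/data/validation_samples.tsv")
groups <- stats::setNames(sheet$group, sheet$sample_id)

ct <- contrast_table(q, groups, add_bh = TRUE)
utils::write.table(ct, "results/contrasts.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

truth <- kdm5c_marker_ratios()
for (cl in c("missense", "truncating")) {
  sub <- ct[ct$class == cl, ]
  tr <- truth[[paste0("ratio_", cl)]][match(sub$gene_id, truth$gene_id)]
  message("\n", cl, " vs control:")
  for (i in seq_len(nrow(sub))) {
    message(sprintf("  %-9s ratio %5.2f (true %5.2f)  p=%8.2e %s",
                    sub$gene_id[i], sub$ratio[i], tr[i],
                    sub$p_value[i], sub$code[i]))
  }
  message(sprintf("  %d/%d markers significant at p < 0.05",
                  sum(sub$p_value < 0.05), nrow(sub)))
}
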