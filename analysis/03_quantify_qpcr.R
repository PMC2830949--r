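#!/usr/bin/env Rscript

# Absolute quantification of the validation cohort and the blind samples:
# one factor-2 serial-dilution standard curve per marker assay, triplicate
# QC (Ct ceiling 35 cycles, max triplicate SD 0.5), quantities on each
# assay's own dilution scale. Writes results/quantities.tsv and
# results/blind_quantities.tsv.

suppressPackageStartupMessages(library(wapdgkit))

dat <- "results/data"
plate <- read_qpcr_plate(file.path(dat, "validation_plate.tsv"),
                         file.path(dat, "validation_standards.tsv"),
                         file.path(dat, "validation_samples.tsv"))
q <- quantify_plate(plate)
curves <- attr(q, "curves")
for (g in names(curves)) {
  message(sprintf("%-9s slope %.3f  efficiency %.3f  r^2 %.4f",
                  g, curves[[g]]$slope, curves[[g]]$efficiency,
                  curves[[g]]$r_squared))
}
utils::write.table(q, "results/quantities.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
nq <- q[q$status != "ok", ]
message(nrow(q), " measurements quantified; ", nrow(nq), " not quantifiable")

# blind plates: standards are per blind sample (grown in another lab), so
# quantify each sample against its own curves
blind <- utils::read.delim(file.path(dat, "blind_plate.tsv"), stringsAsFactors = FALSE)
blind_std <- utils::read.delim(file.path(dat, "blind_standards.tsv"), stringsAsFactors = FALSE)
blind_q <- do.call(rbind, lapply(unique(blind$sample_id), function(id) {
  bp <- structure(list(measurements = blind[blind$sample_id == id, ],
                       standards = blind_std[blind_std$plate_id == id, ],
                       groups = stats::setNames("unknown", id),
                       truth = NULL, params = list(dilution_factor = 2)),
                  class = "qpcr_plate")
  quantify_plate(bp)
}))
utils::write.table(blind_q, "results/blind_quantities.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("blind samples quantified: ",
        paste(unique(blind_q$sample_id), collapse = ", "))
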