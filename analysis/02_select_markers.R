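#!/usr/bin/env Rscript

# Discovery-stage marker selection: rank-invariant normalisation of the
# patient + control arrays, detection scoring against negative-control
# probes, pairwise differential-expression scores, and the tiered
# candidate filter (strict DS > 100 / DT > 0.99; standard DS > 50 / DT at
# the empirical maximum; relaxed = standard in 2 of 3 comparisons).
# Writes results/candidates.tsv.

suppressPackageStartupMessages(library(wapdgkit))

dat <- "results/data"
expr <- read_expression_tsv(file.path(dat, "discovery_expr.tsv"),
                            file.path(dat, "discovery_samples.tsv"))
neg <- read_expression_tsv(file.path(dat, "discovery_neg.tsv"),
                           file.path(dat, "discovery_samples.tsv"))

controls <- names(expr$groups)[expr$groups == "control"]
patient <- names(expr$groups)[expr$groups != "control"]
stopifnot(length(patient) == 1)

norm <- rank_invariant_normalize(expr, reference_sample = controls[1])
message("scale factors: ",
        paste(sprintf("%s=%.4f", names(attr(norm, "scale_factors")),
                      attr(norm, "scale_factors")), collapse = " "))

det <- detection_scores(norm, neg)
vm <- fit_variance_model(neg, cv = 0.1)
cand <- select_candidates(norm, det, patient, controls,
                          candidate_thresholds(), vm)

utils::write.table(cand, "results/candidates.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(nrow(cand), " candidate gene(s): ",
        paste(names(table(cand$tier)), table(cand$tier), sep = "=", collapse = ", "))
spiked <- grepl("^SPIKE", cand$gene_id)
message(sum(spiked), "/21 true spikes recovered; ",
        sum(!spiked), " background gene(s) selected")
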