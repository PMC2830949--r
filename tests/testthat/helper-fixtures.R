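# shared fixture builders; everything is generated in code, no stored data

# quantity matrix with per-group fold changes and multiplicative log-normal
# noise, built directly (bypassing the qPCR layer) for fast statistical tests
make_quantity_matrix <- function(genes, group_sizes, fold_table = NULL,
                                 base = 0.1, cv = 0.25, seed = 1L) {
  groups <- rep(names(group_sizes), group_sizes)
  ids <- paste0(toupper(substr(groups, 1, 1)), unlist(lapply(group_sizes, seq_len)))
  names(groups) <- ids
  fold <- matrix(1, length(genes), length(group_sizes),
                 dimnames = list(genes, names(group_sizes)))
  if (!is.null(fold_table)) {
    fold[cbind(match(fold_table$gene_id, genes),
               match(fold_table$group, colnames(fold)))] <- fold_table$fold
  }
  s <- sqrt(log1p(cv^2))
  withr::with_seed(seed, {
    noise <- matrix(exp(rnorm(length(genes) * length(ids), -s^2 / 2, s)),
                    nrow = length(genes))
    vals <- base * fold[, groups, drop = FALSE] * noise
    dimnames(vals) <- list(genes, ids)
    expression_matrix(vals, groups)
  })
}

# exhaustive-count oracle for the shared-value proportion: loop over every
# value, test membership in the range intersection directly
shared_proportion_oracle <- function(a, b) {
  lo <- max(min(a), min(b))
  hi <- min(max(a), max(b))
  n_in <- 0L
  for (v in c(a, b)) {
    if (v >= lo && v <= hi) n_in <- n_in + 1L
  }
  if (lo > hi) 0 else n_in / (length(a) + length(b))
}

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}

# handmade two-assay plate for exact qPCR checks (no simulation layer)
manual_plate <- function(standard_cts, sample_cts, gene = "G1",
                         dilution_factor = 2) {
  steps <- seq_along(standard_cts) - 1L
  standards <- data.frame(gene_id = gene, dilution_step = steps, replicate = 1L,
                          ct = standard_cts, stringsAsFactors = FALSE)
  measurements <- do.call(rbind, lapply(names(sample_cts), function(s) {
    data.frame(gene_id = gene, sample_id = s,
               replicate = seq_along(sample_cts[[s]]), ct = sample_cts[[s]],
               stringsAsFactors = FALSE)
  }))
  structure(list(measurements = measurements, standards = standards,
                 groups = stats::setNames(rep("control", length(sample_cts)),
                                          names(sample_cts)),
                 truth = NULL,
                 params = list(dilution_factor = dilution_factor)),
            class = "qpcr_plate")
}
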