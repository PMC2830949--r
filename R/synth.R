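#' Simulation configuration for synthetic cohorts
#'
#' Describes a synthetic study: how many background genes and negative-control
#' probes, which genes are spiked at which patient/control fold change, the
#' cohort composition, and the noise model. One `sim_config` drives both the
#' bead-array generator ([simulate_array_experiment()]) and the qPCR plate
#' generator ([simulate_qpcr_experiment()]).
#'
#' The noise model is multiplicative log-normal: a sample's value is the
#' gene's group mean times `exp(N(-s^2/2, s))` with `s^2 = log(1 + cv^2)`, so
#' the multiplier has expectation 1 and coefficient of variation `cv_within`.
#' `cv_within = 0` is allowed and yields noise-free values, which the exact
#' round-trip checks of the qPCR stage rely on.
#'
#' @param n_genes Number of background (fold 1) genes; may be 0 when only
#'   spiked assay genes are wanted.
#' @param n_neg_controls Number of negative-control probes (array only).
#' @param spike_table `NULL`, or a `data.frame` with columns `gene_id`,
#'   `group`, `fold` giving per-group fold changes (> 0) relative to the
#'   control mean. Gene ids not among the background genes are appended as
#'   extra genes. Groups must exist in `group_sizes`.
#' @param group_sizes Named integer vector, group label -> sample count; all
#'   counts >= 1. Labels must be valid `expression_matrix` groups.
#' @param baseline_log_mean,baseline_log_sd Location/spread (log scale) of
#'   per-gene background mean intensities.
#' @param cv_within Within-group coefficient of variation, in `[0, 1)`.
#' @param dropout_rate Fraction (in `[0, 1)`) of background genes expressed
#'   below the quantification floor: on arrays their means are drawn from the
#'   negative-control distribution, on qPCR plates their template amount sits
#'   beyond the Ct ceiling.
#' @param neg_log_mean,neg_log_sd Log-normal parameters of negative-control
#'   probe intensities.
#' @param seed Integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(n_genes = 1000,
                       n_neg_controls = 1000,
                       spike_table = NULL,
                       group_sizes = c(missense = 8L, truncating = 4L, control = 5L),
                       baseline_log_mean = log(1000),
                       baseline_log_sd = 0.5,
                       cv_within = 0.25,
                       dropout_rate = 0,
                       neg_log_mean = log(100),
                       neg_log_sd = 0.3,
                       seed = 1L) {
  group_sizes <- unlist(group_sizes)  # tolerate YAML-style lists
  if (!is_count(n_genes)) stop("n_genes must be a non-negative count", call. = FALSE)
  if (!is_count(n_neg_controls)) stop("n_neg_controls must be a count", call. = FALSE)
  if (is.null(names(group_sizes)) || any(names(group_sizes) == "")) {
    stop("group_sizes must be named by group label", call. = FALSE)
  }
  bad <- setdiff(names(group_sizes), c("missense", "truncating", "control", "unknown"))
  if (length(bad)) stop("invalid group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(group_sizes < 1) || any(group_sizes != as.integer(group_sizes))) {
    stop("all group sizes must be integers >= 1", call. = FALSE)
  }
  if (!is_number(cv_within) || cv_within < 0 || cv_within >= 1) {
    stop("cv_within must lie in [0, 1)", call. = FALSE)
  }
  if (!is_number(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(spike_table)) {
    if (!all(c("gene_id", "group", "fold") %in% names(spike_table))) {
      stop("spike_table needs columns gene_id, group, fold", call. = FALSE)
    }
    if (any(spike_table$fold <= 0)) stop("all fold changes must be > 0", call. = FALSE)
    unknown <- setdiff(unique(spike_table$group), names(group_sizes))
    if (length(unknown)) {
      stop("configuration error: spike_table references unknown group(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(spike_table[c("gene_id", "group")])) {
      stop("duplicate (gene_id, group) entries in spike_table", call. = FALSE)
    }
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_neg_controls = as.integer(n_neg_controls),
                 spike_table = spike_table,
                 group_sizes = stats::setNames(as.integer(group_sizes), names(group_sizes)),
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 cv_within = cv_within,
                 dropout_rate = dropout_rate,
                 neg_log_mean = neg_log_mean,
                 neg_log_sd = neg_log_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

group_prefixes <- c(missense = "PM", truncating = "PT", control = "C", unknown = "U")

sim_samples <- function(config) {
  groups <- rep(names(config$group_sizes), config$group_sizes)
  ids <- unlist(lapply(names(config$group_sizes), function(g) {
    sprintf("%s%02d", group_prefixes[[g]], seq_len(config$group_sizes[[g]]))
  }), use.names = FALSE)
  stats::setNames(groups, ids)
}

sim_gene_ids <- function(config) {
  ids <- if (config$n_genes > 0) sprintf("G%05d", seq_len(config$n_genes)) else character()
  if (!is.null(config$spike_table)) {
    ids <- c(ids, setdiff(unique(config$spike_table$gene_id), ids))
  }
  ids
}

# fold-change matrix gene x group, default 1, filled from the spike table
sim_fold_matrix <- function(config, gene_ids) {
  fold <- matrix(1, length(gene_ids), length(config$group_sizes),
                 dimnames = list(gene_ids, names(config$group_sizes)))
  st <- config$spike_table
  if (!is.null(st)) fold[cbind(match(st$gene_id, gene_ids), match(st$group, colnames(fold)))] <- st$fold
  fold
}

lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log1p(cv^2))
  exp(stats::rnorm(n, -s^2 / 2, s))
}

#' Simulate a bead-array experiment
#'
#' Background gene mean intensities are log-normal around
#' `baseline_log_mean`, floored at twice the negative-control distribution's
#' 99th percentile so that every expressed gene sits above background in
#' expectation; spiked genes have their group means multiplied by the
#' configured fold change; a `dropout_rate` fraction of background genes is
#' instead drawn from the negative-control distribution in all samples
#' (genes below the quantification floor); negative-control probes are
#' low-intensity log-normal.
#'
#' @param config A [sim_config()].
#' @return A list with elements `expr` (the gene x sample
#'   `expression_matrix`; dropout gene ids in `attr(, "dropout_genes")`) and
#'   `neg_controls` (negative-control probe x sample `expression_matrix`).
#' @export
simulate_array_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  samples <- sim_samples(config)
  gene_ids <- sim_gene_ids(config)
  if (!length(gene_ids)) stop("no genes to simulate", call. = FALSE)
  fold <- sim_fold_matrix(config, gene_ids)
  with_seed(stage_seed(config$seed, "array"), {
    floor_at <- 2 * stats::qlnorm(0.99, config$neg_log_mean, config$neg_log_sd)
    base <- pmax(stats::rlnorm(length(gene_ids), config$baseline_log_mean,
                               config$baseline_log_sd), floor_at)
    names(base) <- gene_ids
    background <- if (config$n_genes > 0) gene_ids[seq_len(config$n_genes)] else character()
    n_drop <- round(config$dropout_rate * length(background))
    dropout <- if (n_drop > 0) sample(background, n_drop) else character()
    base[dropout] <- stats::rlnorm(n_drop, config$neg_log_mean, config$neg_log_sd)
    means <- base * fold[, samples, drop = FALSE]  # gene x sample group means
    noise <- matrix(lognormal_noise(length(means), config$cv_within),
                    nrow = nrow(means))
    vals <- means * noise
    dimnames(vals) <- list(gene_ids, names(samples))
    neg <- matrix(stats::rlnorm(config$n_neg_controls * length(samples),
                                config$neg_log_mean, config$neg_log_sd),
                  nrow = config$n_neg_controls,
                  dimnames = list(sprintf("NEG%04d", seq_len(config$n_neg_controls)),
                                  names(samples)))
    expr <- expression_matrix(vals, samples)
    attr(expr, "dropout_genes") <- dropout
    list(expr = expr, neg_controls = expression_matrix(neg, samples))
  })
}

#' Simulate a QRT-PCR experiment with serial-dilution standards
#'
#' Per gene and sample, a true template quantity (on the dilution scale of
#' that gene's own standard, undiluted reference = 1) is
#' `base_quantity * fold * log-normal noise`; each of `n_replicates`
#' technical replicates observes `Ct = ct_intercept - log2(quantity) /
#' log2(efficiency) + N(0, ct_sd)`. Every assay also carries a serial
#' dilution of the reference template (`dilution_levels` steps of factor
#' `base_dilution_factor`), measured with the same replicate structure, from
#' which [fit_standard_curve()] recovers the calibration line. Dropout genes
#' (see [sim_config()]) get a template amount `2^-15` of `base_quantity`,
#' far beyond any usual Ct ceiling.
#'
#' @param config A [sim_config()].
#' @param dilution_levels Number of standard-curve steps (>= 3).
#' @param base_dilution_factor Dilution factor between consecutive steps (> 1).
#' @param efficiency Amplification efficiency as fold per cycle (2 = perfect
#'   doubling).
#' @param ct_intercept Ct of the undiluted reference (quantity 1), cycles.
#' @param ct_sd SD of additive Gaussian technical noise on each replicate Ct,
#'   cycles (default 0.15).
#' @param base_quantity Control-group template quantity on the dilution
#'   scale; 0.1 keeps typical samples inside a 5-step factor-2 curve.
#' @param n_replicates Technical replicates per measurement (default 3).
#' @return A `qpcr_plate`: list with `measurements` (`gene_id`, `sample_id`,
#'   `replicate`, `ct`), `standards` (`gene_id`, `dilution_step`,
#'   `replicate`, `ct`), `groups`, `truth` (the simulated quantities) and
#'   `params`.
#' @export
simulate_qpcr_experiment <- function(config,
                                     dilution_levels = 5L,
                                     base_dilution_factor = 2,
                                     efficiency = 2,
                                     ct_intercept = 22,
                                     ct_sd = 0.15,
                                     base_quantity = 0.1,
                                     n_replicates = 3L) {
  stopifnot(inherits(config, "sim_config"))
  if (!is_count(dilution_levels, min = 3)) stop("dilution_levels must be >= 3", call. = FALSE)
  if (!is_number(base_dilution_factor) || base_dilution_factor <= 1) {
    stop("base_dilution_factor must be > 1", call. = FALSE)
  }
  if (!is_number(efficiency) || efficiency <= 1) stop("efficiency must be > 1", call. = FALSE)
  if (ct_sd < 0) stop("ct_sd must be >= 0", call. = FALSE)
  samples <- sim_samples(config)
  gene_ids <- sim_gene_ids(config)
  if (!length(gene_ids)) stop("no genes to simulate", call. = FALSE)
  fold <- sim_fold_matrix(config, gene_ids)
  with_seed(stage_seed(config$seed, "qpcr"), {
    background <- if (config$n_genes > 0) gene_ids[seq_len(config$n_genes)] else character()
    n_drop <- round(config$dropout_rate * length(background))
    dropout <- if (n_drop > 0) sample(background, n_drop) else character()
    base <- stats::setNames(rep(base_quantity, length(gene_ids)), gene_ids)
    base[dropout] <- base_quantity * 2^-15
    qty <- base * fold[, samples, drop = FALSE] *
      matrix(lognormal_noise(length(gene_ids) * length(samples), config$cv_within),
             nrow = length(gene_ids))
    dimnames(qty) <- list(gene_ids, names(samples))
    grid <- expand.grid(replicate = seq_len(n_replicates),
                        sample_id = names(samples), gene_id = gene_ids,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    true_ct <- ct_intercept - log2(qty[cbind(grid$gene_id, grid$sample_id)]) / log2(efficiency)
    measurements <- data.frame(gene_id = grid$gene_id, sample_id = grid$sample_id,
                               replicate = grid$replicate,
                               ct = true_ct + stats::rnorm(nrow(grid), 0, ct_sd),
                               stringsAsFactors = FALSE)
    sgrid <- expand.grid(replicate = seq_len(n_replicates),
                         dilution_step = seq_len(dilution_levels) - 1L,
                         gene_id = gene_ids,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    std_ct <- ct_intercept +
      sgrid$dilution_step * log2(base_dilution_factor) / log2(efficiency)
    standards <- data.frame(gene_id = sgrid$gene_id,
                            dilution_step = sgrid$dilution_step,
                            replicate = sgrid$replicate,
                            ct = std_ct + stats::rnorm(nrow(sgrid), 0, ct_sd),
                            stringsAsFactors = FALSE)
    truth <- data.frame(gene_id = rep(gene_ids, times = length(samples)),
                        sample_id = rep(names(samples), each = length(gene_ids)),
                        quantity = as.vector(qty), stringsAsFactors = FALSE)
    structure(list(measurements = measurements, standards = standards,
                   groups = samples, truth = truth,
                   params = list(dilution_factor = base_dilution_factor,
                                 efficiency = efficiency,
                                 ct_intercept = ct_intercept,
                                 ct_sd = ct_sd,
                                 base_quantity = base_quantity,
                                 dropout_genes = dropout)),
              class = "qpcr_plate")
  })
}

#' @export
print.qpcr_plate <- function(x, ...) {
  cat("qpcr_plate:", length(unique(x$measurements$gene_id)), "assay(s),",
      length(x$groups), "samples,",
      max(x$standards$dilution_step) + 1, "standard steps\n")
  invisible(x)
}

#' Write / read a qPCR plate as TSV
#'
#' Measurements and the standard-curve series are written as two long-format
#' TSVs (columns as in the `qpcr_plate` fields). Group labels travel in a
#' sample sheet.
#'
#' @param plate A `qpcr_plate`.
#' @param measurements_path,standards_path File paths.
#' @return `write_qpcr_plate` returns the paths invisibly.
#' @export
write_qpcr_plate <- function(plate, measurements_path, standards_path) {
  stopifnot(inherits(plate, "qpcr_plate"))
  utils::write.table(plate$measurements, measurements_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(plate$standards, standards_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(measurements_path, standards_path))
}

#' @rdname write_qpcr_plate
#' @param sample_sheet Sample-sheet `data.frame` or path (for group labels).
#' @return `read_qpcr_plate` returns a `qpcr_plate` (without simulation truth).
#' @export
read_qpcr_plate <- function(measurements_path, standards_path, sample_sheet) {
  if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
  structure(list(measurements = utils::read.delim(measurements_path, stringsAsFactors = FALSE),
                 standards = utils::read.delim(standards_path, stringsAsFactors = FALSE),
                 groups = stats::setNames(sample_sheet$group, sample_sheet$sample_id),
                 truth = NULL, params = list()),
            class = "qpcr_plate")
}

#' Write a simulation configuration as YAML
#'
#' Field-for-field mirror of [sim_config()]; [read_sim_config()] validates on
#' the way back in.
#'
#' @param config A `sim_config`.
#' @param path File path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  out <- unclass(config)
  out$group_sizes <- as.list(out$group_sizes)
  if (!is.null(out$spike_table)) out$spike_table <- as.list(out$spike_table)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$spike_table)) raw$spike_table <- as.data.frame(raw$spike_table)
  raw$group_sizes <- unlist(raw$group_sizes)
  do.call(sim_config, raw)
}
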