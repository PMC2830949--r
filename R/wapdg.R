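#' Grand-mean weighting of expression values
#'
#' The first WAPDG step: every gene's expression values are divided by that
#' gene's grand mean over all samples in the two labelled groups combined,
#' yielding dimensionless, equally weighted gene information (each gene's
#' weighted values average exactly 1). The grand means are retained so an
#' unknown sample can later be weighted onto the same scale.
#'
#' @param x An `expression_matrix`.
#' @param gene_set Genes to weight (default all).
#' @param samples Samples whose values define the grand means (default all
#'   columns); classification of unknowns must exclude them here.
#' @return A `weighted_matrix`: list with `values` (weighted gene x sample
#'   matrix over `samples`), `groups`, `grand_means`.
#' @export
weight_expression <- function(x, gene_set = NULL, samples = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  gene_set <- gene_set %||% rownames(x$values)
  samples <- samples %||% colnames(x$values)
  sub <- em_subset(x, genes = gene_set, samples = samples)
  gm <- rowMeans(sub$values)
  if (any(gm <= 0)) {
    stop("grand mean is zero for gene(s): ",
         paste(names(gm)[gm <= 0], collapse = ", "), call. = FALSE)
  }
  structure(list(values = sub$values / gm, groups = sub$groups, grand_means = gm),
            class = "weighted_matrix")
}

#' Per-group means and SDs of weighted values
#'
#' @param weighted A [weight_expression()] result.
#' @param groups Optional named character overriding the matrix's labels
#'   (e.g. collapsing missense + truncating to `"patient"`); every group
#'   must have at least 2 samples or the sample SD is undefined.
#' @return A `data.frame` with columns `gene_id`, `group`, `mean`, `sd`
#'   (denominator n - 1), `n`.
#' @export
summarize_groups <- function(weighted, groups = NULL) {
  stopifnot(inherits(weighted, "weighted_matrix"))
  groups <- groups %||% weighted$groups
  groups <- groups[colnames(weighted$values)]
  if (anyNA(groups)) stop("group label missing for some samples", call. = FALSE)
  tab <- table(groups)
  if (any(tab < 2)) {
    stop("group(s) of size 1 (SD undefined): ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, lapply(names(tab), function(g) {
    v <- weighted$values[, groups == g, drop = FALSE]
    data.frame(gene_id = rownames(v), group = g,
               mean = rowMeans(v), sd = apply(v, 1, stats::sd),
               n = sum(groups == g), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# positive-truncated normal draws by rejection (redraw until > 0), the
# truncation that produces the slight positive skew of the permuted values
rtrunc_pos <- function(n, mean, sd) {
  if (sd == 0) {
    if (mean <= 0) stop("no positive support: mean <= 0 with sd = 0", call. = FALSE)
    return(rep(mean, n))
  }
  accept <- stats::pnorm(0, mean, sd, lower.tail = FALSE)
  if (accept < 1e-8) {
    stop("no practical positive support: mean ", signif(mean, 3), ", sd ",
         signif(sd, 3), call. = FALSE)
  }
  out <- numeric(0)
  while (length(out) < n) {
    batch <- stats::rnorm(ceiling((n - length(out)) / max(accept, 0.01)), mean, sd)
    out <- c(out, batch[batch > 0])
  }
  out[seq_len(n)]
}

#' Parametric permutation draws for one gene and group
#'
#' Draws `n_draws` values from a normal distribution with the group's mean
#' and SD of weighted values, keeping only values > 0 (rejection sampling,
#' i.e. redraw — not clipping — so an active truncation shows up as a
#' slight positive skew, mirroring the strictly positive original
#' observations). `sd = 0` degenerates to `n_draws` copies of the mean.
#' Draws come from the current RNG state; seed via [wapdg_analyze()] or
#' `set.seed()` for reproducibility.
#'
#' @param summary A [summarize_groups()] data.frame.
#' @param gene,group Which (gene, group) cell to permute.
#' @param n_draws Number of draws (default 1000).
#' @return Numeric vector of `n_draws` positive values.
#' @export
permute_group <- function(summary, gene, group, n_draws = 1000) {
  row <- summary[summary$gene_id == gene & summary$group == group, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("no unique summary row for gene '", gene, "', group '", group, "'",
         call. = FALSE)
  }
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  rtrunc_pos(n_draws, row$mean, row$sd)
}

#' Build the full permutation set for a group summary
#'
#' @param summary A [summarize_groups()] data.frame.
#' @param n_draws Draws per (gene, group) cell (default 1000).
#' @param seed Integer seed; the whole set is drawn under it in a fixed
#'   (gene, group) order, so identical inputs give identical draws.
#' @return A `permutation_set`: nested list `draws[[gene]][[group]]` of
#'   positive numeric vectors, plus `n_draws` and `seed`.
#' @export
build_permutation_set <- function(summary, n_draws = 1000, seed = 1L) {
  genes <- unique(summary$gene_id)
  groups <- unique(summary$group)
  draws <- with_seed(seed, {
    stats::setNames(lapply(genes, function(g) {
      stats::setNames(lapply(groups, function(gr) {
        permute_group(summary, g, gr, n_draws)
      }), groups)
    }), genes)
  })
  structure(list(draws = draws, n_draws = n_draws, seed = as.integer(seed),
                 groups = groups),
            class = "permutation_set")
}

#' Proportion of shared values between two draw sets
#'
#' The overlap interval is the intersection of the two empirical ranges,
#' `[max(min_a, min_b), min(max_a, max_b)]`; the shared proportion is the
#' fraction of all values (both sets pooled) falling inside it, boundary
#' points included. Disjoint ranges give 0; identical sets give 1. With `N`
#' draws per group the smallest reportable bound is `1/N`, so the strongest
#' claim at `N = 1000` is `P < 0.001`.
#'
#' @param draws_a,draws_b Non-empty numeric vectors.
#' @return Proportion in `[0, 1]`.
#' @export
shared_proportion <- function(draws_a, draws_b) {
  if (!length(draws_a) || !length(draws_b)) {
    stop("both draw sets must be non-empty", call. = FALSE)
  }
  lo <- max(min(draws_a), min(draws_b))
  hi <- min(max(draws_a), max(draws_b))
  if (lo > hi) return(0)
  (sum(draws_a >= lo & draws_a <= hi) + sum(draws_b >= lo & draws_b <= hi)) /
    (length(draws_a) + length(draws_b))
}

#' Combine per-gene permutation draws across a gene panel
#'
#' The accumulation step: for each group, combined draw `i` is the mean over
#' the panel of that group's `i`-th per-gene draw (genes are permuted
#' independently, so averaging shrinks the combined spread roughly as
#' `1/sqrt(G)` and panels separate even where single genes overlap). All
#' panel genes must point the same way; mixing up- and down-regulated genes
#' without inverting the latter (see `direction_map` of [wapdg_analyze()])
#' is an error because their effects would cancel.
#'
#' @param perms A [build_permutation_set()].
#' @param gene_set Panel gene ids (present in `perms` for both groups).
#' @param directions Named vector of +1/-1 per panel gene (default all +1).
#' @return Named list (one element per group) of combined draw vectors.
#' @export
combine_genes <- function(perms, gene_set, directions = NULL) {
  stopifnot(inherits(perms, "permutation_set"))
  if (!length(gene_set)) stop("gene_set must be non-empty", call. = FALSE)
  missing <- setdiff(gene_set, names(perms$draws))
  if (length(missing)) {
    stop("gene(s) absent from permutation set: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  directions <- directions %||% stats::setNames(rep(1, length(gene_set)), gene_set)
  if (length(unique(sign(directions[gene_set]))) > 1) {
    stop("mixing up- and down-regulated genes without direction inversion",
         call. = FALSE)
  }
  stats::setNames(lapply(perms$groups, function(gr) {
    rowMeans(vapply(gene_set, function(g) perms$draws[[g]][[gr]],
                    numeric(perms$n_draws)))
  }), perms$groups)
}

# patient/control dichotomy used throughout: missense + truncating pool to
# "patient"; unknown samples are held out
patient_control_groups <- function(groups) {
  out <- ifelse(groups %in% c("missense", "truncating"), "patient",
                ifelse(groups == "control", "control", NA_character_))
  stats::setNames(out, names(groups))
}

#' WAPDG analysis: weighted accumulative permutation differentiation
#'
#' Runs the full chain for a two-group comparison over a marker panel:
#' grand-mean weighting, per-group mean/SD summaries, `n_draws`
#' positive-truncated normal permutation draws per gene and group, the
#' per-gene shared-value proportion, the combined (panel-mean) draws and
#' their shared proportion, and the reportable bound
#' `p_bound = max(proportion, 1/n_draws)`. Down-regulated genes listed with
#' `-1` in `direction_map` enter through their reciprocal raw values so
#' that all panel genes point up; by default the panel is assumed
#' up-regulated.
#'
#' The returned object doubles as a trained model for
#' [classify_sample()]: it retains the training grand means, directions and
#' the combined permutation draws of both groups.
#'
#' @param x An `expression_matrix` (quantities or normalised intensities).
#' @param gene_set Panel gene ids (default: all genes in `x`).
#' @param groups Optional named vector with exactly two labels; defaults to
#'   pooling missense + truncating as `"patient"` vs `"control"`, dropping
#'   `unknown` samples.
#' @param n_draws Permutation draws per gene and group (default 1000).
#' @param seed Integer seed; identical inputs + seed give identical results.
#' @param direction_map Optional named vector of +1/-1 per gene.
#' @return A `wapdg_result` with fields `gene_set`, `directions`,
#'   `grand_means`, `group_summary`, `per_gene` (data.frame of proportions
#'   and p bounds), `combined_proportion`, `combined_p_bound`,
#'   `combined_draws`, `n_draws`, `seed`, `group_labels`.
#' @export
wapdg_analyze <- function(x, gene_set = NULL, groups = NULL, n_draws = 1000,
                          seed = 1L, direction_map = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  gene_set <- gene_set %||% rownames(x$values)
  groups <- groups %||% patient_control_groups(x$groups)
  groups <- groups[!is.na(groups)]
  labels <- unique(groups)
  if (length(labels) != 2) {
    stop("need exactly two labelled groups, got: ",
         paste(labels, collapse = ", "), call. = FALSE)
  }
  directions <- (direction_map %||% stats::setNames(rep(1, length(gene_set)), gene_set))[gene_set]
  if (anyNA(directions)) stop("direction_map missing for some panel genes", call. = FALSE)
  vals <- x$values[gene_set, names(groups), drop = FALSE]
  down <- directions < 0
  if (any(down)) {
    if (any(vals[down, , drop = FALSE] <= 0)) {
      stop("cannot invert non-positive values for down-regulated gene(s)", call. = FALSE)
    }
    vals[down, ] <- 1 / vals[down, , drop = FALSE]
  }
  xx <- expression_matrix(vals, x$groups[names(groups)])
  weighted <- weight_expression(xx)
  summary <- summarize_groups(weighted, groups = groups)
  perms <- build_permutation_set(summary, n_draws = n_draws,
                                 seed = stage_seed(seed, "wapdg"))
  per_gene <- data.frame(
    gene_id = gene_set,
    proportion = vapply(gene_set, function(g) {
      shared_proportion(perms$draws[[g]][[labels[1]]], perms$draws[[g]][[labels[2]]])
    }, numeric(1)),
    stringsAsFactors = FALSE)
  per_gene$p_bound <- pmax(per_gene$proportion, 1 / n_draws)
  combined <- combine_genes(perms, gene_set,
                            directions = stats::setNames(rep(1, length(gene_set)), gene_set))
  comb_prop <- shared_proportion(combined[[labels[1]]], combined[[labels[2]]])
  structure(list(gene_set = gene_set,
                 directions = directions,
                 grand_means = weighted$grand_means,
                 group_summary = summary,
                 per_gene = per_gene,
                 combined_proportion = comb_prop,
                 combined_p_bound = max(comb_prop, 1 / n_draws),
                 combined_draws = combined,
                 n_draws = n_draws,
                 seed = as.integer(seed),
                 group_labels = labels),
            class = "wapdg_result")
}

#' @export
print.wapdg_result <- function(x, ...) {
  cat("WAPDG over", length(x$gene_set), "gene(s),", x$n_draws, "draws/group\n")
  cat(sprintf("combined shared-value proportion: %.4g (P < %.4g)\n",
              x$combined_proportion, x$combined_p_bound))
  invisible(x)
}

#' Classify a blind sample against a trained WAPDG model
#'
#' The unknown's raw values are weighted with the *training* grand means
#' (after the model's direction inversions), averaged over the panel, and
#' located against the central `1 - 2*alpha` empirical intervals of the two
#' groups' combined permutation draws. The verdict is `patient` when the
#' combined value lies inside the patient interval and outside the control
#' interval, `control` in the symmetric case, and `unassigned` when it sits
#' in both or neither (the behaviour expected for intermediate expression
#' signatures).
#'
#' @param values Named numeric vector of the unknown sample's raw values;
#'   must cover all model genes.
#' @param model A [wapdg_analyze()] result; its combined draws and grand
#'   means must be present (an untrained/stripped model is an error).
#' @param alpha Tail mass per side of each acceptance interval (default
#'   0.005, matching the `1/N` resolution at `N = 1000`).
#' @param sample_id Optional id carried into the result.
#' @return One-row `data.frame`: `sample_id`, `combined_value`, `verdict`,
#'   and the quantile position of the value within each group's combined
#'   draws (`q_<group>` columns).
#' @export
classify_sample <- function(values, model, alpha = 0.005, sample_id = NA_character_) {
  stopifnot(inherits(model, "wapdg_result"))
  if (is.null(model$combined_draws) || is.null(model$grand_means)) {
    stop("untrained model: combined draws or grand means missing", call. = FALSE)
  }
  missing <- setdiff(model$gene_set, names(values))
  if (length(missing)) {
    stop("missing gene value(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  v <- values[model$gene_set]
  down <- model$directions < 0
  if (any(down)) {
    if (any(v[down] <= 0)) stop("cannot invert non-positive values", call. = FALSE)
    v[down] <- 1 / v[down]
  }
  combined_value <- mean(v / model$grand_means[model$gene_set])
  inside <- vapply(model$group_labels, function(gr) {
    iv <- stats::quantile(model$combined_draws[[gr]], c(alpha, 1 - alpha),
                          names = FALSE, type = 7)
    combined_value >= iv[1] && combined_value <= iv[2]
  }, logical(1))
  # group_labels are the model's two classes; map to patient/control verdicts
  verdict <- if (sum(inside) != 1) "unassigned" else model$group_labels[inside]
  out <- data.frame(sample_id = sample_id, combined_value = combined_value,
                    verdict = unname(verdict), stringsAsFactors = FALSE)
  for (gr in model$group_labels) {
    out[[paste0("q_", gr)]] <- stats::ecdf(model$combined_draws[[gr]])(combined_value)
  }
  out
}

#' Save / load a trained WAPDG model as JSON
#'
#' Serialises everything [classify_sample()] needs (gene set, directions,
#' grand means, group summaries, combined draws, seed and draw count) to a
#' plain JSON file.
#'
#' @param model A `wapdg_result`.
#' @param path File path.
#' @export
write_wapdg_model <- function(model, path) {
  stopifnot(inherits(model, "wapdg_result"))
  out <- unclass(model)
  out$grand_means <- as.list(out$grand_means)
  out$directions <- as.list(out$directions)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_wapdg_model
#' @return `read_wapdg_model` returns a `wapdg_result`.
#' @export
read_wapdg_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$grand_means <- unlist(raw$grand_means)
  raw$directions <- unlist(raw$directions)
  raw$combined_draws <- lapply(raw$combined_draws, as.numeric)
  structure(raw, class = "wapdg_result")
}
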