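#' Fit a serial-dilution standard curve for one assay
#'
#' Ordinary least squares of the standard-series Ct values on
#' `dilution_step * log2(dilution_factor)` (i.e. on the negative log2
#' quantity of the reference template). The slope is in cycles per log2
#' dilution, the intercept is the Ct of the undiluted reference, and the
#' amplification efficiency follows as `2^(1/slope)` fold per cycle
#' (slope 1 = perfect doubling).
#'
#' @param plate A `qpcr_plate`.
#' @param gene_id Assay to fit.
#' @param dilution_factor Dilution factor between consecutive steps
#'   (default taken from the plate's `params`, else 2).
#' @return A `standard_curve`: list with `gene_id`, `slope`, `intercept`,
#'   `efficiency`, `r_squared`, `n_steps`.
#' @export
fit_standard_curve <- function(plate, gene_id, dilution_factor = NULL) {
  stopifnot(inherits(plate, "qpcr_plate"))
  dilution_factor <- dilution_factor %||% plate$params$dilution_factor %||% 2
  if (dilution_factor <= 1) stop("dilution_factor must be > 1", call. = FALSE)
  std <- plate$standards[plate$standards$gene_id == gene_id, , drop = FALSE]
  std <- std[is.finite(std$ct), , drop = FALSE]
  if (length(unique(std$dilution_step)) < 3) {
    stop("curve error: fewer than 3 usable dilution steps for '", gene_id, "'",
         call. = FALSE)
  }
  x <- std$dilution_step * log2(dilution_factor)  # = -log2(relative quantity)
  fit <- stats::lm(std$ct ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("curve error: non-positive slope for '", gene_id,
         "' (reversed dilution labelling?)", call. = FALSE)
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((std$ct - mean(std$ct))^2)
  structure(list(gene_id = gene_id,
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 efficiency = 2^(1 / slope),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 n_steps = length(unique(std$dilution_step))),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve[%s]: slope %.4f cycles/log2, efficiency %.4f, r^2 %.4f\n",
              x$gene_id, x$slope, x$efficiency, x$r_squared))
  invisible(x)
}

#' Quality-control rules for absolute quantification
#'
#' @param ct_ceiling Mean-Ct ceiling beyond which a measurement is called
#'   `not_quantifiable` (default 35 cycles — the template did not yield the
#'   minimum amount of product for a quantitative call).
#' @param max_ct_sd Maximum triplicate SD in cycles (default 0.5).
#' @param min_replicates Minimum usable replicates (default 2); fewer is a
#'   measurement error, not a QC failure.
#' @return A `qc_rules` list.
#' @export
qc_rules <- function(ct_ceiling = 35, max_ct_sd = 0.5, min_replicates = 2L) {
  stopifnot(ct_ceiling > 0, max_ct_sd > 0, min_replicates >= 1)
  structure(list(ct_ceiling = ct_ceiling, max_ct_sd = max_ct_sd,
                 min_replicates = as.integer(min_replicates)),
            class = "qc_rules")
}

#' Absolute quantification of one measurement through its standard curve
#'
#' Replicate Ct values are aggregated by their mean (Ct noise is close to
#' Gaussian; quantity noise is log-normal) and mapped through the inverted
#' standard curve: `quantity = 2^(-(mean_ct - intercept) / slope)`, on the
#' dilution scale of the assay's own reference (undiluted standard = 1).
#' Measurements past the Ct ceiling or with excessive replicate scatter are
#' reported `not_quantifiable` rather than given a number.
#'
#' @param plate A `qpcr_plate`.
#' @param curve The assay's [fit_standard_curve()] result.
#' @param gene_id,sample_id Which measurement to quantify.
#' @param qc [qc_rules()].
#' @return A list with `gene_id`, `sample_id`, `quantity` (`NA` when not
#'   quantifiable), `status` (`"ok"` or `"not_quantifiable"`), `mean_ct`,
#'   `sd_ct`, `n_replicates`.
#' @export
quantify <- function(plate, curve, gene_id, sample_id, qc = qc_rules()) {
  stopifnot(inherits(plate, "qpcr_plate"), inherits(curve, "standard_curve"),
            inherits(qc, "qc_rules"))
  if (curve$gene_id != gene_id) {
    stop("curve was fitted for '", curve$gene_id, "', not '", gene_id, "'",
         call. = FALSE)
  }
  m <- plate$measurements
  ct <- m$ct[m$gene_id == gene_id & m$sample_id == sample_id]
  ct <- ct[is.finite(ct)]
  if (length(ct) < qc$min_replicates) {
    stop("measurement error: only ", length(ct), " usable replicate(s) for ",
         gene_id, "/", sample_id, call. = FALSE)
  }
  mean_ct <- mean(ct)
  sd_ct <- if (length(ct) > 1) stats::sd(ct) else 0
  ok <- mean_ct <= qc$ct_ceiling && sd_ct <= qc$max_ct_sd
  list(gene_id = gene_id, sample_id = sample_id,
       quantity = if (ok) 2^(-(mean_ct - curve$intercept) / curve$slope) else NA_real_,
       status = if (ok) "ok" else "not_quantifiable",
       mean_ct = mean_ct, sd_ct = sd_ct, n_replicates = length(ct))
}

#' Quantify every (gene, sample) measurement on a plate
#'
#' Fits one standard curve per assay (unless supplied) and runs
#' [quantify()] across the plate.
#'
#' @param plate A `qpcr_plate`.
#' @param curves Optional named list of `standard_curve`s keyed by gene id;
#'   missing ones are fitted from the plate's standards.
#' @param qc [qc_rules()].
#' @return A `data.frame` with columns `gene_id`, `sample_id`, `quantity`,
#'   `status`, `mean_ct`, `sd_ct`; the fitted curves are attached as
#'   `attr(, "curves")`.
#' @export
quantify_plate <- function(plate, curves = NULL, qc = qc_rules()) {
  stopifnot(inherits(plate, "qpcr_plate"))
  genes <- unique(plate$measurements$gene_id)
  samples <- unique(plate$measurements$sample_id)
  curves <- curves %||% list()
  for (g in setdiff(genes, names(curves))) {
    curves[[g]] <- fit_standard_curve(plate, g)
  }
  rows <- vector("list", length(genes) * length(samples))
  k <- 0L
  for (g in genes) {
    for (s in samples) {
      q <- quantify(plate, curves[[g]], g, s, qc)
      k <- k + 1L
      rows[[k]] <- data.frame(gene_id = g, sample_id = s,
                              quantity = q$quantity, status = q$status,
                              mean_ct = q$mean_ct, sd_ct = q$sd_ct,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "curves") <- curves
  out
}
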