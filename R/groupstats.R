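#' One-factorial fixed-effect model for one gene's quantities
#'
#' Fits the one-way fixed-effect model behind the per-gene group
#' comparisons: with a single discontinuous factor (patient class /
#' control) and no covariates, the least-squares mean of each class is its
#' arithmetic mean, and the residual variance is pooled across classes with
#' `df = n_total - n_classes`. Tests are run on linear-scale quantities by
#' default; set `log_scale = TRUE` to model log quantities instead.
#'
#' @param values Numeric vector of per-sample quantities for one gene;
#'   `NA`s (e.g. not-quantifiable measurements) are dropped with their
#'   samples.
#' @param groups Factor/character of class labels aligned with `values`.
#' @param log_scale Model `log(values)` instead of `values` (default FALSE).
#' @return A `oneway_fit`: list with `ls_means`, `n_per_class`, `sigma2`
#'   (pooled residual variance), `df`, `log_scale`.
#' @export
fit_oneway <- function(values, groups, log_scale = FALSE) {
  keep <- is.finite(values)
  values <- values[keep]
  groups <- as.character(groups)[keep]
  if (any(values < 0)) stop("quantities must be >= 0 or NA", call. = FALSE)
  n <- table(groups)
  if (length(n) < 2) stop("model error: need at least two classes", call. = FALSE)
  if (any(n < 2)) {
    stop("model error: class(es) with fewer than 2 samples: ",
         paste(names(n)[n < 2], collapse = ", "), call. = FALSE)
  }
  if (log_scale) {
    if (any(values <= 0)) stop("log scale requires positive quantities", call. = FALSE)
    values <- log(values)
  }
  ls_means <- tapply(values, groups, mean)
  sse <- sum((values - ls_means[groups])^2)
  df <- length(values) - length(n)
  sigma2 <- sse / df
  if (sigma2 == 0) {
    stop("degenerate-model error: zero residual variance", call. = FALSE)
  }
  structure(list(ls_means = ls_means,
                 n_per_class = stats::setNames(as.integer(n), names(n)),
                 sigma2 = sigma2, df = df, log_scale = log_scale),
            class = "oneway_fit")
}

#' Default significance-code map
#'
#' The conventional star map: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `NS` otherwise.
#'
#' @return Named numeric vector of upper p bounds.
#' @export
default_star_map <- function() c("***" = 0.001, "**" = 0.01, "*" = 0.05)

star_code <- function(p, star_map = default_star_map()) {
  star_map <- sort(star_map)
  for (code in names(star_map)) if (p < star_map[[code]]) return(code)
  "NS"
}

#' LS-mean contrast between two classes
#'
#' Student t test of `H0: LSM(a) = LSM(b)` using the model's pooled residual
#' variance: `t = (LSM_a - LSM_b) / SE` with
#' `SE = sqrt(sigma2 * (1/n_a + 1/n_b))` and the model residual df; the
#' two-sided p-value comes from the Student t distribution. The reported
#' ratio is `LSM_a / LSM_b` (on the original scale; under a log-scale model
#' the ratio is the exponentiated LS-mean difference). With exactly two
#' classes in the model this reduces to the classical pooled two-sample
#' t test.
#'
#' @param model A [fit_oneway()] result.
#' @param class_a,class_b Class labels present in the model (`class_a` is
#'   the numerator of the ratio, conventionally the patient class).
#' @param star_map Named numeric vector mapping significance codes to upper
#'   p bounds (default [default_star_map()]).
#' @param gene_id Optional gene id carried into the output.
#' @return One-row `data.frame`: `gene_id`, `class_a`, `class_b`, `ratio`,
#'   `t_statistic`, `df`, `p_value`, `code`.
#' @export
contrast <- function(model, class_a, class_b, star_map = default_star_map(),
                     gene_id = NA_character_) {
  stopifnot(inherits(model, "oneway_fit"))
  for (cl in c(class_a, class_b)) {
    if (!cl %in% names(model$ls_means)) {
      stop("class '", cl, "' not in model", call. = FALSE)
    }
  }
  la <- model$ls_means[[class_a]]
  lb <- model$ls_means[[class_b]]
  if (!model$log_scale && lb == 0) {
    stop("ratio undefined: LS mean of '", class_b, "' is zero", call. = FALSE)
  }
  se <- sqrt(model$sigma2 * (1 / model$n_per_class[[class_a]] +
                             1 / model$n_per_class[[class_b]]))
  t_stat <- (la - lb) / se
  p <- 2 * stats::pt(-abs(t_stat), df = model$df)
  data.frame(gene_id = gene_id, class_a = class_a, class_b = class_b,
             ratio = if (model$log_scale) exp(la - lb) else la / lb,
             t_statistic = t_stat, df = model$df, p_value = p,
             code = star_code(p, star_map), stringsAsFactors = FALSE)
}

#' Per-gene group contrasts across a quantity table
#'
#' Runs [fit_oneway()] + [contrast()] for every gene: one model per gene
#' over the requested patient classes plus the control class, then one
#' contrast per patient class vs control — the layout of a per-class
#' ratio/significance marker table. As the models are one-factorial, no
#' multiplicity adjustment is applied to the reported p-values; an optional
#' Benjamini-Hochberg column (`p_bh`, across genes within each class) can be
#' added as clearly-labelled extra output.
#'
#' @param quantities Long `data.frame` (`gene_id`, `sample_id`, `quantity`)
#'   as from [quantify_plate()]; non-quantifiable rows may carry `NA`.
#' @param groups Character vector of class labels named by sample id.
#' @param classes Patient classes to contrast (default missense and
#'   truncating).
#' @param control Control class label (default `"control"`).
#' @param star_map See [contrast()].
#' @param log_scale See [fit_oneway()].
#' @param add_bh Add the Benjamini-Hochberg `p_bh` column (default FALSE).
#' @return `data.frame` with one row per gene x class: `gene_id`, `class`,
#'   `ratio`, `t_statistic`, `df`, `p_value`, `code` (and optionally
#'   `p_bh`). Genes whose model cannot be fitted (e.g. all-NA class) are
#'   skipped with a message.
#' @export
contrast_table <- function(quantities, groups,
                           classes = c("missense", "truncating"),
                           control = "control",
                           star_map = default_star_map(),
                           log_scale = FALSE, add_bh = FALSE) {
  stopifnot(all(c("gene_id", "sample_id", "quantity") %in% names(quantities)))
  rows <- list()
  for (g in unique(quantities$gene_id)) {
    sub <- quantities[quantities$gene_id == g, , drop = FALSE]
    cls <- groups[sub$sample_id]
    keep <- cls %in% c(classes, control)
    fit <- tryCatch(fit_oneway(sub$quantity[keep], cls[keep], log_scale = log_scale),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      message("skipping gene ", g, ": ", conditionMessage(fit))
      next
    }
    for (cl in intersect(classes, names(fit$ls_means))) {
      cc <- contrast(fit, cl, control, star_map = star_map, gene_id = g)
      rows[[length(rows) + 1L]] <-
        data.frame(gene_id = g, class = cl, ratio = cc$ratio,
                   t_statistic = cc$t_statistic, df = cc$df,
                   p_value = cc$p_value, code = cc$code,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  if (add_bh) {
    out$p_bh <- NA_real_
    for (cl in unique(out$class)) {
      i <- out$class == cl
      out$p_bh[i] <- stats::p.adjust(out$p_value[i], method = "BH")
    }
  }
  rownames(out) <- NULL
  out
}
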