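#' Expression matrix with sample group labels
#'
#' The common substrate of every analysis stage: a non-negative gene x sample
#' matrix of array intensities or qPCR-derived quantities, plus one group
#' label per sample. Valid labels are `missense`, `truncating`, `control` and
#' `unknown` (blind samples awaiting classification).
#'
#' @param values Numeric matrix, genes in rows, samples in columns; rownames
#'   are gene identifiers and colnames sample identifiers, both unique; all
#'   values must be finite and >= 0.
#' @param groups Character vector of group labels, either named by sample id
#'   or in column order.
#' @return An object of class `expression_matrix` with fields `values` and
#'   `groups` (a character vector named by sample id).
#' @examples
#' m <- matrix(c(2, 6, 4, 8), nrow = 2,
#'             dimnames = list(c("gA", "gB"), c("s1", "s2")))
#' expression_matrix(m, c(s1 = "control", s2 = "missense"))
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' needs gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicated gene ids", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicated sample ids", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("expression values must be finite and non-negative", call. = FALSE)
  }
  groups <- as.character(groups)
  if (is.null(names(groups))) {
    if (length(groups) != ncol(values)) {
      stop("unnamed 'groups' must have one label per sample", call. = FALSE)
    }
    names(groups) <- colnames(values)
  }
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing)) {
    stop("no group label for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  groups <- groups[colnames(values)]
  bad <- setdiff(unique(groups), c("missense", "truncating", "control", "unknown"))
  if (length(bad)) {
    stop("invalid group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(values = values, groups = groups), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  tab <- table(x$groups)
  cat("groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by genes and/or samples
#'
#' @param x An `expression_matrix`.
#' @param genes,samples Character vectors of identifiers to keep (`NULL` =
#'   keep all). Unknown identifiers are an error.
#' @return An `expression_matrix`.
#' @export
em_subset <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  genes <- genes %||% rownames(x$values)
  samples <- samples %||% colnames(x$values)
  if (length(bad <- setdiff(genes, rownames(x$values)))) {
    stop("unknown gene(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(bad <- setdiff(samples, colnames(x$values)))) {
    stop("unknown sample(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  expression_matrix(x$values[genes, samples, drop = FALSE], x$groups[samples])
}

#' Write / read an expression matrix as TSV
#'
#' The on-disk layout is a header row of sample ids with a leading `gene_id`
#' column, one gene per row. Group labels travel separately in a sample
#' sheet (see [write_sample_sheet()]).
#'
#' @param x An `expression_matrix`.
#' @param path File path.
#' @return `write_expression_tsv` returns `path` invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param sample_sheet A sample-sheet `data.frame` (columns `sample_id`,
#'   `group`) or a path to one, used to attach group labels.
#' @return `read_expression_tsv` returns an `expression_matrix`.
#' @export
read_expression_tsv <- function(path, sample_sheet) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
  groups <- stats::setNames(sample_sheet$group, sample_sheet$sample_id)
  expression_matrix(vals, groups)
}

#' Write / read a sample sheet as TSV
#'
#' Columns: `sample_id`, `group`, and optionally `mutation_type` (free text,
#' e.g. the specific KDM5C change a simulated patient is meant to carry).
#'
#' @param groups Character vector of group labels named by sample id, or an
#'   `expression_matrix` (its labels are used).
#' @param path File path.
#' @param mutation_type Optional character vector aligned with `groups`.
#' @return `write_sample_sheet` returns `path` invisibly;
#'   `read_sample_sheet` a `data.frame`.
#' @export
write_sample_sheet <- function(groups, path, mutation_type = NULL) {
  if (inherits(groups, "expression_matrix")) groups <- groups$groups
  df <- data.frame(sample_id = names(groups), group = unname(groups),
                   stringsAsFactors = FALSE)
  if (!is.null(mutation_type)) df$mutation_type <- mutation_type
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("sample sheet needs 'sample_id' and 'group' columns", call. = FALSE)
  }
  df
}

#' Assemble an expression matrix from a long quantity table
#'
#' Convenience bridge from [quantify_plate()] output (long format with a
#' `status` column) to the matrix container the group contrasts and WAPDG
#' stages consume. Non-quantifiable measurements become `NA` and any gene
#' with an `NA` in a retained sample is dropped (with a message), because
#' downstream stages require complete non-negative values.
#'
#' @param quantities `data.frame` with columns `gene_id`, `sample_id`,
#'   `quantity`, `status`.
#' @param groups Character vector of group labels named by sample id.
#' @return An `expression_matrix`.
#' @export
quantities_to_matrix <- function(quantities, groups) {
  stopifnot(all(c("gene_id", "sample_id", "quantity") %in% names(quantities)))
  genes <- unique(quantities$gene_id)
  samples <- unique(quantities$sample_id)
  vals <- matrix(NA_real_, length(genes), length(samples),
                 dimnames = list(genes, samples))
  vals[cbind(match(quantities$gene_id, genes),
             match(quantities$sample_id, samples))] <- quantities$quantity
  incomplete <- rownames(vals)[apply(vals, 1, anyNA)]
  if (length(incomplete)) {
    message("dropping ", length(incomplete),
            " gene(s) without complete quantification: ",
            paste(incomplete, collapse = ", "))
    vals <- vals[setdiff(rownames(vals), incomplete), , drop = FALSE]
  }
  expression_matrix(vals, groups[samples])
}
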