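#' KDM5C marker panel with reported patient/control expression ratios
#'
#' The twelve lymphoblastoid marker genes of the KDM5C expression
#' fingerprint, with the reported LS-mean patient/control expression ratios
#' per mutation class (missense changes vs protein-truncating mutations) and
#' each gene's regulation direction. These ratios are the printed effect
#' sizes the synthetic cohorts use as generator truth; `TNFSF4` is the single
#' down-regulated gene and is excluded from the default combined WAPDG panel.
#'
#' @return A `data.frame` with columns `gene_id`, `ratio_missense`,
#'   `ratio_truncating`, `direction` (`"up"`/`"down"`).
#' @seealso [upregulated_panel()], [diagnostic_subset()]
#' @export
kdm5c_marker_ratios <- function() {
  data.frame(
    gene_id = c("CETP", "CD55", "CMKOR1", "EMILIN2", "HSPA1B", "KDM5B",
                "KIAA0469", "MGC20983", "MKNK2", "MYC", "SLAMF6", "TNFSF4"),
    ratio_missense = c(4.34, 2.03, 6.85, 2.34, 4.00, 3.18,
                       1.52, 2.72, 2.07, 2.54, 2.71, 0.20),
    ratio_truncating = c(8.57, 1.88, 6.29, 2.49, 2.66, 1.94,
                         1.74, 2.94, 2.40, 2.89, 2.41, 0.12),
    direction = c(rep("up", 11), "down"),
    stringsAsFactors = FALSE
  )
}

#' The eleven up-regulated marker genes
#'
#' The default WAPDG combination panel: every marker except the
#' down-regulated `TNFSF4`.
#'
#' @return Character vector of gene ids.
#' @export
upregulated_panel <- function() {
  m <- kdm5c_marker_ratios()
  m$gene_id[m$direction == "up"]
}

#' The six-gene diagnostic subset
#'
#' A reduced panel (CETP, CMKOR1, EMILIN2, HSPA1B, MYC, SLAMF6) reported to
#' retain full patient/control discrimination.
#'
#' @return Character vector of gene ids.
#' @export
diagnostic_subset <- function() {
  c("CETP", "CMKOR1", "EMILIN2", "HSPA1B", "MYC", "SLAMF6")
}

#' Spike table for a validation-style cohort at the reported ratios
#'
#' Builds the [sim_config()] `spike_table` that plants each marker gene's
#' reported missense and truncating ratios as true generator fold changes.
#'
#' @param genes Marker gene ids to include (default: all twelve).
#' @param classes Patient classes to spike (default both).
#' @return A `data.frame` with columns `gene_id`, `group`, `fold`.
#' @export
marker_spike_table <- function(genes = kdm5c_marker_ratios()$gene_id,
                               classes = c("missense", "truncating")) {
  m <- kdm5c_marker_ratios()
  m <- m[m$gene_id %in% genes, , drop = FALSE]
  if (nrow(m) < length(genes)) {
    stop("unknown marker gene(s): ",
         paste(setdiff(genes, m$gene_id), collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, lapply(classes, function(cl) {
    data.frame(gene_id = m$gene_id, group = cl,
               fold = m[[paste0("ratio_", cl)]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
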