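#' Pipeline configuration
#'
#' A single validated configuration object for [run_pipeline()]: which
#' stages to run, where artifacts go, the analysis thresholds, and either
#' simulation settings or paths to existing inputs. Can also be loaded from
#' a YAML file mirroring these fields via [read_pipeline_config()].
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Global integer seed; stage substreams derive from it via
#'   [stage_seed()].
#' @param stages Character subset of `c("simulate", "select", "quantify",
#'   "contrast", "wapdg", "classify")`, executed in this canonical order.
#' @param discovery Arguments for the discovery-array [sim_config()] (used
#'   by `simulate` + `select`), or `NULL` to skip the array arm.
#' @param validation Arguments for the validation-qPCR [sim_config()] (used
#'   by `simulate` + downstream stages), or `NULL`.
#' @param inputs Named list of paths for runs on existing data:
#'   `matrix`, `neg_controls`, `sample_sheet` (array arm);
#'   `plate`, `standards`, `qpcr_sample_sheet` (qPCR arm); or a ready-made
#'   `quantities` TSV (skipping quantification). Referenced files must
#'   exist at configuration time.
#' @param thresholds Named list overriding any of: `ds`, `ds_strict`,
#'   `detection`, `min_fold`, `detection_max`, `ct_ceiling`, `max_ct_sd`,
#'   `alpha`, `n_draws`, plus `tech_cv` (variance-model CV for the DS
#'   z-test).
#' @param panel WAPDG panel gene ids (default [upregulated_panel()]).
#' @param patient Discovery patient sample id (default: the single
#'   non-control sample).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            stages = c("simulate", "select", "quantify",
                                       "contrast", "wapdg", "classify"),
                            discovery = NULL,
                            validation = NULL,
                            inputs = list(),
                            thresholds = list(),
                            panel = upregulated_panel(),
                            patient = NULL) {
  known <- c("simulate", "select", "quantify", "contrast", "wapdg", "classify")
  if (length(bad <- setdiff(stages, known))) {
    stop("configuration error: unknown stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(ds = 50, ds_strict = 100, detection = 0.99, min_fold = 2,
                   detection_max = NULL, ct_ceiling = 35, max_ct_sd = 0.5,
                   alpha = 0.005, n_draws = 1000, tech_cv = 0.1)
  if (length(bad <- setdiff(names(thresholds), names(defaults)))) {
    stop("configuration error: unknown threshold(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  thresholds <- utils::modifyList(defaults, thresholds)
  for (p in Filter(is.character, inputs)) {
    if (!file.exists(p)) {
      stop("configuration error: input file not found: ", p, call. = FALSE)
    }
  }
  if (!"simulate" %in% stages) {
    if ("select" %in% stages &&
        !all(c("matrix", "neg_controls", "sample_sheet") %in% names(inputs))) {
      stop("configuration error: 'select' without 'simulate' needs inputs ",
           "matrix, neg_controls, sample_sheet", call. = FALSE)
    }
    if ("quantify" %in% stages &&
        !all(c("plate", "standards", "qpcr_sample_sheet") %in% names(inputs))) {
      stop("configuration error: 'quantify' without 'simulate' needs inputs ",
           "plate, standards, qpcr_sample_sheet", call. = FALSE)
    }
    if (!"quantify" %in% stages &&
        any(c("contrast", "wapdg", "classify") %in% stages) &&
        !all(c("quantities", "qpcr_sample_sheet") %in% names(inputs))) {
      stop("configuration error: downstream stages need inputs ",
           "quantities + qpcr_sample_sheet when 'quantify' is disabled",
           call. = FALSE)
    }
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = intersect(known, stages), discovery = discovery,
                 validation = validation, inputs = inputs,
                 thresholds = thresholds, panel = panel, patient = patient),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file mirroring the `pipeline_config` fields.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", ...)
  writeLines(msg, con)
}

run_stage <- function(name, log_con, expr) {
  log_line(log_con, "stage ", name, ": start")
  res <- tryCatch(expr, error = function(e) {
    log_line(log_con, "stage ", name, ": ERROR ", conditionMessage(e))
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
  })
  log_line(log_con, "stage ", name, ": done")
  res
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the enabled stages in order — simulate the discovery array and
#' validation qPCR cohorts, normalise/detect/select candidate genes,
#' quantify the qPCR plate, compute per-class group contrasts, run the
#' WAPDG panel statistic, and classify any `unknown` samples — writing
#' per-stage TSV/JSON artifacts plus a timestamped run log (`run.log`)
#' recording the seed, package version and full threshold set. Errors abort
#' with a stage-tagged message.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of stage results and artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- function(name) file.path(config$out_dir, name)
  log_con <- file(art("run.log"), open = "wt")
  on.exit(close(log_con))
  log_line(log_con, "run_pipeline wapdgkit ",
           as.character(utils::packageVersion("wapdgkit")),
           " seed=", config$seed)
  log_line(log_con, "thresholds: ",
           paste(names(config$thresholds),
                 vapply(config$thresholds,
                        function(v) if (is.null(v)) "default" else format(v), ""),
                 sep = "=", collapse = " "))
  th <- config$thresholds
  results <- list(paths = character())
  add_path <- function(p) results$paths <<- c(results$paths, p)

  arr <- NULL; plate <- NULL
  if ("simulate" %in% config$stages) {
    run_stage("simulate", log_con, {
      if (!is.null(config$discovery)) {
        dcfg <- do.call(sim_config, utils::modifyList(
          config$discovery, list(seed = stage_seed(config$seed, "array"))))
        arr <- simulate_array_experiment(dcfg)
        add_path(write_expression_tsv(arr$expr, art("discovery_expr.tsv")))
        add_path(write_expression_tsv(arr$neg_controls, art("discovery_neg.tsv")))
        add_path(write_sample_sheet(arr$expr, art("discovery_samples.tsv")))
      }
      if (!is.null(config$validation)) {
        vargs <- config$validation
        sim_args <- vargs[intersect(names(vargs), names(formals(sim_config)))]
        plate_args <- vargs[intersect(names(vargs),
                                      setdiff(names(formals(simulate_qpcr_experiment)), "config"))]
        vcfg <- do.call(sim_config, utils::modifyList(
          sim_args, list(seed = stage_seed(config$seed, "qpcr"))))
        plate <- do.call(simulate_qpcr_experiment, c(list(vcfg), plate_args))
        write_qpcr_plate(plate, art("plate.tsv"), art("standards.tsv"))
        add_path(art("plate.tsv")); add_path(art("standards.tsv"))
        add_path(write_sample_sheet(plate$groups, art("qpcr_samples.tsv")))
      }
      NULL
    })
  }

  if ("select" %in% config$stages) {
    results$candidates <- run_stage("select", log_con, {
      if (is.null(arr)) {
        expr <- read_expression_tsv(config$inputs$matrix, config$inputs$sample_sheet)
        neg <- read_expression_tsv(config$inputs$neg_controls, config$inputs$sample_sheet)
      } else {
        expr <- arr$expr; neg <- arr$neg_controls
      }
      controls <- names(expr$groups)[expr$groups == "control"]
      patient <- config$patient %||% setdiff(names(expr$groups), controls)
      if (length(patient) != 1) {
        stop("discovery design needs exactly one patient sample (got ",
             length(patient), "); set config$patient")
      }
      normalized <- rank_invariant_normalize(expr, reference_sample = controls[1])
      det <- detection_scores(normalized, neg)
      vm <- fit_variance_model(neg, cv = th$tech_cv)
      cand <- select_candidates(
        normalized, det, patient, controls,
        candidate_thresholds(ds = th$ds, ds_strict = th$ds_strict,
                             detection = th$detection, min_fold = th$min_fold,
                             detection_max = th$detection_max),
        vm)
      utils::write.table(cand, art("candidates.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      add_path(art("candidates.tsv"))
      cand
    })
  }

  groups <- NULL
  quantities <- NULL
  if ("quantify" %in% config$stages) {
    results$quantities <- run_stage("quantify", log_con, {
      if (is.null(plate)) {
        plate <- read_qpcr_plate(config$inputs$plate, config$inputs$standards,
                                  config$inputs$qpcr_sample_sheet)
      }
      q <- quantify_plate(plate, qc = qc_rules(ct_ceiling = th$ct_ceiling,
                                               max_ct_sd = th$max_ct_sd))
      utils::write.table(q, art("quantities.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      add_path(art("quantities.tsv"))
      q
    })
    quantities <- results$quantities
    groups <- plate$groups
  } else if (any(c("contrast", "wapdg", "classify") %in% config$stages)) {
    if (!is.null(plate)) {
      quantities <- quantify_plate(plate)
      groups <- plate$groups
    } else {
      quantities <- utils::read.delim(config$inputs$quantities, stringsAsFactors = FALSE)
      sheet <- read_sample_sheet(config$inputs$qpcr_sample_sheet)
      groups <- stats::setNames(sheet$group, sheet$sample_id)
    }
  }

  if ("contrast" %in% config$stages) {
    results$contrasts <- run_stage("contrast", log_con, {
      known_cls <- intersect(c("missense", "truncating"), unique(groups))
      ct <- contrast_table(quantities, groups, classes = known_cls)
      utils::write.table(ct, art("contrasts.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      add_path(art("contrasts.tsv"))
      ct
    })
  }

  model <- NULL
  if ("wapdg" %in% config$stages) {
    results$wapdg <- run_stage("wapdg", log_con, {
      known <- names(groups)[groups != "unknown"]
      mat <- quantities_to_matrix(
        quantities[quantities$sample_id %in% known, , drop = FALSE], groups)
      panel <- intersect(config$panel, rownames(mat$values))
      if (!length(panel)) stop("no panel genes present in quantity matrix")
      model <- wapdg_analyze(mat, gene_set = panel, n_draws = th$n_draws,
                              seed = config$seed)
      res_json <- list(seed = config$seed, n_draws = th$n_draws,
                       gene_set = panel,
                       per_gene = model$per_gene,
                       combined_proportion = model$combined_proportion,
                       combined_p_bound = model$combined_p_bound)
      jsonlite::write_json(res_json, art("wapdg_result.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      add_path(art("wapdg_result.json"))
      add_path(write_wapdg_model(model, art("wapdg_model.json")))
      model
    })
  }

  if ("classify" %in% config$stages) {
    results$verdicts <- run_stage("classify", log_con, {
      if (is.null(model)) stop("classification needs the wapdg stage (or a model)")
      unknowns <- names(groups)[groups == "unknown"]
      verdicts <- NULL
      if (!length(unknowns)) {
        log_line(log_con, "stage classify: no unknown samples")
      } else {
        verdicts <- do.call(rbind, lapply(unknowns, function(s) {
          v <- quantities[quantities$sample_id == s, , drop = FALSE]
          classify_sample(stats::setNames(v$quantity, v$gene_id), model,
                          alpha = th$alpha, sample_id = s)
        }))
        utils::write.table(verdicts, art("verdicts.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        add_path(art("verdicts.tsv"))
      }
      verdicts
    })
  }

  log_line(log_con, "run complete: ", length(results$paths), " artifact(s)")
  invisible(results)
}
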