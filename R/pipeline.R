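#' Pipeline run configuration
#'
#' Collects every tunable threshold of the analysis in one place so a run
#' is fully described by its configuration and seed.
#'
#' @param bmr_grid Candidate BMR thresholds in percent.
#' @param bmr_tol Stabilization tolerance for [select_bmr()].
#' @param anchor Baseline-anchor responses on the plate VC before analysis.
#' @param vc_threshold VC baseline ceiling in percent.
#' @param dup_threshold Duplicate concordance limit in log10 units.
#' @param cutoff_p Tail probability of the specificity noise cutoff.
#' @param strict_qc Drop plates failing the VC mortality checks instead of
#'   only flagging them.
#' @param collapse_level Defect-group level for ontology collapsing.
#' @return `run_config` list.
#' @export
run_config <- function(bmr_grid = seq(5, 95, by = 5), bmr_tol = 0.05,
                       anchor = TRUE, vc_threshold = 20, dup_threshold = 0.5,
                       cutoff_p = 0.05, strict_qc = FALSE,
                       collapse_level = c("general", "granular")) {
  structure(
    list(
      bmr_grid = bmr_grid, bmr_tol = bmr_tol, anchor = anchor,
      vc_threshold = vc_threshold, dup_threshold = dup_threshold,
      cutoff_p = cutoff_p, strict_qc = strict_qc,
      collapse_level = match.arg(collapse_level)
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file with any subset of the fields above.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(paste("unknown config fields:", paste(unknown, collapse = ", ")))
  }
  if (!is.null(vals$bmr_grid) && is.character(vals$bmr_grid)) {
    # "5:95:5" shorthand
    parts <- as.numeric(strsplit(vals$bmr_grid, ":")[[1]])
    vals$bmr_grid <- seq(parts[1], parts[2], by = parts[3])
  }
  do.call(run_config, vals)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline for one dataset (lab)
#'
#' Ordered stages: validate, endpoint construction, QC, BMR estimation,
#' BMC fitting, specificity analysis, ontology collapse. Each stage's
#' result is returned; when `out_dir` is given, artifacts are also written
#' (`endpoint_data.csv`, `qc_vc.csv`, `bmr.json`, `bmc.csv`,
#' `specificity.csv`, `substance_calls.csv`, `groupcalls.csv`,
#' `qc_report.json`). Artifacts already written are retained when a later
#' stage fails; the error names the failing stage.
#'
#' @param wells,manifest,recordings One lab's data (see [simulate_study()]
#'   or the CSV readers).
#' @param map Optional ontology mapping tibble; when `NULL` the collapse
#'   stage is skipped.
#' @param lab Lab id used to select recordings from the map.
#' @param config A [run_config()].
#' @param out_dir Optional artifact directory (created if needed).
#' @return List with `violations`, `endpoint_data`, `qc`, `bmr`, `bmc`,
#'   `specificity`, `group_calls` (NULL without a map).
#' @export
run_pipeline <- function(wells, manifest, recordings, map = NULL,
                         lab = recordings$lab_id[1], config = run_config(),
                         out_dir = NULL) {
  write_artifact <- function(x, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    path <- file.path(out_dir, name)
    if (grepl("\\.json$", name)) {
      jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else {
      readr::write_csv(x, path)
    }
    invisible(path)
  }

  violations <- pipeline_stage("validate", {
    v <- validate_dataset(wells, manifest, recordings)
    if (nrow(v)) {
      warn(sprintf("dataset has %d validation finding(s); see $violations", nrow(v)))
    }
    v
  })

  vc_flags <- pipeline_stage("qc_vc", {
    check_vc(wells, manifest, recordings, config$vc_threshold)
  })
  write_artifact(vc_flags, "qc_vc.csv")

  if (config$strict_qc) {
    failing <- vc_flags |>
      filter(!.data$pass, grepl("^Mortality", .data$endpoint)) |>
      pull(.data$plate_id) |>
      unique()
    if (length(failing)) {
      inform(sprintf("strict QC: excluding %d plate(s) failing VC mortality",
                     length(failing)))
      wells <- wells |> filter(!.data$plate_id %in% failing)
    }
  }

  endpoint_data <- pipeline_stage("endpoints", {
    build_endpoint_data(wells, manifest, recordings)
  })
  write_artifact(endpoint_data, "endpoint_data.csv")

  bmr <- pipeline_stage("bmr", {
    estimate_dataset_bmr(endpoint_data, grid = config$bmr_grid,
                         tol = config$bmr_tol, anchor = config$anchor)
  })
  write_artifact(
    setNames(as.list(bmr$bmr), bmr$endpoint), "bmr.json"
  )

  bmc <- pipeline_stage("bmc", {
    fit_bmc(endpoint_data, bmr, anchor = config$anchor)
  })
  write_artifact(bmc, "bmc.csv")

  qc <- pipeline_stage("qc", {
    qc_report(wells, manifest, recordings, bmc,
              vc_threshold = config$vc_threshold,
              dup_threshold = config$dup_threshold)
  })
  write_artifact(
    list(
      n_vc_failures = sum(!qc$vc_flags$pass),
      pc_median_sd = qc$pc$median_sd %||% NA,
      pc_median_fold = qc$pc$median_fold %||% NA,
      n_discordant_duplicates = qc$duplicates$n_discordant
    ),
    "qc_report.json"
  )

  pc_ids <- manifest$substance_id[manifest$role == "positive_control"]
  spec <- pipeline_stage("specificity", {
    specificity_analysis(bmc |> filter(!.data$substance_id %in% pc_ids),
                         p = config$cutoff_p)
  })
  write_artifact(spec$plate_calls, "specificity.csv")
  write_artifact(spec$substance_calls, "substance_calls.csv")

  group_calls <- NULL
  if (!is.null(map)) {
    group_calls <- pipeline_stage("ontology", {
      collapse_calls(spec$substance_calls, map, lab = lab,
                     level = config$collapse_level)
    })
    write_artifact(group_calls, "groupcalls.csv")
  }

  list(
    violations = violations, endpoint_data = endpoint_data, qc = qc,
    bmr = bmr, bmc = bmc, specificity = spec, group_calls = group_calls
  )
}
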