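#' Describe a 96-well screening plate layout
#'
#' A plate carries one test substance at several concentrations (one embryo
#' per well), a block of vehicle-control (VC) wells, and a positive-control
#' (PC) dilution series with one embryo per PC concentration. The well
#' arithmetic must account for every well on the plate.
#'
#' @param n_test_concentrations Number of test-substance concentrations.
#' @param n_embryos_per_concentration Embryos (wells) per test concentration.
#' @param n_vc_wells Vehicle-control wells per plate.
#' @param n_pc_wells Positive-control wells per plate (one concentration each).
#' @param dosing_scenario `"S"` (single/static dose) or `"SR"` (static renewal,
#'   media plus substance replaced every 24 h).
#' @param chorion_status `"C"` (chorion intact) or `"DC"` (de-chorionated).
#' @param plate_size Total wells on the plate; the four blocks must sum to it.
#'
#' @return A `plate_design` list with the validated fields.
#' @examples
#' plate_design(7, 11)   # 77 + 12 + 7 = 96
#' plate_design(11, 7)   # 77 + 12 + 7 = 96
#' @export
plate_design <- function(n_test_concentrations,
                         n_embryos_per_concentration,
                         n_vc_wells = 12,
                         n_pc_wells = 7,
                         dosing_scenario = c("S", "SR"),
                         chorion_status = c("C", "DC"),
                         plate_size = 96) {
  dosing_scenario <- match.arg(dosing_scenario)
  chorion_status <- match.arg(chorion_status)
  stopifnot(
    n_test_concentrations >= 1, n_embryos_per_concentration >= 1,
    n_vc_wells >= 0, n_pc_wells >= 0
  )
  total <- n_test_concentrations * n_embryos_per_concentration +
    n_vc_wells + n_pc_wells
  if (total != plate_size) {
    abort(sprintf(
      "plate design does not fill the plate: %d test + %d VC + %d PC wells = %d, expected %d",
      n_test_concentrations * n_embryos_per_concentration,
      n_vc_wells, n_pc_wells, total, plate_size
    ))
  }
  structure(
    list(
      n_test_concentrations = as.integer(n_test_concentrations),
      n_embryos_per_concentration = as.integer(n_embryos_per_concentration),
      n_vc_wells = as.integer(n_vc_wells),
      n_pc_wells = as.integer(n_pc_wells),
      dosing_scenario = dosing_scenario,
      chorion_status = chorion_status,
      plate_size = as.integer(plate_size)
    ),
    class = "plate_design"
  )
}

#' @export
print.plate_design <- function(x, ...) {
  cat(sprintf(
    "<plate_design> %d conc x %d embryos + %d VC + %d PC = %d wells [%s-%s]\n",
    x$n_test_concentrations, x$n_embryos_per_concentration,
    x$n_vc_wells, x$n_pc_wells, x$plate_size,
    x$dosing_scenario, x$chorion_status
  ))
  invisible(x)
}

#' Built-in laboratory plate designs
#'
#' Two layouts are in routine use: a wide-spacing design with 7 test
#' concentrations and 11 embryos per concentration, and a narrow-spacing
#' design with 11 concentrations and 7 embryos each. Both carry 12 VC wells
#' and a 7-well PC series, filling the 96-well plate exactly.
#'
#' @return Named list of three [plate_design()] objects (`lab_A`, `lab_B`,
#'   `lab_C`), reflecting the test condition each laboratory runs in-house:
#'   static renewal/chorion, static/de-chorion, and static/chorion.
#' @export
lab_designs <- function() {
  list(
    lab_A = plate_design(7, 11, dosing_scenario = "SR", chorion_status = "C"),
    lab_B = plate_design(11, 7, dosing_scenario = "S", chorion_status = "DC"),
    lab_C = plate_design(7, 11, dosing_scenario = "S", chorion_status = "C")
  )
}

#' Convert a micromolar concentration to log10 molar
#'
#' Doses are recorded in uM as plated; potency estimates are reported on the
#' log10(molar) scale. 1 uM = 1e-6 M, so 100 uM maps to -4.
#'
#' @param conc_uM Numeric vector of concentrations in micromolar; must be
#'   strictly positive (vehicle-control wells at 0 uM have no molar potency).
#' @return log10(concentration in mol/L).
#' @examples
#' log10_molar(100) # -4
#' log10_molar(1)   # -6
#' @export
log10_molar <- function(conc_uM) {
  if (any(!is.finite(conc_uM)) || any(conc_uM <= 0)) {
    abort("conc_uM must be finite and > 0; 0 uM (vehicle control) has no log10 molar value")
  }
  log10(conc_uM * 1e-6)
}

phenotype_columns <- function(wells, recordings) {
  intersect(unique(recordings$recording_name), names(wells))
}

new_violation <- function(rule, detail, n = NA_integer_) {
  tibble(rule = rule, detail = detail, n = as.integer(n))
}

#' Validate a well-level screening dataset
#'
#' Checks the structural invariants of the data without mutating it:
#' viability consistency (alive at 120 hpf implies alive at 24 hpf),
#' non-negative concentrations, phenotype flags only on survivors, every
#' substance present in the manifest, exactly one positive control in the
#' manifest, blinded duplicate groups of exactly two members, and (when a
#' design is supplied) full plates.
#'
#' @param wells Well-level tibble (see [read_wells_csv()] for the layout).
#' @param manifest Substance manifest tibble with columns `substance_id`,
#'   `role` (`test`, `positive_control`, `vehicle_control`) and optional
#'   `duplicate_group`.
#' @param recordings Recording definitions (`lab_id`, `recording_name`,
#'   `is_binarized_quantitative`); used to locate phenotype columns.
#' @param design Optional [plate_design()]; enables the well-count check.
#' @return A tibble of violations (`rule`, `detail`, `n`); zero rows means
#'   the dataset is valid. Problems are reported, never raised as errors.
#' @export
validate_dataset <- function(wells, manifest, recordings = NULL, design = NULL) {
  out <- list()

  bad_viab <- wells$alive_120 & !wells$alive_24
  if (any(bad_viab)) {
    out[[length(out) + 1L]] <- new_violation(
      "viability inconsistency",
      "wells alive at 120 hpf but recorded dead at 24 hpf",
      sum(bad_viab)
    )
  }

  bad_conc <- wells$conc_uM < 0
  if (any(bad_conc)) {
    out[[length(out) + 1L]] <- new_violation(
      "negative concentration", "conc_uM below 0", sum(bad_conc)
    )
  }

  if (!is.null(recordings)) {
    ph_cols <- phenotype_columns(wells, recordings)
    if (length(ph_cols)) {
      flags <- as.matrix(wells[!wells$alive_120, ph_cols, drop = FALSE])
      n_bad <- sum(flags %in% TRUE)
      if (n_bad > 0) {
        out[[length(out) + 1L]] <- new_violation(
          "phenotype on dead embryo",
          "phenotype flags set for wells not alive at 120 hpf", n_bad
        )
      }
    }
  }

  missing_sub <- setdiff(unique(wells$substance_id), manifest$substance_id)
  if (length(missing_sub)) {
    out[[length(out) + 1L]] <- new_violation(
      "missing substance in manifest",
      paste(missing_sub, collapse = ", "), length(missing_sub)
    )
  }

  n_pc <- sum(manifest$role == "positive_control")
  if (n_pc != 1L) {
    out[[length(out) + 1L]] <- new_violation(
      "positive control count",
      sprintf("manifest lists %d positive controls, expected exactly 1", n_pc),
      n_pc
    )
  }

  if ("duplicate_group" %in% names(manifest)) {
    dup_sizes <- manifest |>
      filter(!is.na(.data$duplicate_group), .data$duplicate_group != "") |>
      count(.data$duplicate_group)
    bad_dup <- dup_sizes |> filter(.data$n != 2L)
    if (nrow(bad_dup)) {
      out[[length(out) + 1L]] <- new_violation(
        "duplicate group size",
        paste(bad_dup$duplicate_group, collapse = ", "), nrow(bad_dup)
      )
    }
  }

  if (!is.null(design)) {
    counts <- wells |> count(.data$plate_id)
    bad_plates <- counts |> filter(.data$n != design$plate_size)
    if (nrow(bad_plates)) {
      out[[length(out) + 1L]] <- new_violation(
        "incomplete plate",
        paste0(bad_plates$plate_id, " (", bad_plates$n, " wells)",
               collapse = ", "),
        nrow(bad_plates)
      )
    }
  }

  if (length(out)) bind_rows(out) else new_violation(character(), character())[0, ]
}

#' Read / write the flat-file exchange formats
#'
#' Wells files are wide: one row per well with the fixed columns
#' `plate_id,run_date,well,substance_id,conc_uM,alive_24,alive_120` followed
#' by one logical column per recording name (empty cell = not assessed, which
#' is how phenotypes of dead embryos are stored).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_wells_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    mutate(
      run_date = as.Date(.data$run_date),
      across(-c("plate_id", "run_date", "well", "substance_id", "conc_uM"),
             as.logical)
    )
}

#' @rdname read_wells_csv
#' @export
read_manifest_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_wells_csv
#' @export
read_recordings_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    mutate(is_binarized_quantitative = as.logical(.data$is_binarized_quantitative))
}

#' @rdname read_wells_csv
#' @param x Tibble to write.
#' @export
write_wells_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' Relational schema for a screening database
#'
#' Emits ANSI-SQL `CREATE TABLE` statements mirroring the pipeline's data
#' model in three groups: substance information, screening data (with the
#' `well` table central), and analysis results. The DDL avoids engine-specific
#' types so it loads into any standard SQL engine.
#'
#' @return A single character scalar of SQL DDL.
#' @export
schema_ddl <- function() {
  paste(
    "-- substance information",
    "CREATE TABLE test_substance (",
    "  substance_id VARCHAR(32) PRIMARY KEY,",
    "  role VARCHAR(20) NOT NULL,",
    "  duplicate_group VARCHAR(32)",
    ");",
    "CREATE TABLE test_substance_identity (",
    "  substance_id VARCHAR(32) PRIMARY KEY REFERENCES test_substance (substance_id),",
    "  dtxsid VARCHAR(32),",
    "  lot VARCHAR(64),",
    "  supplier VARCHAR(128),",
    "  use_category_level1 VARCHAR(64),",
    "  use_category_level2 VARCHAR(64)",
    ");",
    "",
    "-- screening data (the well table is the hub)",
    "CREATE TABLE dataset (",
    "  dataset_id VARCHAR(32) PRIMARY KEY,",
    "  lab_id VARCHAR(32) NOT NULL,",
    "  dosing_scenario VARCHAR(2) NOT NULL,",
    "  chorion_status VARCHAR(2) NOT NULL",
    ");",
    "CREATE TABLE screen_plate (",
    "  plate_id VARCHAR(64) PRIMARY KEY,",
    "  dataset_id VARCHAR(32) REFERENCES dataset (dataset_id),",
    "  run_date TIMESTAMP",
    ");",
    "CREATE TABLE dose (",
    "  dose_id INTEGER PRIMARY KEY,",
    "  substance_id VARCHAR(32) REFERENCES test_substance (substance_id),",
    "  conc_uM DOUBLE PRECISION NOT NULL",
    ");",
    "CREATE TABLE recording (",
    "  recording_id INTEGER PRIMARY KEY,",
    "  lab_id VARCHAR(32) NOT NULL,",
    "  recording_name VARCHAR(128) NOT NULL,",
    "  is_binarized_quantitative BOOLEAN NOT NULL",
    ");",
    "CREATE TABLE phenotype_ontology (",
    "  ontology_id VARCHAR(16) PRIMARY KEY,",
    "  term_label VARCHAR(128) NOT NULL,",
    "  granular_group VARCHAR(64),",
    "  general_group VARCHAR(64)",
    ");",
    "CREATE TABLE well (",
    "  well_id INTEGER PRIMARY KEY,",
    "  plate_id VARCHAR(64) REFERENCES screen_plate (plate_id),",
    "  dose_id INTEGER REFERENCES dose (dose_id),",
    "  well_position VARCHAR(4) NOT NULL,",
    "  alive_24 BOOLEAN NOT NULL,",
    "  alive_120 BOOLEAN NOT NULL",
    ");",
    "CREATE TABLE well_phenotype (",
    "  well_id INTEGER REFERENCES well (well_id),",
    "  recording_id INTEGER REFERENCES recording (recording_id),",
    "  present BOOLEAN NOT NULL,",
    "  PRIMARY KEY (well_id, recording_id)",
    ");",
    "",
    "-- analyses",
    "CREATE TABLE bmc_input_key (",
    "  input_key_id INTEGER PRIMARY KEY,",
    "  endpoint VARCHAR(160) NOT NULL,",
    "  substance_id VARCHAR(32) REFERENCES test_substance (substance_id),",
    "  replicate_key VARCHAR(64) NOT NULL",
    ");",
    "CREATE TABLE bmc_input (",
    "  input_key_id INTEGER REFERENCES bmc_input_key (input_key_id),",
    "  conc_log10M DOUBLE PRECISION NOT NULL,",
    "  response_pct DOUBLE PRECISION NOT NULL,",
    "  n_embryos INTEGER NOT NULL,",
    "  PRIMARY KEY (input_key_id, conc_log10M)",
    ");",
    "CREATE TABLE bmc_output (",
    "  input_key_id INTEGER PRIMARY KEY REFERENCES bmc_input_key (input_key_id),",
    "  bmr_pct DOUBLE PRECISION NOT NULL,",
    "  active BOOLEAN NOT NULL,",
    "  bmc_log10M DOUBLE PRECISION,",
    "  censored_at_max BOOLEAN NOT NULL",
    ");",
    "CREATE TABLE specificity (",
    "  input_key_id INTEGER PRIMARY KEY REFERENCES bmc_input_key (input_key_id),",
    "  recording_id INTEGER REFERENCES recording (recording_id),",
    "  score DOUBLE PRECISION,",
    "  class VARCHAR(16) NOT NULL",
    ");",
    sep = "\n"
  )
}

#' @rdname schema_ddl
#' @param path Where to write the DDL file.
#' @export
write_schema_ddl <- function(path) {
  writeLines(schema_ddl(), path)
  invisible(path)
}
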