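#' Enumerate the 120-hpf endpoints implied by a recording list
#'
#' Each recorded altered phenotype yields one combined endpoint
#' `"<recording>+Mort@120"` whose incidence counts embryos either dead at
#' 120 hpf or alive with the phenotype. Two dataset-level endpoints are
#' always added: `Mortality@120` and `MalformedAny+Mort@120` (dead or
#' malformed in any binary recording), so a lab recording n phenotypes
#' produces n + 2 endpoints at 120 hpf. `Mortality@24` is generated
#' separately (see [mortality24_endpoint()]) and used for QC only.
#'
#' @param recordings Tibble with `recording_name` and
#'   `is_binarized_quantitative` (one lab's recordings).
#' @return Tibble of endpoint definitions: `name`, `timepoint`, `kind`
#'   (`mortality`, `combined_phenotype`, `malformed_any`), `recording`.
#' @examples
#' recs <- tibble::tibble(
#'   recording_name = paste0("Pheno_", 1:21),
#'   is_binarized_quantitative = FALSE
#' )
#' nrow(enumerate_endpoints(recs)) # 23
#' @export
enumerate_endpoints <- function(recordings) {
  stopifnot(anyDuplicated(recordings$recording_name) == 0)
  combined <- tibble(
    name = paste0(recordings$recording_name, "+Mort@120"),
    timepoint = 120L,
    kind = "combined_phenotype",
    recording = recordings$recording_name
  )
  bind_rows(
    tibble(name = "Mortality@120", timepoint = 120L,
           kind = "mortality", recording = NA_character_),
    combined,
    tibble(name = "MalformedAny+Mort@120", timepoint = 120L,
           kind = "malformed_any", recording = NA_character_)
  )
}

#' @rdname enumerate_endpoints
#' @export
mortality24_endpoint <- function() {
  tibble(name = "Mortality@24", timepoint = 24L,
         kind = "mortality", recording = NA_character_)
}

# count affected embryos for one endpoint definition (vector over wells)
endpoint_events <- function(wells, endpoint, recordings) {
  kind <- endpoint$kind
  if (kind == "mortality") {
    if (endpoint$timepoint == 24L) return(!wells$alive_24)
    return(!wells$alive_120)
  }
  if (kind == "combined_phenotype") {
    rec <- endpoint$recording
    if (!rec %in% names(wells)) {
      abort(sprintf("recording '%s' not present in wells data", rec))
    }
    flag <- wells[[rec]] %in% TRUE
    return(!wells$alive_120 | (wells$alive_120 & flag))
  }
  if (kind == "malformed_any") {
    binary <- recordings |> filter(!.data$is_binarized_quantitative)
    cols <- intersect(binary$recording_name, names(wells))
    if (length(cols)) {
      m <- as.matrix(wells[, cols, drop = FALSE])
      any_flag <- rowSums(m == TRUE, na.rm = TRUE) > 0
    } else {
      any_flag <- rep(FALSE, nrow(wells))
    }
    return(!wells$alive_120 | (wells$alive_120 & any_flag))
  }
  abort(sprintf("unknown endpoint kind '%s'", kind))
}

#' Percent response of one endpoint on one substance x plate
#'
#' Converts well-level incidence into a concentration-response record:
#' at each tested concentration the numerator is the count of affected
#' embryos (dead at the endpoint's timepoint, plus survivors with the
#' phenotype for combined endpoints) and the denominator is all embryos
#' dosed at that concentration. Concentrations with no embryos are dropped
#' with a warning rather than imputed.
#'
#' @param wells Wells for a single substance on a single plate (test
#'   concentrations, `conc_uM > 0`).
#' @param endpoint A one-row endpoint definition from
#'   [enumerate_endpoints()] or [mortality24_endpoint()].
#' @param recordings Recording definitions for the lab.
#' @return Tibble `conc_uM`, `conc_log10M`, `n`, `response` (percent,
#'   0-100), ascending in concentration.
#' @export
percent_response <- function(wells, endpoint, recordings = NULL) {
  stopifnot(nrow(wells) > 0)
  if (length(unique(wells$substance_id)) > 1L || length(unique(wells$plate_id)) > 1L) {
    abort("percent_response expects wells from a single substance on a single plate")
  }
  events <- endpoint_events(wells, endpoint, recordings)
  out <- tibble(conc_uM = wells$conc_uM, event = events) |>
    group_by(.data$conc_uM) |>
    summarise(n = n(), response = 100 * sum(.data$event) / n(), .groups = "drop") |>
    arrange(.data$conc_uM)
  empty <- out$n == 0L
  if (any(empty)) {
    warn(sprintf("dropping %d concentration(s) with zero embryos", sum(empty)))
    out <- out[!empty, , drop = FALSE]
  }
  out |> mutate(conc_log10M = log10_molar(.data$conc_uM), .after = "conc_uM")
}

#' Vehicle-control percent response on a plate
#'
#' @param wells VC wells (`conc_uM == 0`) of one plate.
#' @inheritParams percent_response
#' @return Percent response (scalar).
#' @export
vc_response <- function(wells, endpoint, recordings = NULL) {
  if (nrow(wells) == 0) abort("no vehicle-control wells supplied")
  events <- endpoint_events(wells, endpoint, recordings)
  100 * sum(events) / length(events)
}

iso_week <- function(dates) format(as.Date(dates), "%G-W%V")

#' Pool positive-control wells by calendar week
#'
#' Plates carry only one PC embryo per concentration, too few for a
#' concentration-response fit, so PC wells from all plates run within the
#' same ISO calendar week are pooled: the denominator at each concentration
#' is the number of contributing plates.
#'
#' @param pc_wells PC wells across plates (must carry `run_date`).
#' @inheritParams percent_response
#' @return Tibble keyed by `pool_id` (ISO week) with `conc_uM`,
#'   `conc_log10M`, `n`, `response`, and `low_n` flagging single-plate pools.
#' @export
pool_pc_weekly <- function(pc_wells, endpoint, recordings = NULL) {
  if (nrow(pc_wells) == 0) {
    return(tibble(pool_id = character(), conc_uM = numeric(),
                  conc_log10M = numeric(), n = integer(),
                  response = numeric(), low_n = logical()))
  }
  pc_wells |>
    mutate(pool_id = iso_week(.data$run_date),
           event = endpoint_events(pc_wells, endpoint, recordings)) |>
    group_by(.data$pool_id, .data$conc_uM) |>
    summarise(n = n(), response = 100 * sum(.data$event) / n(),
              n_plates = n_distinct(.data$plate_id), .groups = "drop_last") |>
    mutate(low_n = max(.data$n_plates) <= 1L) |>
    ungroup() |>
    mutate(conc_log10M = log10_molar(.data$conc_uM), .after = "conc_uM") |>
    arrange(.data$pool_id, .data$conc_uM) |>
    select("pool_id", "conc_uM", "conc_log10M", "n", "response", "low_n")
}

#' Build the full endpoint input table for one dataset (lab)
#'
#' The analysis currency of the pipeline: one row per endpoint x substance x
#' replicate x concentration, where the replicate is a plate for blinded test
#' substances and an ISO-week pool for the positive control. Each row also
#' carries the same-plate (or pooled-week mean) vehicle-control response for
#' optional baseline anchoring downstream.
#'
#' @param wells Well table of one lab.
#' @param manifest Substance manifest (roles decide VC/PC/test handling).
#' @param recordings The lab's recording definitions.
#' @param endpoints Endpoint definitions; default [enumerate_endpoints()] on
#'   `recordings`.
#' @return Tibble: `endpoint`, `kind`, `recording`, `substance_id`,
#'   `replicate_key`, `conc_uM`, `conc_log10M`, `n`, `response`, `vc_response`.
#' @export
build_endpoint_data <- function(wells, manifest, recordings,
                                endpoints = enumerate_endpoints(recordings)) {
  vc_ids <- manifest$substance_id[manifest$role == "vehicle_control"]
  pc_ids <- manifest$substance_id[manifest$role == "positive_control"]
  vc_wells <- wells |> filter(.data$substance_id %in% vc_ids | .data$conc_uM == 0)
  pc_wells <- wells |> filter(.data$substance_id %in% pc_ids)
  test_wells <- wells |>
    filter(!.data$substance_id %in% c(vc_ids, pc_ids), .data$conc_uM > 0)

  res <- vector("list", nrow(endpoints))
  for (i in seq_len(nrow(endpoints))) {
    ep <- endpoints[i, ]
    # per-plate VC baseline for this endpoint (vectorized event counting)
    vc_by_plate <- vc_wells |>
      mutate(event = endpoint_events(vc_wells, ep, recordings)) |>
      group_by(plate_id = .data$plate_id) |>
      summarise(vc_response = 100 * sum(.data$event) / n(), .groups = "drop")

    test_cr <- test_wells |>
      mutate(event = endpoint_events(test_wells, ep, recordings)) |>
      group_by(.data$substance_id, replicate_key = .data$plate_id,
               .data$conc_uM) |>
      summarise(n = n(), response = 100 * sum(.data$event) / n(),
                .groups = "drop") |>
      mutate(conc_log10M = log10_molar(.data$conc_uM)) |>
      left_join(vc_by_plate, by = c(replicate_key = "plate_id"))

    pc_cr <- pool_pc_weekly(pc_wells, ep, recordings)
    if (nrow(pc_cr)) {
      # pooled weeks anchor to the mean VC response of that week's plates
      vc_by_week <- vc_by_plate |>
        left_join(vc_wells |> distinct(.data$plate_id, .data$run_date),
                  by = "plate_id") |>
        mutate(pool_id = iso_week(.data$run_date)) |>
        group_by(.data$pool_id) |>
        summarise(vc_response = mean(.data$vc_response), .groups = "drop")
      pc_cr <- pc_cr |>
        left_join(vc_by_week, by = "pool_id") |>
        mutate(substance_id = pc_ids[1], replicate_key = .data$pool_id) |>
        select("substance_id", "replicate_key", "conc_uM", "conc_log10M",
               "n", "response", "vc_response")
    } else {
      pc_cr <- NULL
    }

    res[[i]] <- bind_rows(test_cr, pc_cr) |>
      mutate(endpoint = ep$name, kind = ep$kind, recording = ep$recording)
  }
  bind_rows(res) |>
    mutate(vc_response = tidyr::replace_na(.data$vc_response, 0)) |>
    select("endpoint", "kind", "recording", "substance_id", "replicate_key",
           "conc_uM", "conc_log10M", "n", "response", "vc_response") |>
    arrange(.data$endpoint, .data$substance_id, .data$replicate_key, .data$conc_uM)
}
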