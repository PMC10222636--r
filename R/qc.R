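#' Fold-change equivalent of a log10 standard deviation
#'
#' @param sd Standard deviation in log10 concentration units.
#' @return `10^sd`; 1 means no potency shift, 0.5 log10 units is ~3.2-fold.
#' @export
fold_change <- function(sd) 10^sd

#' Vehicle-control baseline check per plate
#'
#' Computes the VC response of the three primary endpoints (`Mortality@24`,
#' `Mortality@120`, `MalformedAny+Mort@120`) on every plate and flags
#' responses strictly above the threshold (default 20%). A response of
#' exactly 20% passes. Flags only: no plate is dropped here — exclusion is
#' a separate, opt-in decision (see `strict` in [run_pipeline()]).
#'
#' @param wells Well table of one lab.
#' @param manifest Substance manifest.
#' @param recordings Recording definitions of the lab.
#' @param threshold Baseline ceiling in percent (default 20).
#' @return Tibble: `plate_id`, `endpoint`, `response`, `pass`.
#' @export
check_vc <- function(wells, manifest, recordings, threshold = 20) {
  vc_ids <- manifest$substance_id[manifest$role == "vehicle_control"]
  vc <- wells |> filter(.data$substance_id %in% vc_ids | .data$conc_uM == 0)
  if (nrow(vc) == 0L) abort("no vehicle-control wells in dataset")
  eps <- bind_rows(
    mortality24_endpoint(),
    enumerate_endpoints(recordings) |>
      filter(.data$name %in% c("Mortality@120", "MalformedAny+Mort@120"))
  )
  out <- list()
  for (i in seq_len(nrow(eps))) {
    ep <- eps[i, ]
    out[[i]] <- vc |>
      group_by(plate_id = .data$plate_id) |>
      group_modify(~ tibble(response = vc_response(
        .x |> mutate(plate_id = .y$plate_id), ep, recordings))) |>
      ungroup() |>
      mutate(endpoint = ep$name)
  }
  bind_rows(out) |>
    mutate(pass = .data$response <= threshold) |>
    select("plate_id", "endpoint", "response", "pass") |>
    arrange(.data$plate_id, .data$endpoint)
}

#' Positive-control reproducibility across the testing period
#'
#' The positive control is analyzed per weekly pool; the spread of its BMC
#' values over the weeks measures potency drift. Reports the sample SD of
#' BMC per endpoint, the median SD across endpoints, and the fold-change
#' equivalents (10^SD).
#'
#' @param pc_bmc BMC results ([fit_bmc()]) restricted to the positive
#'   control, with `replicate_key` the week-pool id.
#' @return List: `per_endpoint` tibble (`endpoint`, `n_pools`, `sd`,
#'   `fold`), `median_sd`, `median_fold`.
#' @export
pc_reproducibility <- function(pc_bmc) {
  per <- pc_bmc |>
    group_by(.data$endpoint) |>
    summarise(n_pools = n(),
              sd = if (n() >= 2L) sd(.data$bmc_log10M) else NA_real_,
              .groups = "drop") |>
    mutate(fold = fold_change(.data$sd))
  if (any(per$n_pools < 2L)) {
    warn("some endpoints have a single PC week-pool; SD undefined there")
  }
  med <- median(per$sd, na.rm = TRUE)
  list(per_endpoint = per, median_sd = med, median_fold = fold_change(med))
}

#' Blinded-duplicate concordance
#'
#' For each blinded duplicate pair and endpoint, the median BMC over the
#' triplicate plates of each member is compared; pairs differing by more
#' than `threshold` log10 units (default 0.5, ~3.2-fold) are flagged.
#' Endpoints where a member is missing are skipped with a warning. The
#' returned `plot_table` drops pairs with identical medians, which would
#' sit exactly on the identity line.
#'
#' @param bmc_tbl BMC results from [fit_bmc()].
#' @param manifest Substance manifest carrying `duplicate_group`.
#' @param threshold Concordance limit in log10 units.
#' @return List: `table` (per duplicate_group x endpoint: `bmc_rep1`,
#'   `bmc_rep2`, `delta`, `concordant`), `plot_table` (non-identical pairs
#'   only), `n_discordant`.
#' @export
duplicate_concordance <- function(bmc_tbl, manifest, threshold = 0.5) {
  dups <- manifest |>
    filter(!is.na(.data$duplicate_group), .data$duplicate_group != "") |>
    select("substance_id", "duplicate_group") |>
    group_by(.data$duplicate_group) |>
    mutate(member = paste0("rep", row_number())) |>
    ungroup()
  med <- bmc_tbl |>
    inner_join(dups, by = "substance_id") |>
    group_by(.data$duplicate_group, .data$member, .data$endpoint) |>
    summarise(bmc = median(.data$bmc_log10M), .groups = "drop")
  wide <- med |>
    tidyr::pivot_wider(names_from = "member", values_from = "bmc",
                       names_prefix = "bmc_")
  incomplete <- is.na(wide$bmc_rep1) | is.na(wide$bmc_rep2)
  if (any(incomplete)) {
    warn(sprintf("skipping %d endpoint(s) missing one duplicate member",
                 sum(incomplete)))
    wide <- wide[!incomplete, , drop = FALSE]
  }
  tab <- wide |>
    mutate(delta = abs(.data$bmc_rep1 - .data$bmc_rep2),
           concordant = .data$delta <= threshold)
  list(
    table = tab,
    plot_table = tab |> filter(.data$delta > 0),
    n_discordant = sum(!tab$concordant)
  )
}

#' Triplicate BMC variability per endpoint
#'
#' The sample SD of the BMC values of each substance's replicates (censored
#' highest-tested-concentration values included for inactive replicates)
#' summarizes run-to-run potency variation. Substances with SD = 0 — all
#' replicates inactive, or identical BMCs — are excluded from the reported
#' distribution (only substances active in at least one run vary).
#'
#' @param bmc_tbl BMC results from [fit_bmc()].
#' @return Tibble: `endpoint`, `substance_id`, `n`, `sd`; only rows with
#'   `sd > 0`.
#' @export
endpoint_variability <- function(bmc_tbl) {
  bmc_tbl |>
    group_by(.data$endpoint, .data$substance_id) |>
    summarise(n = n(), sd = sd(.data$bmc_log10M), .groups = "drop") |>
    filter(.data$n >= 2L, !is.na(.data$sd), .data$sd > 0)
}

#' Assemble the QC report for one dataset
#'
#' @param wells,manifest,recordings One lab's data.
#' @param bmc_tbl BMC results for the lab (test substances and PC pools).
#' @param vc_threshold Baseline ceiling in percent.
#' @param dup_threshold Duplicate concordance limit in log10 units.
#' @return List with elements `vc_flags`, `pc`, `duplicates`,
#'   `endpoint_variability`.
#' @export
qc_report <- function(wells, manifest, recordings, bmc_tbl,
                      vc_threshold = 20, dup_threshold = 0.5) {
  pc_ids <- manifest$substance_id[manifest$role == "positive_control"]
  test_bmc <- bmc_tbl |> filter(!.data$substance_id %in% pc_ids)
  pc_bmc <- bmc_tbl |> filter(.data$substance_id %in% pc_ids)
  list(
    vc_flags = check_vc(wells, manifest, recordings, vc_threshold),
    pc = if (nrow(pc_bmc)) pc_reproducibility(pc_bmc) else NULL,
    duplicates = duplicate_concordance(test_bmc, manifest, dup_threshold),
    endpoint_variability = endpoint_variability(test_bmc)
  )
}
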