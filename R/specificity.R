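#' Specificity scores of altered-phenotype endpoints against mortality
#'
#' For every substance x replicate, the specificity score of a 120-hpf
#' non-mortality endpoint is the log10 difference between the mortality BMC
#' and the endpoint BMC: positive scores mean the phenotype appears below
#' lethal concentrations. When mortality is inactive its censored
#' highest-tested-concentration value is used, so a phenotype active under
#' an inactive mortality curve earns a large positive score. When the
#' phenotype endpoint itself is inactive there is no score and the
#' replicate is a non-toxic candidate.
#'
#' @param bmc_tbl BMC results from [fit_bmc()] covering `Mortality@120` and
#'   the non-mortality 120-hpf endpoints.
#' @return Tibble: `substance_id`, `endpoint`, `replicate_key`, `score`,
#'   `endpoint_active`, `both_active`, `bmc_endpoint`, `bmc_mortality`.
#' @export
specificity_scores <- function(bmc_tbl) {
  mort <- bmc_tbl |>
    filter(.data$endpoint == "Mortality@120") |>
    select("substance_id", "replicate_key",
           bmc_mortality = "bmc_log10M", mortality_active = "active")
  pheno <- bmc_tbl |>
    filter(.data$endpoint != "Mortality@120", .data$endpoint != "Mortality@24")
  joined <- pheno |>
    inner_join(mort, by = c("substance_id", "replicate_key"))
  if (nrow(joined) == 0L) abort("no matching mortality/phenotype replicate pairs")
  joined |>
    mutate(
      endpoint_active = .data$active,
      score = ifelse(.data$endpoint_active,
                     .data$bmc_mortality - .data$bmc_log10M, NA_real_),
      both_active = .data$endpoint_active & .data$mortality_active
    ) |>
    select("substance_id", "endpoint", "replicate_key", "score",
           "endpoint_active", "both_active",
           bmc_endpoint = "bmc_log10M", "bmc_mortality")
}

#' Noise cutoff from the negative tail of the score distribution
#'
#' In theory specificity scores are non-negative; observed negative scores
#' are treated as draws from the noise of the BMC calculation. The cutoff
#' mirrors that noise tail to the positive side: it is minus the 5th
#' percentile of the scores below zero (linear-interpolation quantile,
#' `h = (n - 1) p`), returned as a positive number.
#'
#' @param scores Numeric vector of specificity scores (NAs ignored).
#' @param p Tail probability (default 0.05).
#' @return Positive cutoff in log10 units; 0 with a warning when no
#'   negative scores exist.
#' @examples
#' derive_cutoff(c(-0.40, -0.20, -0.10, -0.05, 0.3, 1.2)) # 0.37
#' @export
derive_cutoff <- function(scores, p = 0.05) {
  negs <- scores[!is.na(scores) & scores < 0]
  if (length(negs) == 0L) {
    warn("no negative specificity scores; cutoff set to 0")
    return(0)
  }
  unname(-quantile(negs, p, type = 7))
}

#' Classify one replicate's specificity
#'
#' `specific` when the score strictly exceeds the cutoff, `non-specific`
#' when the score is at or below it, `non-toxic` when the phenotype
#' endpoint is inactive. Vectorized.
#'
#' @param score Specificity score(s); NA for inactive endpoints.
#' @param endpoint_active Logical, phenotype endpoint activity.
#' @param cutoff Non-negative cutoff from [derive_cutoff()].
#' @return Character vector of classes.
#' @export
classify_plate <- function(score, endpoint_active, cutoff) {
  stopifnot(cutoff >= 0)
  dplyr::case_when(
    !endpoint_active ~ "non-toxic",
    score > cutoff ~ "specific",
    TRUE ~ "non-specific"
  )
}

#' Aggregate replicate classes to a substance-level call
#'
#' The majority class (strictly more than half the replicates, usually 2 of
#' 3 plates) is reported with the mean BMC and mean score of that class's
#' replicates. With no majority the call is `inconclusive` and the BMC and
#' score of the `specific` replicates are reported (NA when none were
#' specific).
#'
#' @param cls Character vector of per-replicate classes.
#' @param bmc Per-replicate phenotype BMC values (log10 M).
#' @param score Per-replicate specificity scores.
#' @return One-row tibble: `cls`, `bmc_summary`, `score_summary`,
#'   `n_plates`.
#' @export
aggregate_substance <- function(cls, bmc = rep(NA_real_, length(cls)),
                                score = rep(NA_real_, length(cls))) {
  stopifnot(length(cls) >= 1L, length(bmc) == length(cls),
            length(score) == length(cls))
  tab <- sort(table(cls), decreasing = TRUE)
  if (tab[1] > length(cls) / 2) {
    winner <- names(tab)[1]
  } else {
    winner <- "inconclusive"
  }
  summarise_from <- if (winner == "inconclusive") "specific" else winner
  sel <- cls == summarise_from
  n_plates <- length(cls)
  tibble(
    cls = winner,
    bmc_summary = if (any(sel) && any(!is.na(bmc[sel]))) mean(bmc[sel], na.rm = TRUE) else NA_real_,
    score_summary = if (any(sel) && any(!is.na(score[sel]))) mean(score[sel], na.rm = TRUE) else NA_real_,
    n_plates = n_plates
  )
}

#' Full specificity analysis of a dataset's BMC table
#'
#' Scores every non-mortality 120-hpf endpoint against mortality per
#' replicate, derives the dataset noise cutoff, classifies replicates and
#' aggregates to substance-level calls.
#'
#' @inheritParams specificity_scores
#' @param p Tail probability for the cutoff (default 0.05).
#' @param exclude Endpoints to leave out of scoring (default the
#'   any-malformation aggregate is kept; pass e.g. `"MalformedAny+Mort@120"`
#'   to restrict to single-phenotype endpoints).
#' @return List: `scores`, `cutoff`, `plate_calls` (per replicate),
#'   `substance_calls` (per substance x endpoint).
#' @export
specificity_analysis <- function(bmc_tbl, p = 0.05, exclude = character()) {
  scores <- specificity_scores(bmc_tbl) |>
    filter(!.data$endpoint %in% exclude)
  cutoff <- derive_cutoff(scores$score, p)
  plate_calls <- scores |>
    mutate(cls = classify_plate(.data$score, .data$endpoint_active, cutoff))
  substance_calls <- plate_calls |>
    group_by(.data$substance_id, .data$endpoint) |>
    group_modify(~ aggregate_substance(.x$cls, .x$bmc_endpoint, .x$score)) |>
    ungroup()
  list(scores = scores, cutoff = cutoff,
       plate_calls = plate_calls, substance_calls = substance_calls)
}
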