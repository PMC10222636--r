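#' Weighted isotonic (non-decreasing) least-squares fit
#'
#' Pool-adjacent-violators algorithm minimising sum(w * (y - yhat)^2) subject
#' to yhat non-decreasing. Used as the noise-correction stage before BMC
#' interpolation: screening responses are expected to rise monotonically with
#' concentration, and the isotonic projection removes downward noise
#' excursions while leaving monotone data untouched.
#'
#' @param y Numeric response vector (ordered by ascending concentration).
#' @param w Positive weights, typically embryo counts per concentration.
#' @return Fitted non-decreasing vector of the same length.
#' @export
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  stopifnot(length(w) == n, all(w > 0))
  if (n == 0L) return(numeric())
  # block merge with running weighted means
  val <- numeric(n); wt <- numeric(n); len <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    val[k] <- y[i]; wt[k] <- w[i]; len[k] <- 1L
    while (k > 1L && val[k - 1L] > val[k]) {
      tw <- wt[k - 1L] + wt[k]
      val[k - 1L] <- (wt[k - 1L] * val[k - 1L] + wt[k] * val[k]) / tw
      wt[k - 1L] <- tw
      len[k - 1L] <- len[k - 1L] + len[k]
      k <- k - 1L
    }
  }
  rep(val[seq_len(k)], times = len[seq_len(k)])
}

#' Noise-correct a concentration-response curve
#'
#' Applies the weighted isotonic projection ([pava()]) to the response
#' vector of a concentration-response record and clips the result to
#' [0, 100] percent.
#'
#' @param cr Tibble with `conc_log10M`, `response`, `n` (ascending
#'   concentration, at least two concentrations).
#' @return `cr` with a `response_corrected` column added; the maximum
#'   corrected response is in attribute `max_response`.
#' @export
monotonize <- function(cr) {
  if (nrow(cr) < 2L) abort("monotonize needs at least 2 concentrations")
  if (is.unsorted(cr$conc_log10M, strictly = TRUE)) {
    abort("concentrations must be strictly increasing")
  }
  corrected <- pmin(100, pmax(0, pava(cr$response, cr$n)))
  out <- cr |> mutate(response_corrected = corrected)
  attr(out, "max_response") <- max(corrected)
  out
}

#' Benchmark concentration at a given benchmark response
#'
#' The curve is active when its maximum corrected response reaches the BMR;
#' the BMC is then the log10-molar concentration at which the corrected
#' curve first attains the BMR, linearly interpolated between the bracketing
#' tested concentrations. Boundary conventions: if the lowest tested
#' concentration already responds at or above the BMR, the BMC is that
#' lowest concentration and `censored_low` is set; if the curve never
#' reaches the BMR the result is inactive and the highest tested
#' concentration is substituted (`censored_at_max`), so downstream variance
#' summaries have a defined value for inactive replicates. On a flat
#' corrected segment lying exactly at the BMR the lowest concentration of
#' the segment is reported.
#'
#' @param curve Output of [monotonize()] (needs `conc_log10M`,
#'   `response_corrected`).
#' @param bmr Benchmark response in percent, 0 < bmr < 100.
#' @return One-row tibble: `bmr_used`, `active`, `bmc_log10M`,
#'   `censored_at_max`, `censored_low`, `max_response`.
#' @examples
#' cr <- tibble::tibble(conc_log10M = -6:-3, response = c(0, 0, 20, 40),
#'                      n = rep(11, 4))
#' bmc_at(monotonize(cr), 30)$bmc_log10M # -3.5
#' @export
bmc_at <- function(curve, bmr) {
  stopifnot(bmr > 0, bmr < 100)
  conc <- curve$conc_log10M
  y <- curve$response_corrected
  max_resp <- max(y)
  if (max_resp < bmr) {
    return(tibble(
      bmr_used = bmr, active = FALSE, bmc_log10M = conc[length(conc)],
      censored_at_max = TRUE, censored_low = FALSE, max_response = max_resp
    ))
  }
  if (y[1] >= bmr) {
    return(tibble(
      bmr_used = bmr, active = TRUE, bmc_log10M = conc[1],
      censored_at_max = FALSE, censored_low = TRUE, max_response = max_resp
    ))
  }
  tibble(
    bmr_used = bmr, active = TRUE, bmc_log10M = bmc_value(conc, y, bmr),
    censored_at_max = FALSE, censored_low = FALSE, max_response = max_resp
  )
}

# numeric core shared with the threshold scan: first crossing of bmr on a
# non-decreasing curve, censored conventions as in bmc_at
bmc_value <- function(conc, y, bmr) {
  if (y[length(y)] < bmr) return(conc[length(conc)])  # max(y) = last for isotone y
  if (y[1] >= bmr) return(conc[1])
  i <- which(y >= bmr)[1]
  if (y[i] == bmr) return(conc[i])
  conc[i - 1] + (bmr - y[i - 1]) * (conc[i] - conc[i - 1]) / (y[i] - y[i - 1])
}

#' Pooled variance of potency across substances
#'
#' Combines the replicate-to-replicate BMC variance of every substance with
#' at least two replicates: `sum((n_s - 1) * var_s) / sum(n_s - 1)`.
#' Inactive replicates enter with their censored highest-tested-
#' concentration value, so an all-inactive substance contributes zero
#' variance rather than being dropped.
#'
#' @param bmc_tbl Tibble with `substance_id` and `bmc_log10M` (one row per
#'   replicate).
#' @return Pooled variance in squared log10 units.
#' @export
pooled_variance <- function(bmc_tbl) {
  per <- bmc_tbl |>
    group_by(.data$substance_id) |>
    summarise(n = n(), v = var(.data$bmc_log10M), .groups = "drop") |>
    filter(.data$n >= 2L)
  if (nrow(per) == 0L) abort("no substance with >= 2 replicates")
  sum((per$n - 1) * per$v) / sum(per$n - 1)
}

#' Pooled-variance profile over a grid of candidate thresholds
#'
#' For each candidate threshold, every curve in the dataset is evaluated
#' with [bmc_at()] and the potency variance pooled over substances. Low
#' thresholds sit inside the assay noise and produce erratic potencies;
#' as the threshold climbs above the noise floor the pooled variance drops
#' and flattens — the stabilization exploited by [select_bmr()].
#'
#' @param curves List of [monotonize()] outputs, one per substance x
#'   replicate, with names or a parallel `keys` tibble giving
#'   `substance_id`.
#' @param keys Tibble aligned with `curves`: `substance_id` (and anything
#'   else, carried through).
#' @param grid Ascending candidate thresholds in percent, inside (0, 100).
#' @return Tibble `threshold`, `pooled_variance`.
#' @export
scan_thresholds <- function(curves, keys, grid) {
  stopifnot(length(curves) == nrow(keys), !is.unsorted(grid),
            all(grid > 0), all(grid < 100))
  concs <- lapply(curves, function(cv) cv$conc_log10M)
  ys <- lapply(curves, function(cv) cv$response_corrected)
  profile <- vapply(grid, function(t) {
    bmc <- vapply(seq_along(curves),
                  function(j) bmc_value(concs[[j]], ys[[j]], t), numeric(1))
    pooled_variance(tibble(substance_id = keys$substance_id, bmc_log10M = bmc))
  }, numeric(1))
  tibble(threshold = grid, pooled_variance = profile)
}

#' Select the benchmark response from a variance profile
#'
#' Interprets the BMR as the lowest threshold at which potency estimation
#' has stabilized. An exponential decay `v(t) = a * exp(-k * t) + c` is
#' fitted to the pooled-variance profile and the BMR is the smallest grid
#' threshold where the fitted decay term has fallen to `tol` of its
#' amplitude (`a * exp(-k * t) <= tol * a`).
#'
#' Numerical safeguards: the fit uses only the profile up to its minimum,
#' because beyond it the pooled variance is re-inflated by inactive
#' replicates censoring at the top tested concentration (an artifact, not
#' stabilization); the fitted asymptote is constrained near the smallest
#' observed pooled variance so the optimizer cannot trade the plateau for
#' an unobservably low, slow decay. A flat profile is already stable and
#' returns the lowest threshold; a decay spanning fewer than four grid
#' points takes the profile minimum; a profile rising from the first
#' threshold (or one that defeats the fit) returns the highest threshold
#' with `converged = FALSE` and a warning.
#'
#' @param profile Tibble from [scan_thresholds()].
#' @param tol Stabilization tolerance as a fraction of the fitted amplitude
#'   (default 0.05).
#' @return One-row tibble: `bmr`, `plateau` (fitted asymptote `c`),
#'   `converged`, plus the profile in a list column.
#' @export
select_bmr <- function(profile, tol = 0.05) {
  grid <- profile$threshold
  v <- profile$pooled_variance
  res <- function(bmr, plateau, converged) {
    tibble(bmr = bmr, plateau = plateau, converged = converged,
           profile = list(profile))
  }
  if (length(grid) == 0L) abort("empty threshold profile")
  rng <- diff(range(v))
  if (rng <= 1e-12) {           # flat: stabilized from the start
    return(res(grid[1], v[1], TRUE))
  }
  # fit the decay only up to the profile minimum: beyond it the pooled
  # variance is re-inflated by replicates censoring at the top tested
  # concentration, which is a censoring artifact, not noise stabilization
  i_min <- max(which(v <= min(v) + 1e-12))
  if (i_min == 1L) {            # rising from the first threshold: no decay
    warn("variance profile does not decay; BMR set to highest threshold")
    return(res(grid[length(grid)], NA_real_, FALSE))
  }
  if (i_min < 4L) {
    # decay over too few grid points to support the 3-parameter fit:
    # take the profile minimum as the stabilization threshold
    return(res(grid[i_min], v[i_min], TRUE))
  }
  vd <- v[seq_len(i_min)]
  td <- grid[seq_len(i_min)]
  c0 <- min(vd)
  a0 <- max(vd) - c0
  # crude decay-rate start from the upper half of the amplitude
  above <- which(vd - c0 > a0 / 2)
  k0 <- if (length(above)) log(2) / max(diff(range(td[above])), diff(td[1:2])) else 0.1
  # the asymptote is the noise floor: it cannot sit far below the smallest
  # observed pooled variance, which keeps the fit out of a degenerate
  # shallow-decay optimum with an unobservably low plateau
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ a * exp(-k * t) + c,
      data = list(v = vd, t = td),
      start = list(a = a0, k = k0, c = c0),
      lower = c(a = 0, k = 1e-6, c = 0.5 * c0),
      upper = c(a = Inf, k = Inf, c = c0 + 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warn("exponential fit to the variance profile failed; BMR set to highest threshold")
    return(res(grid[length(grid)], NA_real_, FALSE))
  }
  cf <- coef(fit)
  if (cf[["a"]] <= 0 || cf[["k"]] <= 1e-6) {
    warn("variance profile shows no decay amplitude; BMR set to highest threshold")
    return(res(grid[length(grid)], NA_real_, FALSE))
  }
  t_star <- log(1 / tol) / cf[["k"]]
  ok <- grid[grid >= t_star]
  if (length(ok) == 0L) {
    warn("variance profile never stabilizes within the grid; BMR set to highest threshold")
    return(res(grid[length(grid)], unname(cf[["c"]]), FALSE))
  }
  res(ok[1], unname(cf[["c"]]), TRUE)
}

anchor_responses <- function(endpoint_data, anchor = TRUE) {
  if (!anchor) {
    return(endpoint_data |> mutate(response_anchored = .data$response))
  }
  endpoint_data |>
    mutate(response_anchored = pmax(0, .data$response - .data$vc_response))
}

# split one endpoint's rows into monotonized curves + key table;
# curves with < 2 concentrations are skipped
endpoint_curves <- function(df) {
  keyed <- df |>
    group_by(.data$substance_id, .data$replicate_key) |>
    group_split()
  curves <- list(); keys <- list()
  for (g in keyed) {
    if (nrow(g) < 2L) next
    cr <- tibble(conc_log10M = g$conc_log10M,
                 response = g$response_anchored, n = g$n)
    curves[[length(curves) + 1L]] <- monotonize(cr)
    keys[[length(keys) + 1L]] <- tibble(substance_id = g$substance_id[1],
                                        replicate_key = g$replicate_key[1])
  }
  list(curves = curves, keys = bind_rows(keys))
}

#' Dataset-adaptive BMR for every endpoint
#'
#' Runs the threshold scan and stabilization fit per endpoint: responses
#' are (optionally) baseline-anchored by subtracting the same-replicate
#' vehicle-control response (floored at zero), each substance x replicate
#' curve is noise-corrected once, and the pooled-variance profile over the
#' grid is handed to [select_bmr()].
#'
#' @param endpoint_data Output of [build_endpoint_data()].
#' @param grid Candidate thresholds in percent (default 5 to 95 by 5).
#' @param tol Stabilization tolerance, see [select_bmr()].
#' @param anchor Subtract the vehicle-control baseline before analysis.
#' @return Tibble: one row per endpoint with `bmr`, `plateau`, `converged`
#'   and the variance profile as a list column.
#' @export
estimate_dataset_bmr <- function(endpoint_data, grid = seq(5, 95, by = 5),
                                 tol = 0.05, anchor = TRUE) {
  endpoint_data <- anchor_responses(endpoint_data, anchor)
  endpoint_data |>
    group_by(.data$endpoint) |>
    group_modify(function(df, key) {
      ec <- endpoint_curves(df)
      if (length(ec$curves) == 0L) {
        return(tibble(bmr = NA_real_, plateau = NA_real_, converged = FALSE,
                      profile = list(NULL)))
      }
      profile <- scan_thresholds(ec$curves, ec$keys, grid)
      select_bmr(profile, tol)
    }) |>
    ungroup()
}

#' Fit benchmark concentrations for every curve at the selected BMRs
#'
#' @param endpoint_data Output of [build_endpoint_data()].
#' @param bmr_table Tibble `endpoint`, `bmr` (from [estimate_dataset_bmr()]
#'   or supplied directly).
#' @param anchor Subtract the vehicle-control baseline before analysis
#'   (must match the BMR estimation setting).
#' @return Tibble of BMC results: `endpoint`, `kind`, `recording`,
#'   `substance_id`, `replicate_key`, `bmr_used`, `active`, `bmc_log10M`,
#'   `censored_at_max`, `censored_low`, `max_response`.
#' @export
fit_bmc <- function(endpoint_data, bmr_table, anchor = TRUE) {
  endpoint_data <- anchor_responses(endpoint_data, anchor)
  endpoint_data |>
    inner_join(bmr_table |> select("endpoint", "bmr"), by = "endpoint") |>
    group_by(.data$endpoint, .data$kind, .data$recording,
             .data$substance_id, .data$replicate_key, .data$bmr) |>
    group_modify(function(df, key) {
      if (nrow(df) < 2L || is.na(key$bmr)) {
        return(tibble(bmr_used = key$bmr, active = NA, bmc_log10M = NA_real_,
                      censored_at_max = NA, censored_low = NA,
                      max_response = NA_real_))
      }
      cr <- tibble(conc_log10M = df$conc_log10M,
                   response = df$response_anchored, n = df$n)
      bmc_at(monotonize(cr), key$bmr)
    }) |>
    ungroup() |>
    select(-"bmr") |>
    filter(!is.na(.data$active))
}
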