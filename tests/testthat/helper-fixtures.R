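# shared fixtures, built in code and cached for the session

.fixture_env <- new.env(parent = emptyenv())

# one-lab study, small enough for fast unit tests
small_study <- function(seed = 42) {
  key <- paste0("small_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_study(
      sim_config(n_screening = 6, n_duplicate_pairs = 1,
                 labs = sim_lab_profiles()["Lab_A"]),
      seed = seed
    )
  }
  .fixture_env[[key]]
}

small_endpoint_data <- function(seed = 42) {
  key <- paste0("ed_", seed)
  if (is.null(.fixture_env[[key]])) {
    s <- small_study(seed)
    .fixture_env[[key]] <- build_endpoint_data(s$wells, s$manifest, s$recordings)
  }
  .fixture_env[[key]]
}

# hand-built plate: one substance, 2 concentrations, plus VC wells
toy_wells <- function() {
  bind2 <- function(...) dplyr::bind_rows(...)
  test <- tibble::tibble(
    plate_id = "P1", run_date = as.Date("2021-03-01"),
    well = sprintf("A%02d", 1:22), substance_id = "SUB",
    conc_uM = rep(c(1, 10), each = 11),
    alive_24 = TRUE, alive_120 = TRUE,
    Edema = FALSE, Trait_q = FALSE
  )
  vc <- tibble::tibble(
    plate_id = "P1", run_date = as.Date("2021-03-01"),
    well = sprintf("B%02d", 1:12), substance_id = "VC",
    conc_uM = 0, alive_24 = TRUE, alive_120 = TRUE,
    Edema = FALSE, Trait_q = FALSE
  )
  bind2(test, vc)
}

toy_recordings <- function() {
  tibble::tibble(
    lab_id = "LabX",
    recording_name = c("Edema", "Trait_q"),
    is_binarized_quantitative = c(FALSE, TRUE)
  )
}

# brute-force weighted least-squares isotonic oracle: enumerate every
# partition of 1..n into contiguous blocks, fit block weighted means, keep
# feasible (non-decreasing) candidates, return the minimum weighted SSE fit
isotonic_oracle <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 1L) return(y)
  best <- NULL
  best_sse <- Inf
  # cut points encoded by bits of 0:(2^(n-1) - 1)
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, n)
    fit <- numeric(n)
    means <- numeric(length(starts))
    for (b in seq_along(starts)) {
      idx <- starts[b]:ends[b]
      means[b] <- sum(w[idx] * y[idx]) / sum(w[idx])
      fit[idx] <- means[b]
    }
    if (is.unsorted(means)) next
    sse <- sum(w * (y - fit)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- fit
    }
  }
  best
}
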