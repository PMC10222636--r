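#' Hill-shaped event probability
#'
#' Standard sigmoidal concentration-effect model used by the synthetic
#' plate generator: `p = p0 + (pmax - p0) * conc^s / (ac50^s + conc^s)`.
#'
#' @param conc_uM Concentration(s), uM, >= 0 (0 returns the baseline `p0`).
#' @param ac50_uM Concentration of half-maximal effect, > 0.
#' @param slope Hill slope, > 0.
#' @param p0 Baseline probability (untreated), in [0, 1).
#' @param pmax Asymptotic probability, in (p0, 1].
#' @return Event probability in [0, 1].
#' @export
hill_prob <- function(conc_uM, ac50_uM, slope, p0 = 0, pmax = 1) {
  stopifnot(all(conc_uM >= 0), ac50_uM > 0, slope > 0,
            p0 >= 0, p0 <= pmax, pmax <= 1)
  frac <- conc_uM^slope / (ac50_uM^slope + conc_uM^slope)
  p0 + (pmax - p0) * frac
}

# deterministic 31-bit hash of a string, for per-plate sub-seeds
string_hash <- function(key) {
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  h
}

derive_seed <- function(seed, key) {
  as.integer((seed + string_hash(key)) %% 2147483647)
}

log_spaced_concs <- function(max_uM, spacing_log10, n) {
  10^(log10(max_uM) - spacing_log10 * ((n - 1):0))
}

#' Default laboratory profiles for the synthetic study
#'
#' Three emulated laboratories: two wide-spacing designs (7 concentrations
#' x 11 embryos, 0.5 log10 spacing) and one narrow-spacing design (11
#' concentrations x 7 embryos, 0.2 log10 spacing), each with 12 VC wells
#' and a 7-well PC series per plate. The third lab records part of its
#' phenotypes as binarized quantitative image traits and carries an
#' elevated baseline malformation rate, mimicking automated image-derived
#' readouts.
#'
#' @return Named list of per-lab profiles (design, concentration grid,
#'   recording counts, baseline rates).
#' @export
sim_lab_profiles <- function() {
  list(
    Lab_A = list(
      design = plate_design(7, 11, dosing_scenario = "SR", chorion_status = "C"),
      spacing_log10 = 0.5, n_binary = 21L, n_quant = 0L,
      vc_mort120 = 0.02, frac_dead_by_24 = 0.5, vc_malf_total = 0.08
    ),
    Lab_B = list(
      design = plate_design(11, 7, dosing_scenario = "S", chorion_status = "DC"),
      spacing_log10 = 0.2, n_binary = 9L, n_quant = 0L,
      vc_mort120 = 0.02, frac_dead_by_24 = 0.5, vc_malf_total = 0.08
    ),
    Lab_C = list(
      design = plate_design(7, 11, dosing_scenario = "S", chorion_status = "C"),
      spacing_log10 = 0.5, n_binary = 12L, n_quant = 9L,
      vc_mort120 = 0.02, frac_dead_by_24 = 0.5, vc_malf_total = 0.15
    )
  )
}

#' Configuration of the synthetic interlaboratory study
#'
#' Defaults mirror the emulated study conditions: 35 screening substances
#' plus 3 blinded duplicate pairs (41 blinded codes, 38 unique compounds)
#' plus one positive control; triplicate plates per substance per lab run
#' in three consecutive weeks; maximum test concentration 100 uM.
#'
#' @param n_screening Substances without a duplicate partner.
#' @param n_duplicate_pairs Blinded duplicate pairs (same compound, two
#'   codes).
#' @param labs Laboratory profiles, see [sim_lab_profiles()].
#' @param n_replicates Plates per substance per lab (separate dates).
#' @param max_conc_uM Top test concentration.
#' @param pc_ac50_uM,pc_slope Positive-control mortality curve parameters.
#' @param frac_toxic Fraction of compounds lethal within the tested range.
#' @param frac_specific Among toxic compounds, fraction whose phenotype
#'   potency clearly precedes lethality (~10x lower AC50); the rest track
#'   mortality.
#' @param n_affected_recordings Phenotype recordings responding per
#'   substance and lab.
#' @param start_date First run date (replicates advance by one week).
#' @return `sim_config` list.
#' @export
sim_config <- function(n_screening = 35L, n_duplicate_pairs = 3L,
                       labs = sim_lab_profiles(), n_replicates = 3L,
                       max_conc_uM = 100, pc_ac50_uM = 4, pc_slope = 3,
                       frac_toxic = 0.85, frac_specific = 0.6,
                       n_affected_recordings = 3L,
                       start_date = as.Date("2021-03-01")) {
  structure(
    list(
      n_screening = as.integer(n_screening),
      n_duplicate_pairs = as.integer(n_duplicate_pairs),
      labs = labs, n_replicates = as.integer(n_replicates),
      max_conc_uM = max_conc_uM, pc_ac50_uM = pc_ac50_uM, pc_slope = pc_slope,
      frac_toxic = frac_toxic, frac_specific = frac_specific,
      n_affected_recordings = as.integer(n_affected_recordings),
      start_date = as.Date(start_date)
    ),
    class = "sim_config"
  )
}

sim_recordings <- function(labs) {
  bind_rows(lapply(names(labs), function(lab) {
    p <- labs[[lab]]
    bind_rows(
      if (p$n_binary > 0) tibble(
        lab_id = lab,
        recording_name = sprintf("%s_Pheno_%02d", lab, seq_len(p$n_binary)),
        is_binarized_quantitative = FALSE
      ),
      if (p$n_quant > 0) tibble(
        lab_id = lab,
        recording_name = sprintf("%s_Trait_%02d", lab, seq_len(p$n_quant)),
        is_binarized_quantitative = TRUE
      )
    )
  }))
}

# ground-truth table; draws from the current RNG stream
simulate_truth <- function(config) {
  n_unique <- config$n_screening + config$n_duplicate_pairs
  toxic <- runif(n_unique) < config$frac_toxic
  # lethal potencies drawn well inside the tested window (0.1-100 uM) so
  # that a 10x-lower phenotype AC50 also stays above the range floor, as a
  # dose range-finding design intends; inactives sit far above the top
  log_ac50 <- ifelse(toxic, runif(n_unique, 0.5, 1.7), 5)  # 1e5 uM = inactive
  specific <- toxic & (runif(n_unique) < config$frac_specific)
  ratio <- ifelse(specific, 10^runif(n_unique, 0.9, 1.1),
                  10^runif(n_unique, -0.05, 0.05))
  compounds <- tibble(
    compound_id = sprintf("C%02d", seq_len(n_unique)),
    mort_ac50_uM = 10^log_ac50,
    mort_slope = runif(n_unique, 2, 4),
    mort_pmax = runif(n_unique, 0.9, 1),
    pheno_ratio = ratio,
    pheno_ac50_uM = 10^log_ac50 / ratio,
    pheno_slope = runif(n_unique, 2, 4),
    pheno_pmax = runif(n_unique, 0.85, 1),
    toxic = toxic, specific = specific
  )
  # duplicate pairs: the last n_duplicate_pairs compounds appear twice
  dup_ids <- tail(compounds$compound_id, config$n_duplicate_pairs)
  blinded <- bind_rows(
    compounds,
    compounds |> filter(.data$compound_id %in% dup_ids)
  ) |>
    arrange(.data$compound_id) |>
    mutate(
      substance_id = sprintf("S%02d", row_number()),
      duplicate_group = ifelse(.data$compound_id %in% dup_ids,
                               paste0("dup_", .data$compound_id), NA_character_)
    )
  blinded |>
    select("substance_id", "compound_id", "duplicate_group", everything())
}

# which of a lab's binary recordings respond to a given substance:
# a deterministic rotation through the recording list by truth-table index
affected_recordings <- function(truth_index, profile, lab_recs, n_affected) {
  idx <- ((truth_index + seq_len(n_affected) - 2L) %% profile$n_binary) + 1L
  lab_recs$recording_name[!lab_recs$is_binarized_quantitative][idx]
}

# one plate: test substance dilution series + 12 VC wells + 7-well PC series
simulate_plate <- function(lab, profile, truth_row, config, recordings,
                           plate_id, run_date, seed) {
  set.seed(derive_seed(seed, plate_id))
  design <- profile$design
  concs <- log_spaced_concs(config$max_conc_uM, profile$spacing_log10,
                            design$n_test_concentrations)
  pc_concs <- log_spaced_concs(config$max_conc_uM, 0.5, design$n_pc_wells)

  test <- tibble(
    substance_id = truth_row$substance_id,
    conc_uM = rep(concs, each = design$n_embryos_per_concentration)
  )
  vc <- tibble(substance_id = "VC", conc_uM = 0)[rep(1, design$n_vc_wells), ]
  pc <- tibble(substance_id = "PC", conc_uM = pc_concs)
  wells <- bind_rows(test, vc, pc)

  # mortality: overall death probability by 120 hpf from the Hill truth;
  # conditional on death, a fixed fraction occurs by 24 hpf
  p120 <- numeric(nrow(wells))
  is_test <- wells$substance_id == truth_row$substance_id
  is_pc <- wells$substance_id == "PC"
  p120[is_test] <- hill_prob(wells$conc_uM[is_test], truth_row$mort_ac50_uM,
                             truth_row$mort_slope, profile$vc_mort120,
                             truth_row$mort_pmax)
  p120[is_pc] <- hill_prob(wells$conc_uM[is_pc], config$pc_ac50_uM,
                           config$pc_slope, profile$vc_mort120, 0.95)
  p120[!is_test & !is_pc] <- profile$vc_mort120

  dead120 <- rbinom(nrow(wells), 1L, p120) == 1L
  dead24 <- dead120 & (rbinom(nrow(wells), 1L, profile$frac_dead_by_24) == 1L)
  wells$alive_24 <- !dead24
  wells$alive_120 <- !dead120

  # phenotypes in survivors only; a few recordings respond to the substance,
  # the rest (and all wells of VC) show only the lab's baseline rate
  lab_recs <- recordings |> filter(.data$lab_id == lab)
  n_rec <- nrow(lab_recs)
  q_base <- 1 - (1 - profile$vc_malf_total)^(1 / max(1L, profile$n_binary))
  affected <- affected_recordings(truth_row$truth_index, profile, lab_recs,
                                  config$n_affected_recordings)

  alive <- wells$alive_120
  for (j in seq_len(n_rec)) {
    rec <- lab_recs$recording_name[j]
    p <- rep(q_base, nrow(wells))
    if (rec %in% affected) {
      p[is_test] <- hill_prob(wells$conc_uM[is_test], truth_row$pheno_ac50_uM,
                              truth_row$pheno_slope, q_base, truth_row$pheno_pmax)
      p[is_pc] <- hill_prob(wells$conc_uM[is_pc], config$pc_ac50_uM / 3,
                            config$pc_slope, q_base, 0.9)
    }
    flag <- rep(NA, nrow(wells))
    flag[alive] <- rbinom(sum(alive), 1L, p[alive]) == 1L
    wells[[rec]] <- flag
  }

  rows <- nrow(wells)
  wells |>
    mutate(
      plate_id = plate_id, run_date = run_date,
      well = sprintf("%s%02d", rep(LETTERS[1:8], each = 12)[seq_len(rows)],
                     rep(1:12, times = 8)[seq_len(rows)]),
      lab_id = lab
    ) |>
    select("lab_id", "plate_id", "run_date", "well", "substance_id",
           "conc_uM", "alive_24", "alive_120", everything())
}

#' Simulate a complete blinded interlaboratory study
#'
#' Generates the full well-level dataset for every lab profile: triplicate
#' plates per blinded substance on dates one week apart (so the weekly PC
#' pools contain all of a week's plates), duplicate pairs sharing identical
#' ground-truth curves under different blinded codes, lab-specific baseline
#' malformation rates, and phenotype flags drawn only for embryos surviving
#' to 120 hpf. Reproducible: the global seed plus a per-plate sub-seed
#' derived from a hash of the plate id makes every plate independently
#' regenerable and the whole study byte-identical across runs.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed driving all randomness.
#' @return List: `wells` (all labs, one column per recording, NA where a
#'   lab lacks a recording), `manifest`, `recordings`, `truth` (ground
#'   truth per blinded code, for recovery tests), `affected` (which
#'   recordings respond to each substance, per lab), `config`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  truth <- simulate_truth(config) |> mutate(truth_index = row_number())
  recordings <- sim_recordings(config$labs)

  manifest <- bind_rows(
    tibble(substance_id = "VC", dtxsid = NA_character_, role = "vehicle_control",
           duplicate_group = NA_character_),
    tibble(substance_id = "PC", dtxsid = "DTXSID0020440", role = "positive_control",
           duplicate_group = NA_character_),
    tibble(substance_id = truth$substance_id,
           dtxsid = sprintf("DTXSIDSYN%04d", seq_len(nrow(truth))),
           role = "test", duplicate_group = truth$duplicate_group)
  )

  plates <- list()
  lab_names <- names(config$labs)
  for (li in seq_along(lab_names)) {
    lab <- lab_names[li]
    profile <- config$labs[[lab]]
    for (rep_i in seq_len(config$n_replicates)) {
      run_date <- config$start_date + (rep_i - 1L) * 7L + (li - 1L)
      for (si in seq_len(nrow(truth))) {
        plate_id <- sprintf("%s_%s_R%d", lab, truth$substance_id[si], rep_i)
        plates[[length(plates) + 1L]] <- simulate_plate(
          lab, profile, truth[si, ], config, recordings,
          plate_id, run_date, seed
        )
      }
    }
  }
  affected <- bind_rows(lapply(lab_names, function(lab) {
    lab_recs <- recordings |> filter(.data$lab_id == lab)
    bind_rows(lapply(seq_len(nrow(truth)), function(si) {
      tibble(
        lab_id = lab, substance_id = truth$substance_id[si],
        recording = affected_recordings(truth$truth_index[si],
                                        config$labs[[lab]], lab_recs,
                                        config$n_affected_recordings)
      )
    }))
  }))

  list(
    wells = bind_rows(plates),
    manifest = manifest,
    recordings = recordings,
    truth = truth |> select(-"truth_index"),
    affected = affected,
    config = config
  )
}

#' Synthetic ontology map for simulated recordings
#'
#' Deterministically assigns every simulated recording one ontology term
#' and rolls terms up into granular and general defect groups, so the
#' ontology-collapse stage runs on simulated studies. Recordings sharing a
#' position index across labs map to the same term, giving the cross-lab
#' overlap structure the harmonization operations expect.
#'
#' @param recordings Recording table from [simulate_study()].
#' @param n_granular,n_general Number of defect groups at each level.
#' @return Mapping tibble in the [read_ontology_map()] layout.
#' @export
sim_ontology_map <- function(recordings, n_granular = 6L, n_general = 3L) {
  idx <- as.integer(sub(".*_(\\d+)$", "\\1", recordings$recording_name))
  gran <- (idx - 1L) %% n_granular + 1L
  gen <- (gran - 1L) %% n_general + 1L
  tibble(
    lab = recordings$lab_id,
    recording = recordings$recording_name,
    ontology_id = sprintf("ZP:SIM%04d", idx),
    term_label = sprintf("simulated phenotype %02d, abnormal", idx),
    granular_group = sprintf("granular defect %d", gran),
    general_group = sprintf("general defect %d", gen)
  )
}
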