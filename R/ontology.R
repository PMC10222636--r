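#' Read a phenotype-ontology mapping table
#'
#' The mapping is a static CSV with one row per recording-to-term edge:
#' `lab,recording,ontology_id,term_label,granular_group,general_group`.
#' A recording may map to several ontology terms (many-to-many); each term
#' belongs to at most one granular developmental-defect group, which nests
#' in at most one general group. Terms that do not involve a structural
#' change carry empty group cells.
#'
#' A small illustrative mapping covering three laboratories ships with the
#' package (`system.file("extdata", "ontology_map_synthetic.csv",
#' package = "zfscreen")`); it is a partial, synthetic stand-in for a full
#' study mapping table and is intended for examples and tests.
#'
#' @param path CSV path.
#' @return Tibble with the columns above (`NA` for empty groups).
#' @export
read_ontology_map <- function(path) {
  map <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("lab", "recording", "ontology_id", "term_label",
                "granular_group", "general_group")
  missing <- setdiff(required, names(map))
  if (length(missing)) {
    abort(paste("mapping file lacks columns:", paste(missing, collapse = ", ")))
  }
  # group nesting must be unique: a granular group sits inside one general group
  nest <- map |>
    filter(!is.na(.data$granular_group)) |>
    distinct(.data$granular_group, .data$general_group)
  dup <- nest |> count(.data$granular_group) |> filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(paste("granular group(s) mapped to multiple general groups:",
                paste(dup$granular_group, collapse = ", ")))
  }
  map
}

#' @rdname read_ontology_map
#' @export
example_ontology_map <- function() {
  read_ontology_map(system.file("extdata", "ontology_map_synthetic.csv",
                                package = "zfscreen", mustWork = TRUE))
}

#' Ontology terms mapped to a recorded phenotype
#'
#' @param recording Recording name as used by the laboratory.
#' @param map Mapping tibble from [read_ontology_map()].
#' @param lab Optional lab id to disambiguate identically named recordings.
#' @return Tibble of the matching term rows, in file order.
#' @export
map_recording <- function(recording, map, lab = NULL) {
  hits <- map |> filter(.data$recording == .env$recording)
  if (!is.null(lab)) hits <- hits |> filter(.data$lab == .env$lab)
  if (nrow(hits) == 0L) {
    abort(sprintf("recording '%s' is not in the ontology map", recording))
  }
  hits
}

#' Mapping granularity statistics for one laboratory
#'
#' The ratio of distinct mapped terms to distinct recordings measures how
#' specific a lab's recording vocabulary is: 1.0 means one term per
#' recording; larger values mean coarser recordings each covering several
#' ontology terms.
#'
#' @param map Mapping tibble.
#' @param lab Lab id.
#' @return Tibble: `lab`, `n_recordings`, `n_terms`, `terms_per_recording`
#'   (rounded to 2 decimals in print; stored unrounded).
#' @export
mapping_stats <- function(map, lab) {
  sub <- map |> filter(.data$lab == .env$lab)
  if (nrow(sub) == 0L) {
    warn(sprintf("no mappings for lab '%s'", lab))
    return(tibble(lab = lab, n_recordings = 0L, n_terms = 0L,
                  terms_per_recording = NA_real_))
  }
  tibble(
    lab = lab,
    n_recordings = n_distinct(sub$recording),
    n_terms = n_distinct(sub$ontology_id),
    terms_per_recording = n_distinct(sub$ontology_id) / n_distinct(sub$recording)
  )
}

#' Cross-laboratory overlap of terms and defect groups
#'
#' For every ontology term (and every granular / general defect group) the
#' set of laboratories with at least one recording mapping to it is
#' computed, along with the count of items shared by all laboratories.
#'
#' @param map Mapping tibble covering two or more labs.
#' @return List of three elements `term`, `granular`, `general`, each a
#'   list with a lab-presence matrix (`presence`, logical tibble with one
#'   column per lab) and `n_fully_shared`.
#' @export
ontology_overlap <- function(map) {
  labs <- sort(unique(map$lab))
  if (length(labs) < 2L) abort("overlap needs mappings from at least 2 labs")
  presence_of <- function(df, item_col) {
    df |>
      filter(!is.na(.data[[item_col]])) |>
      distinct(item = .data[[item_col]], .data$lab) |>
      mutate(present = TRUE) |>
      tidyr::pivot_wider(names_from = "lab", values_from = "present",
                         values_fill = FALSE) |>
      arrange(.data$item)
  }
  one_level <- function(item_col) {
    pres <- presence_of(map, item_col)
    lab_cols <- setdiff(names(pres), "item")
    shared <- if (nrow(pres)) {
      rowSums(as.matrix(pres[, labs[labs %in% lab_cols], drop = FALSE])) == length(labs)
    } else {
      logical()
    }
    list(presence = pres, n_fully_shared = sum(shared))
  }
  list(
    term = one_level("term_label"),
    granular = one_level("granular_group"),
    general = one_level("general_group")
  )
}

.class_precedence <- c("specific", "non-specific", "inconclusive", "non-toxic")

#' Collapse several calls into one defect-group representative
#'
#' When multiple altered-phenotype endpoints feed a defect group, the
#' representative is chosen by class precedence — specific first, then
#' non-specific, inconclusive, non-toxic — and ties within the winning
#' class are resolved by the most potent (numerically smallest log10
#' molar) BMC. Collapsing is idempotent.
#'
#' @param calls Tibble with `cls`, `bmc_summary`, `score_summary` and an
#'   identifying `endpoint` column.
#' @return One-row tibble: `cls`, `bmc`, `score`, `provenance` (the
#'   contributing endpoint), `n_contributing`.
#' @export
collapse_group <- function(calls) {
  stopifnot(nrow(calls) >= 1L, all(calls$cls %in% .class_precedence))
  best_cls <- .class_precedence[min(match(calls$cls, .class_precedence))]
  cand <- calls |> filter(.data$cls == best_cls)
  pick <- if (all(is.na(cand$bmc_summary))) {
    cand[1L, ]
  } else {
    cand |> slice_min(.data$bmc_summary, n = 1L, with_ties = FALSE, na_rm = TRUE)
  }
  tibble(
    cls = best_cls,
    bmc = pick$bmc_summary,
    score = pick$score_summary,
    provenance = pick$endpoint,
    n_contributing = nrow(calls)
  )
}

#' Collapse substance-level endpoint calls into defect groups
#'
#' Joins substance calls (one per substance x combined endpoint) to the
#' ontology map through the endpoint's recording name and applies
#' [collapse_group()] per substance x defect group at the requested level.
#' Mortality and any-malformation endpoints carry no recording and are
#' excluded; recordings whose terms lack a defect group do not contribute.
#'
#' @param substance_calls `substance_calls` tibble from
#'   [specificity_analysis()].
#' @param map Ontology mapping tibble.
#' @param lab Lab id whose recordings the endpoints use.
#' @param level `"general"` or `"granular"`.
#' @return Tibble: `substance_id`, `group`, `cls`, `bmc`, `score`,
#'   `provenance`, `n_contributing`.
#' @export
collapse_calls <- function(substance_calls, map, lab,
                           level = c("general", "granular")) {
  level <- match.arg(level)
  group_col <- paste0(level, "_group")
  links <- map |>
    filter(.data$lab == .env$lab, !is.na(.data[[group_col]])) |>
    distinct(.data$recording, group = .data[[group_col]])
  joined <- substance_calls |>
    mutate(recording = sub("\\+Mort@120$", "", .data$endpoint)) |>
    inner_join(links, by = "recording", relationship = "many-to-many")
  joined |>
    group_by(.data$substance_id, .data$group) |>
    group_modify(~ collapse_group(.x)) |>
    ungroup()
}

#' Edge list of the recording-to-defect-group hierarchy
#'
#' Flattens the mapping into the three edge layers of a Sankey diagram
#' (recording -> term -> granular group -> general group) with the node
#' annotations used to read such a diagram: per recording the number of
#' mapped terms, per term the number of laboratories recording it, per
#' defect group the number of recorded phenotypes (from all labs) feeding
#' it. Terms without a defect group have no outgoing edge.
#'
#' @param map Mapping tibble.
#' @return List: `edges` (`from`, `to`, `layer`, `n`) and `nodes`
#'   (`node`, `level`, `annotation`).
#' @export
sankey_edges <- function(map) {
  rec_term <- map |>
    distinct(.data$lab, .data$recording, .data$term_label) |>
    count(from = paste0(.data$lab, ":", .data$recording),
          to = .data$term_label) |>
    mutate(layer = "recording->term")
  term_gran <- map |>
    filter(!is.na(.data$granular_group)) |>
    distinct(from = .data$term_label, to = .data$granular_group) |>
    mutate(n = 1L, layer = "term->granular")
  gran_gen <- map |>
    filter(!is.na(.data$granular_group), !is.na(.data$general_group)) |>
    distinct(from = .data$granular_group, to = .data$general_group) |>
    mutate(n = 1L, layer = "granular->general")

  node_rec <- map |>
    group_by(node = paste0(.data$lab, ":", .data$recording)) |>
    summarise(annotation = n_distinct(.data$ontology_id), .groups = "drop") |>
    mutate(level = "recording")
  node_term <- map |>
    group_by(node = .data$term_label) |>
    summarise(annotation = n_distinct(.data$lab), .groups = "drop") |>
    mutate(level = "term")
  node_gran <- map |>
    filter(!is.na(.data$granular_group)) |>
    group_by(node = .data$granular_group) |>
    summarise(annotation = n_distinct(paste0(.data$lab, ":", .data$recording)),
              .groups = "drop") |>
    mutate(level = "granular")
  node_gen <- map |>
    filter(!is.na(.data$general_group)) |>
    group_by(node = .data$general_group) |>
    summarise(annotation = n_distinct(paste0(.data$lab, ":", .data$recording)),
              .groups = "drop") |>
    mutate(level = "general")

  list(
    edges = bind_rows(rec_term, term_gran, gran_gen) |>
      select("from", "to", "layer", "n"),
    nodes = bind_rows(node_rec, node_term, node_gran, node_gen) |>
      select("node", "level", "annotation")
  )
}
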