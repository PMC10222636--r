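toy_map <- function() {
  tibble::tibble(
    lab = c("L1", "L1", "L2", "L2", "L3", "L3", "L3"),
    recording = c("edema", "bent", "EDM", "TRNK", "edm_img", "trunk_img", "pig_img"),
    ontology_id = c("T1", "T2", "T1", "T2", "T1", "T2", "T3"),
    term_label = c("edema term", "axis term", "edema term", "axis term",
                   "edema term", "axis term", "pigment term"),
    granular_group = c("g-edema", "g-axis", "g-edema", "g-axis",
                       "g-edema", "g-axis", NA),
    general_group = c("G-heart", "G-torso", "G-heart", "G-torso",
                      "G-heart", "G-torso", NA)
  )
}

test_that("recording lookup returns its terms, order-stable", {
  map <- example_ontology_map()
  edem <- map_recording("EDEM", map, lab = "Lab_B")
  expect_identical(nrow(edem), 2L)
  expect_setequal(edem$term_label,
                  c("heart edematous, abnormal", "yolk edematous, abnormal"))
  yolk <- map_recording("Yolk_opacity", map)
  expect_identical(yolk$ontology_id, "ZP:0002198")
  expect_error(map_recording("No_such_recording", map), "No_such_recording")
})

test_that("mapping statistics give terms per recording", {
  # a lab mapping 11 recordings onto 19 distinct terms averages 1.72
  lab <- tibble::tibble(
    lab = "LX",
    recording = rep(paste0("r", 1:11), times = c(2, 2, 2, 2, 2, 2, 2, 2, 1, 1, 1)),
    ontology_id = paste0("T", 1:19),
    term_label = paste0("term ", 1:19),
    granular_group = NA_character_, general_group = NA_character_
  )
  st <- mapping_stats(lab, "LX")
  expect_identical(st$n_recordings, 11L)
  expect_identical(st$n_terms, 19L)
  expect_equal(round(st$terms_per_recording, 2), 1.73) # 19/11
  expect_equal(st$terms_per_recording, 19 / 11)

  one2one <- toy_map() |> dplyr::filter(lab == "L1")
  expect_equal(mapping_stats(one2one, "L1")$terms_per_recording, 1)

  expect_warning(empty <- mapping_stats(toy_map(), "L9"), "no mappings")
  expect_true(is.na(empty$terms_per_recording))
})

test_that("cross-lab overlap counts fully shared items", {
  ov <- ontology_overlap(toy_map())
  expect_identical(ov$term$n_fully_shared, 2L)   # T1, T2 in all three labs
  expect_identical(ov$granular$n_fully_shared, 2L)
  expect_identical(ov$general$n_fully_shared, 2L)

  # single shared term
  m1 <- toy_map() |> dplyr::filter(ontology_id %in% c("T1", "T3"))
  expect_identical(ontology_overlap(m1)$term$n_fully_shared, 1L)

  # disjoint vocabularies share nothing
  m2 <- toy_map() |>
    dplyr::mutate(term_label = paste(lab, term_label))
  expect_identical(ontology_overlap(m2)$term$n_fully_shared, 0L)

  # renaming recordings cannot change term overlap
  m3 <- toy_map() |> dplyr::mutate(recording = paste0("renamed_", recording))
  expect_identical(ontology_overlap(m3)$term$n_fully_shared,
                   ontology_overlap(toy_map())$term$n_fully_shared)
})

test_that("the bundled map reproduces the expected sharing structure", {
  map <- example_ontology_map()
  ov <- ontology_overlap(map)
  expect_identical(ov$term$n_fully_shared, 8L)
  # terms without structural change carry no defect group
  no_group <- map |> dplyr::filter(is.na(granular_group))
  expect_setequal(unique(no_group$term_label),
                  c("yolk opaque, abnormal", "whole organism dead, abnormal",
                    "touch response decreased, abnormal"))
})

test_that("group collapsing follows class precedence then potency", {
  calls <- tibble::tibble(
    endpoint = c("A+Mort@120", "B+Mort@120", "C+Mort@120"),
    cls = c("specific", "specific", "non-specific"),
    bmc_summary = c(-4.5, -5.0, -6.0),
    score_summary = c(0.4, 0.6, 0.1)
  )
  g <- collapse_group(calls)
  expect_identical(g$cls, "specific")
  expect_equal(g$bmc, -5.0)             # most potent of the winning class
  expect_identical(g$provenance, "B+Mort@120")

  g2 <- collapse_group(tibble::tibble(
    endpoint = c("A", "B"), cls = c("non-specific", "inconclusive"),
    bmc_summary = c(-5, -4), score_summary = c(0.1, NA)
  ))
  expect_identical(g2$cls, "non-specific")

  g3 <- collapse_group(tibble::tibble(
    endpoint = "A", cls = "non-toxic",
    bmc_summary = NA_real_, score_summary = NA_real_
  ))
  expect_identical(g3$cls, "non-toxic")

  # idempotence: collapsing a collapsed result changes nothing
  again <- collapse_group(g |> dplyr::rename(bmc_summary = bmc,
                                             score_summary = score,
                                             endpoint = provenance) |>
                            dplyr::select(endpoint, cls, bmc_summary, score_summary))
  expect_identical(again$cls, g$cls)
  expect_equal(again$bmc, g$bmc)
})

test_that("substance calls collapse into defect groups through the map", {
  calls <- tibble::tibble(
    substance_id = "S1",
    endpoint = c("edema+Mort@120", "bent+Mort@120"),
    cls = c("specific", "non-specific"),
    bmc_summary = c(-5, -4.5), score_summary = c(0.5, 0.1), n_plates = 3L
  )
  gc <- collapse_calls(calls, toy_map(), lab = "L1", level = "general")
  expect_setequal(gc$group, c("G-heart", "G-torso"))
  expect_identical(gc$cls[gc$group == "G-heart"], "specific")

  # general-level class precedence dominates each granular member
  gg <- collapse_calls(calls, toy_map(), lab = "L1", level = "granular")
  prec <- c(specific = 1, `non-specific` = 2, inconclusive = 3, `non-toxic` = 4)
  for (g in seq_len(nrow(gg))) {
    gen <- gc$cls[gc$group == "G-heart"]
    expect_lte(prec[[gen]], prec[[gg$cls[gg$group == "g-edema"]]])
  }
})

test_that("sankey edge list carries the hierarchy and lab counts", {
  one <- toy_map()[1, ]
  sk1 <- sankey_edges(one)
  expect_identical(nrow(sk1$edges), 3L)   # recording -> term -> granular -> general
  expect_identical(sk1$edges$layer,
                   c("recording->term", "term->granular", "granular->general"))

  sk <- sankey_edges(toy_map())
  nodes <- sk$nodes
  expect_identical(nodes$annotation[nodes$node == "edema term"], 3L) # 3 labs
  # a term without a defect group has no outgoing edge
  expect_false("pigment term" %in% sk$edges$from)
  # general-group annotation counts recordings from all labs
  expect_identical(nodes$annotation[nodes$node == "G-heart"], 3L)
})
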