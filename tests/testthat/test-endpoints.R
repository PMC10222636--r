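test_that("endpoint enumeration follows the n + 2 rule", {
  recs <- function(n) tibble::tibble(
    recording_name = paste0("P", seq_len(n)),
    is_binarized_quantitative = FALSE
  )
  expect_identical(nrow(enumerate_endpoints(recs(21))), 23L)
  expect_identical(nrow(enumerate_endpoints(recs(9))), 11L)
  expect_identical(nrow(enumerate_endpoints(recs(5))), 7L)
  eps <- enumerate_endpoints(recs(3))
  expect_true(all(c("Mortality@120", "MalformedAny+Mort@120") %in% eps$name))
  expect_true(all(eps$timepoint == 120L))
  expect_identical(sum(eps$kind == "combined_phenotype"), 3L)
  # combined endpoint names are "<recording>+Mort@120" verbatim
  expect_true("P1+Mort@120" %in% eps$name)
})

test_that("percent response counts dead plus flagged survivors", {
  w <- toy_wells() |> dplyr::filter(substance_id == "SUB")
  recs <- toy_recordings()
  # at 10 uM: 3 dead at 120, 2 survivors with edema
  hi <- which(w$conc_uM == 10)
  w$alive_120[hi[1:3]] <- FALSE
  w$Edema[hi[1:3]] <- NA
  w$Edema[hi[4:5]] <- TRUE
  ep <- enumerate_endpoints(recs) |> dplyr::filter(recording == "Edema")
  cr <- percent_response(w, ep, recs)
  expect_equal(cr$response, c(0, 100 * 5 / 11))
  expect_equal(cr$n, c(11L, 11L))
  expect_equal(cr$conc_log10M, c(-6, -5))
})

test_that("vehicle control with no events responds at 0 percent", {
  w <- toy_wells() |> dplyr::filter(substance_id == "VC")
  recs <- toy_recordings()
  ep <- enumerate_endpoints(recs) |> dplyr::filter(name == "Mortality@120")
  expect_equal(vc_response(w, ep, recs), 0)
})

test_that("mortality endpoints attribute deaths to their timepoint", {
  w <- toy_wells() |> dplyr::filter(substance_id == "SUB", conc_uM == 10)
  recs <- toy_recordings()
  # one embryo dead by 24 hpf, one dies between 24 and 120 hpf
  w$alive_24[1] <- FALSE; w$alive_120[1] <- FALSE; w$Edema[1] <- NA
  w$alive_120[2] <- FALSE; w$Edema[2] <- NA
  m24 <- percent_response(w, mortality24_endpoint(), recs)
  m120 <- percent_response(
    w, enumerate_endpoints(recs) |> dplyr::filter(name == "Mortality@120"), recs
  )
  expect_equal(m24$response, 100 * 1 / 11)
  expect_equal(m120$response, 100 * 2 / 11)
})

test_that("any-malformation excludes binarized quantitative traits", {
  w <- toy_wells() |> dplyr::filter(substance_id == "SUB", conc_uM == 10)
  recs <- toy_recordings()
  # 1 dead, 2 with the binary phenotype, 1 with only the quantitative trait
  w$alive_120[1] <- FALSE; w$Edema[1] <- NA; w$Trait_q[1] <- NA
  w$Edema[2:3] <- TRUE
  w$Trait_q[4] <- TRUE
  ep <- enumerate_endpoints(recs) |> dplyr::filter(kind == "malformed_any")
  cr <- percent_response(w, ep, recs)
  expect_equal(cr$response, 100 * 3 / 11)

  # the quantitative-trait-only embryo is not affected; dead always is
  ep_q <- enumerate_endpoints(recs) |> dplyr::filter(recording == "Trait_q")
  cr_q <- percent_response(w, ep_q, recs)
  expect_equal(cr_q$response, 100 * 2 / 11) # the dead embryo + the flagged one
})

test_that("PC wells pool by ISO calendar week", {
  recs <- toy_recordings()
  mk_pc <- function(plate, date) tibble::tibble(
    plate_id = plate, run_date = as.Date(date),
    well = sprintf("H%02d", 1:7), substance_id = "PC",
    conc_uM = 10^seq(-1, 2, by = 0.5),
    alive_24 = TRUE, alive_120 = TRUE, Edema = FALSE, Trait_q = FALSE
  )
  ep <- enumerate_endpoints(recs) |> dplyr::filter(name == "Mortality@120")

  one_week <- dplyr::bind_rows(
    mk_pc("P1", "2021-03-01"), mk_pc("P2", "2021-03-03"), mk_pc("P3", "2021-03-05")
  )
  pooled <- pool_pc_weekly(one_week, ep, recs)
  expect_identical(length(unique(pooled$pool_id)), 1L)
  expect_true(all(pooled$n == 3L))
  expect_false(any(pooled$low_n))

  two_weeks <- dplyr::bind_rows(mk_pc("P1", "2021-03-01"), mk_pc("P2", "2021-03-10"))
  pooled2 <- pool_pc_weekly(two_weeks, ep, recs)
  expect_identical(length(unique(pooled2$pool_id)), 2L)
  expect_true(all(pooled2$low_n)) # one plate per week

  empty <- pool_pc_weekly(one_week[0, ], ep, recs)
  expect_identical(nrow(empty), 0L)
})

test_that("combined endpoints dominate mortality pointwise", {
  ed <- small_endpoint_data()
  wide <- ed |>
    dplyr::select(endpoint, substance_id, replicate_key, conc_uM, response) |>
    tidyr::pivot_wider(names_from = endpoint, values_from = response)
  mort <- wide[["Mortality@120"]]
  for (ep in setdiff(names(wide), c("substance_id", "replicate_key", "conc_uM",
                                    "Mortality@120"))) {
    expect_true(all(wide[[ep]] >= mort), info = ep)
  }
})

test_that("endpoint denominators equal embryos dosed per concentration", {
  s <- small_study()
  ed <- small_endpoint_data()
  one <- ed |>
    dplyr::filter(endpoint == "Mortality@120",
                  substance_id == s$truth$substance_id[1])
  n_dosed <- s$wells |>
    dplyr::filter(substance_id == s$truth$substance_id[1]) |>
    dplyr::count(plate_id, conc_uM)
  merged <- dplyr::inner_join(
    one, n_dosed, by = c(replicate_key = "plate_id", "conc_uM")
  )
  expect_identical(nrow(merged), nrow(one))
  expect_identical(merged$n.x, merged$n.y)
})
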