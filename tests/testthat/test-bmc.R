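test_that("weighted PAVA matches the brute-force isotonic oracle", {
  expect_equal(pava(c(0, 10, 5, 20)), c(0, 7.5, 7.5, 20))
  expect_equal(pava(c(1, 2, 3)), c(1, 2, 3))       # already monotone
  expect_equal(pava(c(4, 4, 4)), c(4, 4, 4))       # all equal
  # weights pull the pooled mean toward the heavier observation
  expect_equal(pava(c(10, 0), w = c(1, 3)), c(2.5, 2.5))

  set.seed(101)
  for (i in 1:200) {
    n <- sample(2:6, 1)
    y <- round(runif(n, 0, 100), 1)
    w <- sample(1:11, n, replace = TRUE)
    expect_equal(pava(y, w), isotonic_oracle(y, w), tolerance = 1e-10)
  }
})

test_that("monotonize projects onto non-decreasing curves in [0, 100]", {
  cr <- tibble::tibble(conc_log10M = -6:-3, response = c(30, 10, 50, 40),
                       n = c(11, 11, 11, 11))
  m <- monotonize(cr)
  expect_true(all(diff(m$response_corrected) >= 0))
  expect_true(all(m$response_corrected >= 0 & m$response_corrected <= 100))
  expect_error(monotonize(cr[1, ]), "at least 2")
})

test_that("BMC interpolation, boundary and censoring conventions", {
  mk <- function(y, conc = -6:-3) {
    monotonize(tibble::tibble(conc_log10M = conc, response = y,
                              n = rep(11, length(y))))
  }
  # linear interpolation between bracketing concentrations
  r <- bmc_at(mk(c(0, 0, 20, 40)), 30)
  expect_true(r$active)
  expect_equal(r$bmc_log10M, -3.5)

  # inactive: censored at the highest tested concentration
  r2 <- bmc_at(mk(c(0, 5, 10, 15)), 30)
  expect_false(r2$active)
  expect_true(r2$censored_at_max)
  expect_equal(r2$bmc_log10M, -3)

  # exact hit at a tested concentration
  r3 <- bmc_at(mk(c(0, 10, 30, 60)), 30)
  expect_equal(r3$bmc_log10M, -4)

  # first concentration already above the threshold: censored low
  r4 <- bmc_at(mk(c(50, 60, 70, 80)), 30)
  expect_true(r4$censored_low)
  expect_equal(r4$bmc_log10M, -6)

  # flat corrected segment exactly at the threshold: lowest conc of segment
  r5 <- bmc_at(mk(c(0, 30, 30, 60)), 30)
  expect_equal(r5$bmc_log10M, -5)
})

test_that("raising the BMR never yields a more potent BMC", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(4:9, 1)
    cr <- monotonize(tibble::tibble(
      conc_log10M = seq(-7, by = 0.5, length.out = n),
      response = runif(n, 0, 100), n = rep(11, n)
    ))
    bmrs <- sort(runif(2, 5, 95))
    lo <- bmc_at(cr, bmrs[1])$bmc_log10M
    hi <- bmc_at(cr, bmrs[2])$bmc_log10M
    expect_gte(hi, lo)
  }
})

test_that("pooled variance combines substances by degrees of freedom", {
  one <- tibble::tibble(substance_id = "a", bmc_log10M = c(-4.0, -4.2, -4.1))
  expect_equal(pooled_variance(one), 0.01)

  two <- dplyr::bind_rows(
    tibble::tibble(substance_id = "a", bmc_log10M = c(-4.1, -4.0, -4.2)),
    tibble::tibble(substance_id = "b", bmc_log10M = c(-5.2, -5.0, -4.8))
  )
  expect_equal(pooled_variance(two), (2 * 0.01 + 2 * 0.04) / 4)

  # singleton substances carry no degrees of freedom
  expect_error(
    pooled_variance(tibble::tibble(substance_id = c("a", "b"),
                                   bmc_log10M = c(-4, -5))),
    ">= 2 replicates"
  )
})

test_that("threshold scan on identical replicates is identically zero", {
  cr <- monotonize(tibble::tibble(conc_log10M = -6:-3,
                                  response = c(0, 20, 60, 90), n = rep(11, 4)))
  curves <- list(cr, cr, cr)
  keys <- tibble::tibble(substance_id = "a", replicate_key = c("p1", "p2", "p3"))
  prof <- scan_thresholds(curves, keys, seq(5, 95, by = 5))
  expect_true(all(prof$pooled_variance == 0))

  prof1 <- scan_thresholds(curves, keys, 50)
  expect_identical(nrow(prof1), 1L)
})

test_that("BMR selection finds the stabilization point of a decay profile", {
  grid <- seq(5, 95, by = 5)
  prof <- tibble::tibble(threshold = grid,
                         pooled_variance = 0.5 * exp(-0.3 * grid) + 0.02)
  sel <- select_bmr(prof)
  # analytic stabilization: exp(-0.3 t) = 0.05 at t = 9.986
  expect_true(sel$converged)
  expect_equal(sel$bmr, 10)

  flat <- tibble::tibble(threshold = grid, pooled_variance = rep(0.03, 19))
  sel_flat <- select_bmr(flat)
  expect_equal(sel_flat$bmr, 5)
  expect_true(sel_flat$converged)

  rising <- tibble::tibble(threshold = grid,
                           pooled_variance = seq(0.01, 0.2, length.out = 19))
  expect_warning(sel_up <- select_bmr(rising), "does not decay")
  expect_false(sel_up$converged)
  expect_equal(sel_up$bmr, 95)
})

test_that("BMC recovers simulated Hill potency", {
  # full-top Hill curves, binomial sampling noise, 11 embryos/concentration;
  # BMC at BMR 50 should sit near the true AC50
  set.seed(11)
  conc_uM <- 10^seq(-1, 2, by = 0.5)
  n_sub <- 60
  errs <- vapply(seq_len(n_sub), function(i) {
    ac50 <- 10^runif(1, -0.5, 1.5)
    p <- hill_prob(conc_uM, ac50, runif(1, 2, 4), 0, 1)
    resp <- 100 * rbinom(length(p), 11, p) / 11
    cr <- monotonize(tibble::tibble(conc_log10M = log10_molar(conc_uM),
                                    response = resp, n = rep(11, length(p))))
    bmc_at(cr, 50)$bmc_log10M - log10_molar(ac50)
  }, numeric(1))
  expect_lt(median(abs(errs)), 0.25)
})

test_that("the selected BMR never drops when sampling noise doubles", {
  # same underlying Hill truths scored with 12 vs 3 embryos per
  # concentration: quadrupled binomial variance must not lower the BMR
  conc_uM <- 10^seq(-1, 2, by = 0.5)
  grid <- seq(5, 95, by = 5)
  one_dataset <- function(n_embryo, seed) {
    set.seed(seed)
    curves <- list(); keys <- list()
    for (s in 1:15) {
      ac50 <- 10^runif(1, -0.3, 1.3)
      slope <- runif(1, 2, 4)
      for (r in 1:3) {
        p <- hill_prob(conc_uM, ac50, slope, 0, 0.95)
        resp <- 100 * rbinom(length(p), n_embryo, p) / n_embryo
        curves[[length(curves) + 1L]] <- monotonize(
          tibble::tibble(conc_log10M = log10_molar(conc_uM),
                         response = resp, n = rep(n_embryo, length(p)))
        )
        keys[[length(keys) + 1L]] <- tibble::tibble(substance_id = paste0("s", s))
      }
    }
    suppressWarnings(
      select_bmr(scan_thresholds(curves, dplyr::bind_rows(keys), grid))$bmr
    )
  }
  for (seed in 1:10) {
    expect_gte(one_dataset(3, seed), one_dataset(12, seed))
  }
})

test_that("dataset BMR estimation and BMC fitting run over endpoint data", {
  ed <- small_endpoint_data()
  sub <- ed |> dplyr::filter(endpoint %in% c("Mortality@120",
                                             "MalformedAny+Mort@120"))
  bmr <- suppressWarnings(estimate_dataset_bmr(sub))
  expect_identical(nrow(bmr), 2L)
  expect_true(all(bmr$bmr %in% seq(5, 95, by = 5)))

  bmc <- fit_bmc(sub, bmr)
  expect_true(all(c("active", "bmc_log10M", "censored_at_max") %in% names(bmc)))
  # every inactive replicate is censored at the top tested concentration
  top <- log10_molar(100)
  inact <- bmc |> dplyr::filter(!active)
  expect_true(all(inact$censored_at_max))
  expect_true(all(inact$bmc_log10M == top))
  # active BMCs sit within the tested range
  act <- bmc |> dplyr::filter(active)
  expect_true(all(act$bmc_log10M >= log10_molar(0.1) - 1e-9 &
                    act$bmc_log10M <= top + 1e-9))
})
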