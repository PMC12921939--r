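test_that("regression censoring keeps the strict (14, 30) band", {
  pairs <- tibble::tibble(octopus_db = c(5, 14, 14.5, 20, 29.9, 30, 31),
                          hmp_db_raw = 1)
  kept <- censor_for_regression(pairs)
  expect_equal(kept$octopus_db, c(14.5, 20, 29.9))
  expect_equal(nrow(censor_for_regression(
    tibble::tibble(octopus_db = c(5, 31), hmp_db_raw = 0))), 0)
  # order preserved
  pairs2 <- tibble::tibble(octopus_db = c(20, 15, 25), hmp_db_raw = 1)
  expect_equal(censor_for_regression(pairs2)$octopus_db, c(20, 15, 25))
})

test_that("Deming recovers a noiseless line exactly", {
  x <- seq(1, 10)
  fit <- deming_fit(x = x, y = 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$n, 10)
  expect_true(fit$slope_ci[1] <= fit$slope && fit$slope <= fit$slope_ci[2])
  # data-frame-first interface with default column names
  df <- data.frame(octopus_db = x, hmp_db_raw = 2 * x + 1)
  expect_equal(deming_fit(df)$slope, 2, tolerance = 1e-9)
})

test_that("Deming with lambda = 1 satisfies the axis-swap identity", {
  set.seed(14)
  x <- runif(40, 0, 30)
  y <- 0.8 * x - 5 + rnorm(40, 0, 2)
  xy <- deming_fit(x = x, y = y)
  yx <- deming_fit(x = y, y = x)
  expect_equal(xy$slope, 1 / yx$slope, tolerance = 1e-9)
})

test_that("Deming matches a perpendicular-distance minimization oracle", {
  set.seed(25)
  for (lambda in c(1, 2)) {
    for (rep in 1:3) {
      x <- runif(20, 0, 30)
      y <- 0.77 * x - 10 + rnorm(20, 0, 1.5)
      x <- x + rnorm(20, 0, 1.5 / sqrt(lambda))
      fit <- deming_fit(x = x, y = y, lambda = lambda)
      oracle <- deming_oracle(x, y, lambda = lambda)
      expect_equal(fit$slope, unname(oracle["slope"]), tolerance = 1e-3)
      expect_equal(fit$intercept, unname(oracle["intercept"]),
                   tolerance = 1e-3)
    }
  }
})

test_that("Deming rejects degenerate inputs", {
  expect_error(deming_fit(x = 1:2, y = 1:2), "at least 3")
  expect_error(deming_fit(x = c(1, 1, 1), y = 1:3), "identical")
  expect_error(deming_fit(x = 1:4, y = 1:3), "equal length")
  # zero covariance with flat y: horizontal line, not an error
  flat <- deming_fit(x = 1:5, y = rep(7, 5))
  expect_equal(flat$slope, 0)
  expect_equal(flat$intercept, 7)
})

test_that("jackknife intervals cover a known slope at roughly nominal rate", {
  set.seed(8)
  hits <- replicate(60, {
    x <- runif(40, 0, 30)
    y <- 0.8 * x - 5 + rnorm(40, 0, 1.5)
    x <- x + rnorm(40, 0, 1.5)
    ci <- deming_fit(x = x, y = y)$slope_ci
    ci[1] <= 0.8 && 0.8 <= ci[2]
  })
  expect_gte(mean(hits), 0.8)
})

test_that("Bland-Altman statistics follow the 1.96-SD construction", {
  x <- c(10, 20, 30)
  ba0 <- bland_altman(x = x, y = x)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(ba0$loa_high - ba0$loa_low, 0)
  ba14 <- bland_altman(x = x + 14, y = x)
  expect_equal(ba14$mean_diff, 14)
  expect_equal(ba14$sd_diff, 0)
  set.seed(6)
  d <- rnorm(500, 15.9, 3.8)
  ba <- bland_altman(x = d, y = rep(0, 500))
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd_diff)
  expect_equal(ba$mean_diff, mean(d))
  expect_error(bland_altman(x = 1, y = 2), "at least 2")
})

test_that("limits of agreement contain ~95% of normal differences", {
  set.seed(1234)
  d <- rnorm(10000, 15.9, 3.8)
  ba <- bland_altman(x = d, y = rep(0, 10000))
  inside <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_lt(abs(inside - 0.95), 0.006)
})

test_that("contingency classification matches hand enumeration", {
  pairs <- tibble::tibble(
    octopus_db = c(10, 25, 13.9, 14, 20, 5),
    hmp_db_raw = c(0, 6, 2, 0, 0, 0)
  )
  # by hand: tp (10,0), tn (25,6), fn (13.9,2), fp (14,0), fp (20,0), tp (5,0)
  counts <- contingency_counts(pairs)
  expect_equal(counts$tp, 2)
  expect_equal(counts$tn, 1)
  expect_equal(counts$fn, 1)
  expect_equal(counts$fp, 2)
  expect_equal(counts$tn + counts$fn + counts$fp + counts$tp, nrow(pairs))
})

test_that("contingency counts are conserved on random pair sets", {
  set.seed(42)
  for (i in 1:5) {
    n <- sample(10:200, 1)
    pairs <- tibble::tibble(
      octopus_db = runif(n, 0, 33),
      hmp_db_raw = sample(c(0, runif(n, 0, 16)), n, replace = TRUE)
    )
    counts <- contingency_counts(pairs)
    expect_equal(counts$tn + counts$fn + counts$fp + counts$tp, n)
  }
})

test_that("diagnostic metrics reproduce the published contingency table", {
  counts <- data.frame(tn = 1001, fn = 191, fp = 55, tp = 385)
  m <- diagnostic_metrics(counts)
  expect_equal(round(m$sensitivity, 2), 0.67)
  expect_equal(round(m$specificity, 2), 0.95)
  perfect <- diagnostic_metrics(data.frame(tn = 10, fn = 0, fp = 0, tp = 5))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_error(diagnostic_metrics(data.frame(tn = 1, fn = 0, fp = 0, tp = 0)),
               "sensitivity undefined")
  expect_error(diagnostic_metrics(data.frame(tn = 0, fn = 1, fp = 0, tp = 1)),
               "specificity undefined")
})

test_that("pairing harmonizes scales and rejects unmatched inputs", {
  oct <- measured_tbl(c(20, 25, 10), device = "octopus900")
  hmp <- measured_tbl(c(8, 11, 0), device = "iowa_hmp")
  pairs <- pair_fields(oct, hmp)
  expect_equal(pairs$hmp_db_equivalent, c(22, 25, 0))
  expect_equal(pairs$octopus_db, c(20, 25, 10))
  expect_error(pair_fields(oct, hmp[-1, ]), "unmatched")
  expect_error(pair_fields(oct, dplyr::mutate(hmp, subject_id = "S2")),
               "no matching")
  expect_error(pair_fields(oct[0, ], hmp), "empty")
  expect_error(pair_fields(dplyr::select(oct, -sensitivity_db), hmp),
               "missing column")
})

test_that("self-agreement yields slope 1, mean offset, perfect detection", {
  set.seed(10)
  vals <- runif(68, 0, 16)
  vals[1:6] <- 0  # some floored locations, identically in both devices
  hmp <- measured_tbl(vals, device = "iowa_hmp")
  oct <- measured_tbl(to_octopus_equivalent(vals, 14), device = "octopus900")
  rep <- compare_fields(oct, hmp)
  expect_equal(rep$deming$slope, 1, tolerance = 1e-6)
  expect_equal(rep$bland_altman$mean_diff, 14, tolerance = 1e-9)
  expect_equal(rep$metrics$sensitivity, 1)
  expect_equal(rep$metrics$specificity, 1)
})

test_that("the full report bundles all components with consistent counts", {
  sim <- simulate_study(cohort_config(1, 1, 0, 1), seed = 15)
  oct <- dplyr::filter(sim$measured, device == "octopus900")
  hmp <- dplyr::filter(sim$measured, device == "iowa_hmp")
  rep <- compare_fields(oct, hmp)
  expect_s3_class(rep, "agreement_report")
  expect_equal(rep$options$n_pairs, 6 * 68)
  expect_equal(rep$contingency$n, 6 * 68)
  # regression input honors censoring
  reg <- censor_for_regression(rep$pairs)
  expect_true(all(reg$octopus_db > 14 & reg$octopus_db < 30))
  expect_equal(rep$deming$n, nrow(reg))
  # tidy/glance wiring
  td <- generics::tidy(rep)
  expect_true(all(c("deming", "bland_altman", "diagnostics") %in%
                    td$component))
  gl <- generics::glance(rep)
  expect_equal(gl$n_pairs, 6 * 68)
  # alternative Bland-Altman rule drops floored pairs
  rep2 <- compare_fields(oct, hmp, ba_floor_rule = "drop_floored")
  expect_lte(rep2$bland_altman$n, rep$bland_altman$n)
  expect_error(compare_fields(oct[0, ], hmp), "empty")
})

test_that("noise-free aligned devices recover near-perfect floor detection", {
  # small-cohort sanity check (n = 680 locations); residual misses sit only
  # at the 14 dB boundary, so both metrics approach 1
  cfg <- cohort_config(slope_sd = 0.05, fp_rate = 0, fn_rate = 0,
                       n_normal = 1, n_omd = 1, n_stgd = 1, n_rp = 2)
  set.seed(21)
  cohort <- generate_cohort(cfg)
  oct <- purrr::map_dfr(cohort, ~run_exam(octopus900(), .x))
  hmp <- purrr::map_dfr(cohort, ~run_exam(iowa_hmp(), .x))
  rep <- compare_fields(oct, hmp)
  m <- rep$metrics
  expect_gte(m$sensitivity, 0.98)
  expect_gte(m$specificity, 0.98)
  misses <- rep$pairs[(rep$pairs$octopus_db < 14) !=
                        (rep$pairs$hmp_db_raw == 0), ]
  if (nrow(misses) > 0) {
    expect_true(all(abs(misses$octopus_db - 14) < 1.5))
  }
})

test_that("reports serialize to JSON with all statistic blocks", {
  sim <- simulate_study(cohort_config(1, 0, 0, 1), seed = 33)
  rep <- compare_fields(dplyr::filter(sim$measured, device == "octopus900"),
                        dplyr::filter(sim$measured, device == "iowa_hmp"))
  path <- withr::local_tempfile(fileext = ".json")
  report_to_json(rep, path)
  payload <- jsonlite::read_json(path)
  expect_named(payload, c("deming", "bland_altman", "contingency", "metrics",
                          "options"))
  expect_equal(payload$deming$slope, rep$deming$slope, tolerance = 1e-9)
  expect_equal(payload$contingency$n, rep$contingency$n)
})
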