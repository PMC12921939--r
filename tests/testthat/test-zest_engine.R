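test_that("initial state spans the guarded domain with a normalized prior", {
  hmp <- iowa_hmp()
  st <- zest_init(hmp)
  expect_equal(min(st$domain), -5)
  expect_equal(max(st$domain), dynamic_range(hmp) + 5, tolerance = 0.5)
  expect_equal(sum(st$pdf), 1, tolerance = 1e-12)
  expect_equal(max(st$pdf) - min(st$pdf), 0)
  # supplied prior stored normalized
  w <- seq_along(st$domain)
  st2 <- zest_init(hmp, prior = w)
  expect_equal(sum(st2$pdf), 1, tolerance = 1e-12)
  expect_equal(st2$pdf, w / sum(w))
  expect_error(zest_init(hmp, prior = w[-1]), "one weight per domain level")
  expect_error(zest_init(hmp, prior = -w), "non-negative")
})

test_that("pdf stays normalized and presentations capped through an exam", {
  hmp <- iowa_hmp()
  set.seed(1)
  for (t in c(-4, 5, 12, 30)) {
    obs <- single_location_observer(t)
    st <- zest_init(hmp)
    while (!st$finished) {
      st <- zest_step(st, hmp, function(s) {
        runif(1) < seen_probability(obs, t, s)
      })
      expect_equal(sum(st$pdf), 1, tolerance = 1e-12)
    }
    expect_lte(st$n_presentations, 12)
    expect_error(zest_step(st, hmp, function(s) TRUE), "finished")
  }
})

test_that("Bayes updates move stimuli toward the threshold", {
  hmp <- iowa_hmp()
  t <- 8
  # deterministic observer: seen iff the stimulus is brighter than threshold
  st <- zest_init(hmp)
  levels <- numeric(0)
  while (!st$finished) {
    m <- min(max(sum(st$domain * st$pdf), 0), st$dynamic_range)
    levels <- c(levels, m)
    st <- zest_step(st, hmp, function(s) s < t)
  }
  expect_lt(abs(zest_estimate(st) - t), 1.5)
  # successive levels bracket the threshold ever more tightly
  expect_lt(abs(levels[length(levels)] - t), abs(levels[1] - t))
})

test_that("all-unseen floors the estimate and all-seen ceilings it", {
  hmp <- iowa_hmp()
  st <- zest_init(hmp)
  while (!st$finished) st <- zest_step(st, hmp, function(s) FALSE)
  expect_equal(zest_estimate(st), 0)
  st <- zest_init(hmp)
  while (!st$finished) st <- zest_step(st, hmp, function(s) TRUE)
  expect_equal(zest_estimate(st), dynamic_range(hmp))
  expect_error(zest_estimate(zest_init(hmp)), "before")
})

test_that("threshold recovery is unbiased within the measurable range", {
  hmp <- iowa_hmp()
  set.seed(20)
  est <- replicate(200, zest_estimate(run_single_zest(hmp, 8)))
  expect_lt(abs(mean(est) - 8), 1)
  expect_lte(mean(abs(est - 8)), 2)
})

test_that("mean estimate is non-decreasing in the true threshold", {
  hmp <- iowa_hmp()
  set.seed(31)
  truths <- seq(0, 16, by = 2)
  means <- vapply(truths, function(t) {
    mean(replicate(60, zest_estimate(run_single_zest(hmp, t))))
  }, numeric(1))
  expect_true(all(diff(means) > -0.3))
  expect_true(all(diff(means)[2:6] > 0))
})

test_that("far out-of-range thresholds floor or ceiling almost surely", {
  hmp <- iowa_hmp()
  set.seed(77)
  low <- replicate(100, zest_estimate(run_single_zest(hmp, -4)))
  expect_gte(mean(low == 0), 0.95)
  hi <- replicate(100, zest_estimate(run_single_zest(
    hmp, dynamic_range(hmp) + 3)))
  expect_gte(mean(hi == dynamic_range(hmp)), 0.95)
})

test_that("a full exam respects presentation bounds and the device range", {
  hmp <- iowa_hmp()
  set.seed(2)
  obs <- psychometric_observer(make_true_field("STGD"))
  exam <- run_exam(hmp, obs)
  expect_equal(nrow(exam), 68)
  expect_true(all(exam$n_presentations >= 1 & exam$n_presentations <= 12))
  expect_true(sum(exam$n_presentations) >= 68 &&
                sum(exam$n_presentations) <= 816)
  expect_true(all(exam$sensitivity_db >= 0 &
                    exam$sensitivity_db <= dynamic_range(hmp)))
  expect_equal(exam$device[1], "iowa_hmp")
  # reproducibility from the seed
  set.seed(2)
  obs2 <- psychometric_observer(make_true_field("STGD"))
  exam2 <- run_exam(hmp, obs2)
  expect_identical(exam, exam2)
})

test_that("a blind eye measures exactly 0 dB everywhere", {
  hmp <- iowa_hmp()
  tf <- make_true_field("normal", jitter_sd = 0)
  tf$true_db <- -Inf
  obs <- psychometric_observer(tf, fp_rate = 0, fn_rate = 0)
  set.seed(3)
  exam <- run_exam(hmp, obs)
  expect_true(all(exam$sensitivity_db == 0))
})

test_that("exams convert shared truths onto each device's own scale", {
  # noiseless normal observer: HMP clamps centrally at its ceiling while the
  # projection device keeps resolving higher sensitivities
  set.seed(4)
  obs <- psychometric_observer(make_true_field("normal", jitter_sd = 0),
                               slope_sd = 0.1, fp_rate = 0, fn_rate = 0)
  hmp_exam <- run_exam(iowa_hmp(), obs)
  oct_exam <- run_exam(octopus900(), obs)
  e <- sqrt(hmp_exam$x_deg^2 + hmp_exam$y_deg^2)
  central <- e < 4
  expect_gte(mean(hmp_exam$sensitivity_db[central] >
                    dynamic_range(iowa_hmp()) - 0.75), 0.9)
  expect_gt(mean(oct_exam$sensitivity_db[central]),
            dynamic_range(iowa_hmp()) + 14)
})

test_that("simulate_study produces paired per-device measurements", {
  sim <- simulate_study(cohort_config(1, 0, 1, 0), seed = 9)
  expect_equal(nrow(sim$truths), 4 * 68)
  expect_equal(nrow(sim$measured), 2 * 4 * 68)
  expect_setequal(unique(sim$measured$device), c("octopus900", "iowa_hmp"))
  sim2 <- simulate_study(cohort_config(1, 0, 1, 0), seed = 9)
  expect_identical(sim$measured, sim2$measured)
})
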