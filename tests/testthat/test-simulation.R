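test_that("simulated trials respect the design's fixed sample sizes", {
  d <- paper_design(2)
  trial <- simulate_trial(d, mu = c(0, 1), scheme = "bar", seed = 17)
  counts <- dplyr::count(trial$data, block, arm)
  # experimental totals: 5 per arm burn-in + 3 blocks of 40 = 130
  expect_equal(sum(counts$n[counts$arm > 0]), 130)
  expect_equal(sum(counts$n[counts$arm == 0]), 65)
  # control per block and burn-in counts are fixed by design
  expect_equal(counts$n[counts$arm == 0], c(5, 20, 20, 20))
  expect_equal(counts$n[counts$block == 0 & counts$arm > 0], c(5, 5))
  # every experimental arm appears in every block
  expect_true(all(table(trial$data$block[trial$data$arm > 0],
                        trial$data$arm[trial$data$arm > 0]) >= 1))
})

test_that("identical seeds reproduce the trial bit for bit", {
  d <- small_design(2)
  a <- simulate_trial(d, mu = c(0, 0.5), scheme = "inflator", seed = 23)
  b <- simulate_trial(d, mu = c(0, 0.5), scheme = "inflator", seed = 23)
  expect_identical(a$data, b$data)
  expect_identical(a$aux$counts, b$aux$counts)
})

test_that("vectorized engine reproduces the per-patient reference path", {
  d <- paper_design(2)
  set.seed(61)
  for (sch in c("bar", "inflator", "fixed")) {
    trial <- simulate_trial(d, mu = c(0, 1), scheme = sch)
    adj <- adjusted_z_test(trial$data, d, trial$aux)
    nav <- naive_z_test(trial$data, d)
    run <- run_from_trial(trial)
    for (k in 1:2) {
      pool <- blockrar:::mc_pool(run, k)
      st <- blockrar:::mc_adjusted_stat(pool, run$ctrl_mean, run$n0,
                                        run$sigma2)
      expect_equal(st$statistic, adj$statistic[k], tolerance = 1e-10)
      expect_equal(st$v_sum, adj$v_sum[k], tolerance = 1e-10)
      zn <- blockrar:::mc_naive_stat(pool, run$ctrl_mean, run$n0,
                                     run$sigma2)
      expect_equal(zn, nav$statistic[k], tolerance = 1e-10)
    }
  }
})

test_that("operating characteristics summarise all four methods", {
  d <- small_design(2)
  oc <- operating_characteristics(d, mu = c(0, 1), scheme = "bar",
                                  n_reps = 400, seed = 41)
  expect_setequal(oc$method, c("new_closed_z", "naive_closed_z",
                               "new_holm", "naive_holm"))
  expect_true(all(oc$error >= 0 & oc$error <= 100))
  expect_true(all(oc$power >= 0 & oc$power <= 100))
  expect_equal(oc$error_se,
               sqrt(oc$error / 100 * (1 - oc$error / 100) / 400) * 100)
  # same master seed, same summary
  oc2 <- operating_characteristics(d, mu = c(0, 1), scheme = "bar",
                                   n_reps = 400, seed = 41)
  expect_identical(tibble::as_tibble(oc), tibble::as_tibble(oc2))
})

test_that("error and power columns follow the true/false null split", {
  d <- small_design(2)
  all_null <- operating_characteristics(d, mu = c(0, 0), scheme = "fixed",
                                        n_reps = 200, seed = 42)
  expect_true(all(is.na(all_null$power)))
  expect_true(all(!is.na(all_null$error)))
  none_null <- operating_characteristics(d, mu = c(1, 1), scheme = "fixed",
                                         n_reps = 200, seed = 43)
  expect_true(all(is.na(none_null$error)))
  expect_true(all(!is.na(none_null$power)))
})

test_that("alpha = 0 rejects nothing", {
  d <- small_design(2)
  oc <- operating_characteristics(d, mu = c(0, 5), scheme = "bar",
                                  n_reps = 200, seed = 44, alpha = 0)
  expect_true(all(oc$error == 0))
  expect_true(all(oc$power == 0))
})

test_that("kept attributes expose per-replicate statistics and weights", {
  d <- small_design(2)
  oc <- operating_characteristics(d, mu = c(0, 0), scheme = "inflator",
                                  n_reps = 300, seed = 45,
                                  keep = c("statistics", "min_weight"))
  st <- attr(oc, "statistics")
  expect_equal(dim(st$adjusted), c(300, 2))
  expect_equal(dim(st$naive), c(300, 2))
  expect_length(attr(oc, "min_weight"), 300)
  expect_true(all(attr(oc, "min_weight") > 0))
})

test_that("the case study matches the published trial's sample sizes", {
  cs <- case_study(seed = 7)
  counts <- dplyr::count(cs$trial$data, arm)
  expect_equal(counts$n[counts$arm == 0], 31)
  expect_equal(sum(counts$n[counts$arm > 0]), 61)
  expect_setequal(cs$tests$method, c("z-test", "adjusted"))
  # effect sizes of ~14 standard errors: p-values are tiny in any run
  expect_true(all(cs$tests$p.value < 0.001))
})
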