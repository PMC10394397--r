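test_that("max-z closure applies Bonferroni quantiles per subset", {
  ct <- closed_test_holm(c(3, 0), alpha = 0.05, shortcut = FALSE)
  # {1,2}: max = 3 >= qnorm(0.975); {1}: 3 >= qnorm(0.95); {2}: 0 < qnorm(0.95)
  expect_equal(ct$subsets$rejected, c(TRUE, FALSE, TRUE))
  expect_equal(ct$decisions$rejected, c(TRUE, FALSE))

  none <- closed_test_holm(c(1.0, 1.2, 0.5), alpha = 0.05, shortcut = FALSE)
  expect_false(any(none$decisions$rejected))
})

test_that("explicit closure and the Holm shortcut agree on random inputs", {
  set.seed(314)
  for (i in 1:1000) {
    K <- sample(2:5, 1)
    stats <- rnorm(K, mean = 1, sd = 1.5)
    full <- closed_test_holm(stats, alpha = 0.05, shortcut = FALSE)
    shortcut <- closed_test_holm(stats, alpha = 0.05, shortcut = TRUE)
    expect_identical(full$decisions$rejected, shortcut$decisions$rejected)
  }
})

test_that("non-finite statistics are refused", {
  expect_error(closed_test_holm(c(1, NA)), "finite")
  expect_error(closed_test_holm(c(1, Inf)), "finite")
})

test_that("closed pooled z-test degenerates to the single-arm test for K=1", {
  tt <- trivial_trial(small_design(1), seed = 12)
  ct <- closed_test_pooled_z(tt$data, tt$design, tt$aux)
  adj <- adjusted_z_test(tt$data, tt$design, tt$aux)
  expect_equal(ct$decisions$statistic, adj$statistic)
  expect_equal(ct$decisions$rejected,
               adj$statistic >= qnorm(0.95))
})

test_that("without adaptation the closed pooled z-test is the classical
           closed z-test", {
  tt <- trivial_trial(small_design(2), seed = 13)
  ct <- closed_test_pooled_z(tt$data, tt$design, tt$aux)
  nv <- closed_test_pooled_z(tt$data, tt$design, method = "naive")
  # adjusted and naive pooled statistics coincide subset by subset
  expect_equal(ct$subsets$statistic, nv$subsets$statistic,
               tolerance = 1e-12)
  # and the pooled statistic is plain two-sample arithmetic
  cells <- dplyr::summarise(dplyr::group_by(tt$data, arm),
                            n = dplyr::n(), m = mean(response),
                            .groups = "drop")
  x0 <- cells$m[cells$arm == 0]
  n0 <- cells$n[cells$arm == 0]
  pooled_n <- sum(cells$n[cells$arm > 0])
  pooled_mean <- sum(cells$n[cells$arm > 0] * cells$m[cells$arm > 0]) /
    pooled_n
  z12 <- (pooled_mean - x0) / sqrt(1 / pooled_n + 1 / n0)
  expect_equal(ct$subsets$statistic[ct$subsets$subset == "1,2"], z12,
               tolerance = 1e-12)
})

test_that("closure requires every containing intersection to fall", {
  d <- small_design(2)
  trial <- simulate_trial(d, mu = c(3, 3), scheme = "fixed", seed = 3)
  ct <- closed_test_pooled_z(trial$data, d, trial$aux)
  for (k in 1:2) {
    containing <- ct$subsets$rejected[grepl(as.character(k),
                                            ct$subsets$subset)]
    expect_equal(ct$decisions$rejected[k], all(containing))
  }
  expect_error(closed_test_pooled_z(trial$data, d, method = "adjusted"),
               "aux")
})

test_that("spending plans validate levels and looks", {
  plan <- spending_plan(c(0.01, 0.04), looks = c(1, 3))
  expect_equal(plan$alpha, 0.05)
  expect_error(spending_plan(c(0.01, -0.01), looks = c(1, 2)),
               "non-negative")
  expect_error(spending_plan(c(0.01, 0.04), looks = c(2, 2)), "increasing")
  expect_error(spending_plan(0.05, looks = c(1, 2)), "same length")
})

test_that("the monitor rejects at the first boundary crossing only", {
  plan <- spending_plan(c(0.01, 0.04), looks = c(1, 2))
  mon <- alpha_spending_monitor(plan, c(2.0, 1.8))
  # look 1: 2.0 < qnorm(0.99) = 2.326 -> continue
  expect_false(mon$reject[1])
  # look 2: 1.8 >= qnorm(0.96) = 1.751 -> reject
  expect_true(mon$reject[2])
  expect_equal(mon$critical, qnorm(c(0.99, 0.96)), tolerance = 1e-12)
  expect_equal(mon$stopped, c(FALSE, TRUE))

  silent <- alpha_spending_monitor(plan, c(0, 0))
  expect_false(any(silent$reject))
})

test_that("unplanned looks are refused", {
  plan <- spending_plan(c(0.025, 0.025), looks = c(1, 3))
  expect_error(alpha_spending_monitor(plan, c(1, 1), looks = c(1, 2)),
               "pre-specified")
  expect_error(alpha_spending_monitor(plan, c(1, 1, 1)), "per planned look")
})
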