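test_that("no adaptation collapses the weights to the auxiliary total", {
  tr <- compute_weight_trace(c(4, 4), c(4, 4), burn_in = 2)
  expect_equal(tr$w, rep(10, 3))
  expect_equal(attr(tr, "v_sum"), 1)
  tr3 <- compute_weight_trace(c(40, 40, 40), c(40, 40, 40), burn_in = 5)
  expect_equal(tr3$w, rep(125, 4))
  expect_equal(tr3$v, c(5, 40, 40, 40) / 125)
})

test_that("weights match the worked two-block example", {
  tr <- compute_weight_trace(c(4, 4), c(6, 3), burn_in = 2)
  expect_equal(tr$w[1], 10)
  expect_equal(tr$w[2], 10 * sqrt(10 / 8), tolerance = 1e-12)
  expect_equal(tr$w[3], tr$w[2] * sqrt(3 / 4), tolerance = 1e-12)
  expect_equal(tr$v, c(0.2, 0.5366563, 0.3098387), tolerance = 1e-6)
})

test_that("closed form agrees with a numeric root-finder and telescopes", {
  set.seed(31)
  for (i in 1:100) {
    B <- sample(1:5, 1)
    aux <- sample(1:30, B, replace = TRUE)
    realized <- sample(1:30, B, replace = TRUE)
    b <- sample(1:8, 1)
    tr <- compute_weight_trace(aux, realized, burn_in = b)
    expect_equal(tr$w, uniroot_weights(aux, realized, b), tolerance = 1e-10)
    # telescoping variance identity, and the final-block variance match
    m <- c(tail_sums(aux), 0)
    w <- tr$w
    for (j in seq_len(B)) {
      lhs <- (realized[j] + m[j + 1]) / w[j + 1]^2
      expect_equal(lhs, m[j] / w[j]^2, tolerance = 1e-10)
    }
    # weights increase exactly when the realized block outgrew the plan
    expect_equal(w[-1] > w[-(B + 1)], realized > aux)
    expect_true(all(w > 0))
  }
})

test_that("the linear update variant breaks the variance matching", {
  aux <- c(4, 4)
  realized <- c(6, 3)
  tr <- compute_weight_trace(aux, realized, burn_in = 2, update = "linear")
  m <- c(tail_sums(aux), 0)
  viol <- abs((realized[1] + m[2]) / tr$w[2]^2 - m[1] / tr$w[1]^2)
  expect_gt(viol, 1e-3)
})

test_that("nonpositive counts are rejected with block and arm named", {
  expect_error(compute_weight_trace(c(4, 0), c(4, 4), 2, arm = 2),
               "block 2, arm 2")
  expect_error(compute_weight_trace(c(4, 4), c(0, 4), 2), "block 1")
  expect_error(compute_weight_trace(c(4, 4), c(4, 4), 0), "burn-in")
})

test_that("adjusted test equals the standard z-test without adaptation", {
  for (K in 1:3) {
    tt <- trivial_trial(small_design(K), seed = K)
    adj <- adjusted_z_test(tt$data, tt$design, tt$aux)
    nav <- naive_z_test(tt$data, tt$design)
    expect_equal(adj$statistic, nav$statistic, tolerance = 1e-12)
    expect_equal(adj$v_sum, rep(1, K), tolerance = 1e-12)
  }
})

test_that("identically zero responses give T = 0 and p = 0.5", {
  tt <- trivial_trial(small_design(2), seed = 4)
  dat <- dplyr::mutate(tt$data, response = 0)
  adj <- adjusted_z_test(dat, tt$design, tt$aux)
  expect_equal(adj$statistic, c(0, 0))
  expect_equal(adj$p.value, c(0.5, 0.5))
})

test_that("adjusted test validates data against design and auxiliary", {
  tt <- trivial_trial(small_design(2), seed = 5)
  expect_error(
    adjusted_z_test(dplyr::filter(tt$data, !(arm == 1 & block == 1)),
                    tt$design, tt$aux),
    "arm 1 has no patients in block 1"
  )
  drop_ctrl <- tt$data[-which(tt$data$arm == 0 & tt$data$block == 2)[1], ]
  expect_error(adjusted_z_test(drop_ctrl, tt$design, tt$aux),
               "control counts")
  expect_error(adjusted_z_test(tt$data, tt$design, tt$aux, sigma2 = 0),
               "sigma2")
  wrong_aux <- generate_auxiliary_design(small_design(3), seed = 1)
  expect_error(adjusted_z_test(tt$data, tt$design, wrong_aux), "dimensions")
})

test_that("naive z-statistic is plain arithmetic on realized totals", {
  d <- trial_design(K = 1, burn_in = 10, block_sizes = 40,
                    control_block_sizes = 40, control_burn_in = 10)
  dat <- tibble::tibble(
    block = c(rep(0L, 20), rep(1L, 80)),
    arm = c(rep(0:1, each = 10), rep(0:1, each = 40)),
    response = 0
  )
  dat$response <- ifelse(dat$arm == 1, 1, 0)
  nav <- naive_z_test(dat, d)
  expect_equal(nav$statistic, 1 / sqrt(2 / 50))
  expect_equal(nav$p.value, pnorm(5, lower.tail = FALSE))
})

test_that("pooled variance matches hand computation and handles edge cases", {
  dat <- tibble::tibble(
    block = 0L,
    arm = rep(c(1L, 2L, 0L), each = 2),
    response = c(0, 2, 1, 3, -1, 1)
  )
  pv <- pooled_block_variance(dat, K = 2)
  expect_equal(pv$sigma2_block, 2)
  expect_equal(pv$df, 3L)

  const <- dplyr::mutate(dat, response = rep(c(5, 2, 7), each = 2))
  expect_equal(pooled_block_variance(const, K = 2)$sigma2_block, 0)

  tiny <- dat[c(1, 3, 5), ]
  expect_error(pooled_block_variance(tiny, K = 2), "degree")
})

test_that("pooled variance is unbiased under unequal arm means", {
  set.seed(77)
  n_blocks <- 1000
  est <- vapply(seq_len(n_blocks), function(i) {
    dat <- tibble::tibble(
      block = 0L,
      arm = rep(0:2, each = 5),
      response = rnorm(15, mean = rep(c(0, 1, 3), each = 5), sd = 1.5)
    )
    pooled_block_variance(dat, K = 2)$sigma2_block
  }, numeric(1))
  se <- sd(est) / sqrt(n_blocks)
  expect_lt(abs(mean(est) - 2.25), 3 * se)
})

test_that("estimated-variance mode uses the running pooled estimate", {
  tt <- trivial_trial(paper_design(2), seed = 9)
  adj <- adjusted_z_test(tt$data, tt$design, tt$aux, estimate = TRUE)
  pv <- pooled_block_variance(tt$data, 2)
  expect_equal(attr(adj, "sigma2"), pv$sigma2_cum[nrow(pv)])
  expect_true(all(is.finite(adj$statistic)))
  # ratio to the known-variance statistic is exactly sigma/sigma_hat
  known <- adjusted_z_test(tt$data, tt$design, tt$aux)
  expect_equal(adj$statistic * sqrt(attr(adj, "sigma2")), known$statistic)
})

test_that("tidy and glance summarise test objects", {
  tt <- trivial_trial(small_design(2), seed = 6)
  adj <- adjusted_z_test(tt$data, tt$design, tt$aux)
  td <- tidy(adj)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("arm", "statistic", "p.value", "v_sum", "n_realized",
                     "n_aux"))
  gl <- glance(adj)
  expect_equal(gl$arms, 2L)
  expect_equal(gl$method, "adjusted")
})
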