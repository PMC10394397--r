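#' Variance-matched weight trace for one arm
#'
#' Core of the adjusted test. For experimental arm \eqn{k}, let
#' \eqn{n_{j,k}} be the auxiliary-design count in block \eqn{j},
#' \eqn{\tilde n_{j,k}} the realized count,
#' \eqn{m_{j,k} = n_{j,k} + \dots + n_{B,k}} the auxiliary tail sums, and
#' \eqn{n_k} the auxiliary total. The weights are defined recursively by
#' matching, block by block, the conditional variance of the remaining
#' weighted sum under the realized design to its value under the auxiliary
#' design:
#' \deqn{w_0 = n_k, \quad
#'   w_j = w_{j-1}\sqrt{\frac{\tilde n_{j,k} + m_{j+1,k}}
#'                            {n_{j,k} + m_{j+1,k}}} \ (j < B), \quad
#'   w_B = w_{B-1}\sqrt{\tilde n_{B,k} / n_{B,k}}.}
#' Each \eqn{w_j} is the unique positive solution of
#' \eqn{(\tilde n_{j,k} + m_{j+1,k})/w_j^2 = (n_{j,k} + m_{j+1,k})/w_{j-1}^2}
#' (with \eqn{m_{B+1,k} = 0}), so weights are strictly positive by
#' construction. The contribution coefficients are
#' \eqn{v_j = \tilde n_{j,k}/w_j} with \eqn{\tilde n_{0,k} = n_{0,k}}; when
#' the realized counts equal the auxiliary counts, \eqn{w_j = n_k} for all
#' \eqn{j} and \eqn{\sum_j v_j = 1}.
#'
#' @param aux_counts Auxiliary per-block counts \eqn{n_{1,k},\dots,n_{B,k}}
#'   (all >= 1).
#' @param realized_counts Realized per-block counts
#'   \eqn{\tilde n_{1,k},\dots,\tilde n_{B,k}} (all >= 1, same length).
#' @param burn_in Burn-in count \eqn{n_{0,k}} (>= 1).
#' @param update `"variance-matched"` (the method; default) or `"linear"`,
#'   an internal switch that applies the ratio without the square root.
#'   The linear form does not preserve the conditional variances and is kept
#'   only so that tests can demonstrate the difference.
#' @param arm Optional arm label used in error messages.
#' @return A tibble of class `weight_trace` with columns `block` (0..B),
#'   `aux_n`, `realized_n`, `w`, `v`, and attributes `n_k` (auxiliary total)
#'   and `v_sum`.
#' @examples
#' compute_weight_trace(aux_counts = c(4, 4), realized_counts = c(6, 3),
#'                      burn_in = 2)
#' @export
compute_weight_trace <- function(aux_counts, realized_counts, burn_in,
                                 update = c("variance-matched", "linear"),
                                 arm = NULL) {
  update <- match.arg(update)
  B <- length(aux_counts)
  if (length(realized_counts) != B) {
    abort("`aux_counts` and `realized_counts` must have the same length.")
  }
  lab <- if (is.null(arm)) "" else paste0(", arm ", arm)
  bad <- which(aux_counts < 1)
  if (length(bad)) {
    abort(paste0("nonpositive auxiliary count in block ", bad[1L], lab, "."))
  }
  bad <- which(realized_counts < 1)
  if (length(bad)) {
    abort(paste0("nonpositive realized count in block ", bad[1L], lab, "."))
  }
  if (burn_in < 1) abort(paste0("nonpositive burn-in count", lab, "."))

  n_k <- burn_in + sum(aux_counts)
  m <- c(tail_sums(aux_counts), 0) # m_j for j = 1..B, plus m_{B+1} = 0
  w <- numeric(B + 1L)
  w[1L] <- n_k
  for (j in seq_len(B)) {
    ratio <- (realized_counts[j] + m[j + 1L]) / (aux_counts[j] + m[j + 1L])
    w[j + 1L] <- w[j] * switch(update,
      "variance-matched" = sqrt(ratio),
      "linear" = ratio
    )
  }
  v <- c(burn_in, realized_counts) / w
  out <- tibble::tibble(
    block = 0:B,
    aux_n = c(burn_in, as.numeric(aux_counts)),
    realized_n = c(burn_in, as.numeric(realized_counts)),
    w = w,
    v = v
  )
  attr(out, "n_k") <- n_k
  attr(out, "v_sum") <- sum(v)
  class(out) <- c("weight_trace", class(out))
  out
}

# Adjusted statistic for one (possibly pooled) experimental arm, from
# sufficient statistics. `means` has length B + 1: block-0 (burn-in) mean
# first, then block 1..B means.
adjusted_core <- function(aux_counts, realized_counts, burn_in, means,
                          control_mean, n0, sigma2,
                          update = "variance-matched") {
  trace <- compute_weight_trace(aux_counts, realized_counts, burn_in,
                                update = update)
  n_k <- attr(trace, "n_k")
  v_sum <- attr(trace, "v_sum")
  u_tilde <- sum(trace$v * means)
  u_star <- u_tilde - v_sum * control_mean
  sd_star <- sqrt(sigma2) * sqrt(1 / n_k + v_sum^2 / n0)
  t_stat <- u_star / sd_star
  list(
    statistic = t_stat,
    p.value = pnorm(t_stat, lower.tail = FALSE),
    u_tilde = u_tilde,
    u_star = u_star,
    sd_star = sd_star,
    v_sum = v_sum,
    trace = trace
  )
}

# Per-(block, arm) counts, sums and means from per-patient records.
# Validates the data against the design and auxiliary burn-in.
block_summaries <- function(data, design) {
  required <- c("block", "arm", "response")
  if (!all(required %in% names(data))) {
    abort("`data` needs columns block, arm, response.")
  }
  K <- design$K
  B <- design$B
  if (!all(data$block %in% 0:B)) abort("block indices must be in 0..B.")
  if (!all(data$arm %in% 0:K)) abort("arm labels must be in 0..K (0 = control).")
  cells <- dplyr::summarise(
    dplyr::group_by(data, .data$block, .data$arm),
    n = dplyr::n(), sum = sum(.data$response), .groups = "drop"
  )
  full <- tidyr::complete(cells,
    block = 0:B, arm = 0:K,
    fill = list(n = 0L, sum = 0)
  )
  miss <- dplyr::filter(full, .data$arm > 0L, .data$n == 0L)
  if (nrow(miss)) {
    abort(paste0("arm ", miss$arm[1L], " has no patients in block ",
                 miss$block[1L], "."))
  }
  ctrl <- dplyr::arrange(dplyr::filter(full, .data$arm == 0L), .data$block)
  expected_ctrl <- c(design$control_burn_in, design$control_block_sizes)
  if (!all(ctrl$n == expected_ctrl)) {
    abort("control counts per block do not match the design.")
  }
  burn <- dplyr::filter(full, .data$block == 0L, .data$arm > 0L)
  if (!all(burn$n == design$burn_in)) {
    abort("block-0 counts must equal the design burn-in for every arm.")
  }
  dplyr::mutate(full, mean = ifelse(.data$n > 0, .data$sum / .data$n, NA_real_))
}

check_aux <- function(aux, design) {
  stopifnot(inherits(aux, "aux_design"))
  if (nrow(aux$counts) != design$B || ncol(aux$counts) != design$K) {
    abort("auxiliary design dimensions do not match the trial design.")
  }
  if (!all(rowSums(aux$counts) == design$block_sizes)) {
    abort("auxiliary per-block totals do not match the design block sizes.")
  }
}

#' Variance-matched adjusted z-test for each experimental arm
#'
#' Computes, for each arm, the reweighted statistic
#' \deqn{\tilde T_k = \frac{\tilde U_k - (\sum_j v_j)\,\bar X_0(n_0)}
#'   {\sigma\sqrt{1/n_k + (\sum_j v_j)^2 / n_0}},}
#' where \eqn{\tilde U_k = \sum_{j=0}^B v_j \bar X_k(\tilde n_{j,k})} with
#' the weights of [compute_weight_trace()]. Under \eqn{H_k: \mu_k = \mu_0},
#' \eqn{\tilde T_k} is exactly standard normal when \eqn{\sigma^2} is known,
#' regardless of how the response-adaptive rule redistributed patients —
#' this is the property that restores type I error control. When the
#' realized allocations equal the auxiliary design the statistic reduces to
#' the usual two-sample z-statistic.
#'
#' @param data Per-patient tibble with columns `block` (0 = burn-in), `arm`
#'   (0 = control), `response`.
#' @param design A [trial_design()].
#' @param aux The pre-specified [auxiliary_design()] /
#'   [generate_auxiliary_design()] the trial is compared against.
#' @param sigma2 Response variance; defaults to the design's (known-variance
#'   mode). Pass `estimate = TRUE` to use the pooled estimate instead, in
#'   which case normality holds only asymptotically.
#' @param estimate Logical; estimate `sigma2` via [pooled_block_variance()]?
#' @return A `rar_test` object: tibble with one row per arm and columns
#'   `arm`, `statistic`, `p.value`, `v_sum`, `n_realized`, `n_aux`, plus a
#'   list-column `weights` of per-arm weight traces. Attributes record the
#'   method and the variance used.
#' @seealso [naive_z_test()], [closed_test_pooled_z()], [closed_test_holm()]
#' @export
adjusted_z_test <- function(data, design, aux, sigma2 = design$sigma2,
                            estimate = FALSE) {
  check_aux(aux, design)
  cells <- block_summaries(data, design)
  if (isTRUE(estimate)) {
    pv <- pooled_block_variance(data, design$K)
    sigma2 <- pv$sigma2_cum[nrow(pv)]
  }
  if (sigma2 <= 0) abort("`sigma2` must be positive.")
  ctrl <- dplyr::filter(cells, .data$arm == 0L)
  control_mean <- sum(ctrl$sum) / sum(ctrl$n)
  rows <- purrr::map(seq_len(design$K), function(k) {
    ac <- dplyr::arrange(dplyr::filter(cells, .data$arm == k), .data$block)
    fit <- adjusted_core(
      aux_counts = aux$counts[, k],
      realized_counts = ac$n[-1L],
      burn_in = aux$burn_in[k],
      means = ac$mean,
      control_mean = control_mean,
      n0 = design$n0,
      sigma2 = sigma2
    )
    tibble::tibble(
      arm = k,
      statistic = fit$statistic,
      p.value = fit$p.value,
      v_sum = fit$v_sum,
      n_realized = sum(ac$n),
      n_aux = aux$totals[k],
      weights = list(fit$trace)
    )
  })
  new_rar_test(dplyr::bind_rows(rows), method = "adjusted",
               sigma2 = sigma2, estimated = isTRUE(estimate),
               alpha = design$alpha)
}

#' Naive z-test treating realized sample sizes as fixed
#'
#' The standard one-sided z-statistic
#' \eqn{(\bar X_k - \bar X_0)/\sqrt{\sigma^2/\tilde n_k + \sigma^2/n_0}}
#' computed with the realized (response-adaptive) sample sizes as if they had
#' been fixed in advance. Included as the comparator whose type I error rate
#' can be inflated by adversarial adaptive allocation.
#'
#' @inheritParams adjusted_z_test
#' @return A `rar_test` tibble (one row per arm), as in [adjusted_z_test()]
#'   but without weight traces.
#' @export
naive_z_test <- function(data, design, sigma2 = design$sigma2) {
  cells <- block_summaries(data, design)
  ctrl <- dplyr::filter(cells, .data$arm == 0L)
  n0 <- sum(ctrl$n)
  control_mean <- sum(ctrl$sum) / sum(ctrl$n)
  per_arm <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(cells, .data$arm > 0L), .data$arm),
    n = sum(.data$n), mean = sum(.data$sum) / sum(.data$n), .groups = "drop"
  )
  z <- (per_arm$mean - control_mean) /
    sqrt(sigma2 / per_arm$n + sigma2 / n0)
  new_rar_test(
    tibble::tibble(
      arm = per_arm$arm,
      statistic = z,
      p.value = pnorm(z, lower.tail = FALSE),
      v_sum = NA_real_,
      n_realized = per_arm$n,
      n_aux = NA_integer_,
      weights = list(NULL)
    ),
    method = "naive", sigma2 = sigma2, estimated = FALSE,
    alpha = design$alpha
  )
}

#' Interim adjusted statistic at a pre-specified block
#'
#' Treats block `S` as the final block: auxiliary totals and tail sums are
#' truncated at `S`, the final-block weight rule is applied to block `S`,
#' and the control mean uses only the control patients of blocks `0..S`
#' (whose number is fixed by design, so the interim statistic is again
#' exactly standard normal under the null). Interim looks must be
#' pre-specified — testing at a data-dependent time invalidates the
#' guarantee — and are enforced by [alpha_spending_monitor()].
#'
#' @inheritParams adjusted_z_test
#' @param S Interim block index, `1 <= S < B`.
#' @return A `rar_test` tibble as in [adjusted_z_test()], with attribute
#'   `S`.
#' @export
interim_adjusted_z_test <- function(data, design, aux, S,
                                    sigma2 = design$sigma2) {
  if (length(S) != 1L || S < 1L || S >= design$B) {
    abort("`S` must satisfy 1 <= S < B.")
  }
  check_aux(aux, design)
  trunc_design <- trial_design(
    K = design$K, burn_in = design$burn_in,
    block_sizes = design$block_sizes[seq_len(S)],
    control_block_sizes = design$control_block_sizes[seq_len(S)],
    alpha = design$alpha, sigma2 = design$sigma2,
    control_burn_in = design$control_burn_in
  )
  trunc_aux <- auxiliary_design(
    aux$counts[seq_len(S), , drop = FALSE], aux$burn_in
  )
  out <- adjusted_z_test(dplyr::filter(data, .data$block <= S),
                         trunc_design, trunc_aux, sigma2 = sigma2)
  attr(out, "S") <- S
  out
}

#' Pooled per-block variance estimate
#'
#' The usual pooled variance estimator computed separately in every block
#' \eqn{j} over all arms including the control,
#' \deqn{\hat\sigma^2_j = \frac{\sum_{k=0}^K \sum_i
#'   (x_{ijk} - \bar x_{jk})^2}{\sum_{k=0}^K \tilde n_{j,k} - K - 1},}
#' together with the running combined estimate that averages
#' \eqn{\hat\sigma^2_0, \dots, \hat\sigma^2_j} with equal weights
#' \eqn{1/(j+1)}. Each per-block estimate is independent of the block means,
#' so all are consistent under response-adaptive allocation.
#'
#' @param data Per-patient tibble (`block`, `arm`, `response`).
#' @param K Number of experimental arms.
#' @return Tibble with columns `block`, `df`, `sigma2_block`, `sigma2_cum`.
#' @export
pooled_block_variance <- function(data, K) {
  blocks <- sort(unique(data$block))
  per_block <- purrr::map(blocks, function(j) {
    d <- dplyr::filter(data, .data$block == j)
    stats <- dplyr::summarise(
      dplyr::group_by(d, .data$arm),
      ss = sum((.data$response - mean(.data$response))^2),
      n = dplyr::n(), .groups = "drop"
    )
    df <- sum(stats$n) - K - 1L
    if (df < 1L) {
      abort(paste0("block ", j, " has fewer than one degree of freedom."))
    }
    tibble::tibble(block = j, df = df, sigma2_block = sum(stats$ss) / df)
  })
  out <- dplyr::bind_rows(per_block)
  dplyr::mutate(out, sigma2_cum = cumsum(.data$sigma2_block) /
                  seq_along(.data$sigma2_block))
}

new_rar_test <- function(tbl, method, sigma2, estimated, alpha) {
  structure(
    tbl,
    class = c("rar_test", class(tbl)),
    method = method, sigma2 = sigma2, estimated = estimated, alpha = alpha
  )
}

#' @export
print.rar_test <- function(x, ...) {
  cat(switch(attr(x, "method"),
    adjusted = "Variance-matched adjusted z-test",
    naive = "Naive z-test (realized sample sizes treated as fixed)"
  ), "\n")
  if (isTRUE(attr(x, "estimated"))) {
    cat("  sigma2 estimated:", signif(attr(x, "sigma2"), 4),
        "(asymptotic normality)\n")
  }
  print(tibble::as_tibble(x)[setdiff(names(x), "weights")])
  invisible(x)
}

#' @export
tidy.rar_test <- function(x, ...) {
  tibble::as_tibble(x)[setdiff(names(x), "weights")]
}

#' @export
glance.rar_test <- function(x, ...) {
  tibble::tibble(
    method = attr(x, "method"),
    arms = nrow(x),
    sigma2 = attr(x, "sigma2"),
    alpha = attr(x, "alpha"),
    min_p = min(x$p.value)
  )
}
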