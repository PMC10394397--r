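# Vectorized Monte-Carlo engine.
#
# All test statistics in this package depend on the data only through the
# per-block, per-arm sample counts and response sums (plus the control
# totals), so whole batches of trials are simulated on sufficient
# statistics: allocation labels are drawn to get exact counts (including
# the minimum-one guard), and each cell's response sum is drawn directly
# as N(n * mu, n * sigma2). This is distribution-identical to per-patient
# simulation (see simulate_trial) and is cross-checked against it in the
# test suite.

# Counts for one block across R replicates. `probs` is NULL for uniform
# allocation or an R x K matrix of per-replicate probabilities.
mc_alloc_counts <- function(R, size, K, probs = NULL) {
  if (K == 1L) return(matrix(as.integer(size), R, 1L))
  U <- matrix(runif(R * size), R, size)
  lab <- matrix(1L, R, size)
  if (is.null(probs)) {
    thr <- cumsum(rep(1 / K, K - 1L))
    for (k in seq_len(K - 1L)) lab <- lab + (U > thr[k])
  } else {
    thr <- probs[, 1L]
    lab <- lab + (U > thr)
    if (K > 2L) {
      for (k in 2:(K - 1L)) {
        thr <- thr + probs[, k]
        lab <- lab + (U > thr)
      }
    }
  }
  counts <- matrix(0L, R, K)
  for (k in seq_len(K)) counts[, k] <- rowSums(lab == k)
  bad <- which(rowSums(counts == 0L) > 0L)
  for (r in bad) counts[r, ] <- tabulate(guard_min_one(lab[r, ], K), K)
  counts
}

# Error-inflator counts for one block across R replicates.
mc_inflator_counts <- function(R, size, K, crossed, favored_arm) {
  counts <- matrix(1L, R, K)
  counts[, favored_arm] <- as.integer(size - (K - 1L))
  idx <- which(crossed)
  if (length(idx)) {
    counts[idx, favored_arm] <- 1L
    others <- setdiff(seq_len(K), favored_arm)
    if (K == 2L) {
      counts[idx, others] <- as.integer(size - 1L)
    } else {
      counts[idx, others] <- mc_alloc_counts(length(idx), size - 1L, K - 1L)
    }
  }
  counts
}

# Simulate R replicates of a whole trial; returns sufficient statistics.
mc_run <- function(design, mu, mu0, scheme, R, gamma, threshold,
                   favored_arm) {
  K <- design$K
  B <- design$B
  s2 <- design$sigma2
  b <- design$burn_in
  bs <- design$block_sizes
  cs <- design$control_block_sizes

  burn_sums <- matrix(
    rnorm(R * K, mean = rep(b * mu, each = R), sd = sqrt(b * s2)), R, K
  )
  ctrl_sum <- rnorm(R, design$control_burn_in * mu0,
                    sqrt(design$control_burn_in * s2))
  ctrl_n <- design$control_burn_in
  cum_counts <- matrix(as.numeric(b), R, K)
  cum_sums <- burn_sums
  aux_counts <- array(0L, c(R, K, B))
  rel_counts <- array(0L, c(R, K, B))
  rel_sums <- array(0, c(R, K, B))
  crossed <- rep(FALSE, R)

  for (j in seq_len(B)) {
    aux_counts[, , j] <- mc_alloc_counts(R, bs[j], K)
    cnt <- switch(scheme,
      bar = {
        post <- pnorm((cum_sums / cum_counts - ctrl_sum / ctrl_n) /
                        sqrt(s2 / cum_counts + s2 / ctrl_n))
        pw <- post^gamma
        mc_alloc_counts(R, bs[j], K, probs = pw / rowSums(pw))
      },
      inflator = {
        crossed <- update_crossed(
          crossed, cum_sums[, favored_arm] / cum_counts[, favored_arm],
          threshold
        )
        mc_inflator_counts(R, bs[j], K, crossed, favored_arm)
      },
      fixed = mc_alloc_counts(R, bs[j], K)
    )
    rel_counts[, , j] <- cnt
    sums <- matrix(
      rnorm(R * K, mean = as.vector(cnt) * rep(mu, each = R),
            sd = sqrt(as.vector(cnt) * s2)), R, K
    )
    rel_sums[, , j] <- sums
    cum_counts <- cum_counts + cnt
    cum_sums <- cum_sums + sums
    ctrl_sum <- ctrl_sum + rnorm(R, cs[j] * mu0, sqrt(cs[j] * s2))
    ctrl_n <- ctrl_n + cs[j]
  }
  list(
    aux_counts = aux_counts, rel_counts = rel_counts,
    burn_sums = burn_sums, rel_sums = rel_sums,
    ctrl_mean = ctrl_sum / ctrl_n, n0 = ctrl_n,
    burn_in = b, sigma2 = s2, B = B, K = K, R = R
  )
}

# Pool the sufficient statistics of the arms in subset `s` into R x B
# matrices (plus burn-in vectors).
mc_pool <- function(run, s) {
  B <- run$B
  R <- run$R
  A <- matrix(0, R, B)
  Nr <- matrix(0, R, B)
  Sm <- matrix(0, R, B)
  for (j in seq_len(B)) {
    A[, j] <- rowSums(run$aux_counts[, s, j, drop = FALSE], dims = 1L)
    Nr[, j] <- rowSums(run$rel_counts[, s, j, drop = FALSE], dims = 1L)
    Sm[, j] <- rowSums(run$rel_sums[, s, j, drop = FALSE], dims = 1L)
  }
  list(
    aux = A, realized = Nr, sums = Sm,
    burn_n = run$burn_in * length(s),
    burn_sum = rowSums(run$burn_sums[, s, drop = FALSE])
  )
}

# Vectorized adjusted statistic for a pooled (or single) arm.
mc_adjusted_stat <- function(pool, ctrl_mean, n0, sigma2) {
  A <- pool$aux
  Nr <- pool$realized
  B <- ncol(A)
  M <- A # tail sums m_j
  if (B > 1L) for (j in (B - 1L):1L) M[, j] <- M[, j] + M[, j + 1L]
  nk <- pool$burn_n + M[, 1L]
  w <- nk
  u <- pool$burn_sum / nk
  vsum <- pool$burn_n / nk
  wmin <- w
  for (j in seq_len(B)) {
    mnext <- if (j < B) M[, j + 1L] else 0
    w <- w * sqrt((Nr[, j] + mnext) / (A[, j] + mnext))
    u <- u + pool$sums[, j] / w
    vsum <- vsum + Nr[, j] / w
    wmin <- pmin(wmin, w)
  }
  t_stat <- (u - vsum * ctrl_mean) /
    (sqrt(sigma2) * sqrt(1 / nk + vsum^2 / n0))
  list(statistic = t_stat, v_sum = vsum, wmin = wmin)
}

mc_naive_stat <- function(pool, ctrl_mean, n0, sigma2) {
  n_tot <- pool$burn_n + rowSums(pool$realized)
  xbar <- (pool$burn_sum + rowSums(pool$sums)) / n_tot
  (xbar - ctrl_mean) / sqrt(sigma2 / n_tot + sigma2 / n0)
}

#' Operating characteristics of block-RAR analysis methods
#'
#' Simulates `n_reps` complete trials under one scenario and tabulates the
#' familywise error rate (probability of rejecting at least one true null,
#' i.e. an arm with \eqn{\mu_k = \mu_0}) and the disjunctive power
#' (probability of rejecting at least one false null) for four analysis
#' methods: the naive and variance-matched adjusted statistics, each
#' combined with the closed pooled z-test and with Bonferroni-Holm.
#'
#' Simulation runs on per-block sufficient statistics, vectorized across
#' replicates, so full 1e5-replicate tables take minutes; the path is
#' distribution-identical to [simulate_trial()] and cross-checked against
#' it in the package tests. A single master `seed` makes the whole run
#' reproducible.
#'
#' @inheritParams simulate_trial
#' @param n_reps Number of simulated trials (default 1e4).
#' @param alpha One-sided familywise level (defaults to the design's).
#' @param keep Character vector; `"statistics"` attaches the per-replicate
#'   per-arm adjusted and naive statistics, `"min_weight"` attaches each
#'   replicate's smallest weight over all arms, blocks and pooled subsets.
#' @return An `oc_summary` tibble with one row per method and columns
#'   `method`, `error`, `error_se`, `power`, `power_se` (all in percent;
#'   `NA` when a scenario has no true or no false nulls) and `n_reps`.
#'   Monte-Carlo standard errors are \eqn{\sqrt{p(1-p)/n}} on the percent
#'   scale.
#' @examples
#' d <- trial_design(K = 2)
#' operating_characteristics(d, mu = c(0, 0.5), scheme = "bar",
#'                           n_reps = 500, seed = 1)
#' @export
operating_characteristics <- function(design, mu,
                                      scheme = c("bar", "inflator", "fixed"),
                                      n_reps = 1e4, seed = NULL, mu0 = 0,
                                      gamma = 0.5, threshold = 0.5,
                                      favored_arm = 1L,
                                      alpha = design$alpha,
                                      keep = character()) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(design, "trial_design"))
  K <- design$K
  if (length(mu) != K) abort("`mu` must have length K.")
  if (n_reps < 1) abort("`n_reps` must be at least 1.")
  if (alpha < 0 || alpha >= 1) abort("`alpha` must be in [0, 1).")
  if (!is.null(seed)) set.seed(seed)

  run <- mc_run(design, mu, mu0, scheme, n_reps, gamma, threshold,
                favored_arm)
  subsets <- all_subsets(K)
  sizes <- lengths(subsets)
  pools <- purrr::map(subsets, ~ mc_pool(run, .x))
  adj <- purrr::map(pools, mc_adjusted_stat, ctrl_mean = run$ctrl_mean,
                    n0 = run$n0, sigma2 = run$sigma2)
  nav <- purrr::map(pools, mc_naive_stat, ctrl_mean = run$ctrl_mean,
                    n0 = run$n0, sigma2 = run$sigma2)
  t_adj <- purrr::map(adj, "statistic")
  singles <- match(as.list(seq_len(K)), subsets)

  crit_pooled <- qnorm(1 - alpha)
  crit_holm <- qnorm(1 - alpha / sizes)
  max_over <- function(stat_list, s) Reduce(pmax, stat_list[singles[s]])
  subset_rej <- list(
    new_closed_z = purrr::map(t_adj, ~ .x >= crit_pooled),
    naive_closed_z = purrr::map(nav, ~ .x >= crit_pooled),
    new_holm = purrr::map(seq_along(subsets), function(i) {
      max_over(t_adj, subsets[[i]]) >= crit_holm[i]
    }),
    naive_holm = purrr::map(seq_along(subsets), function(i) {
      max_over(nav, subsets[[i]]) >= crit_holm[i]
    })
  )
  elementary <- purrr::map(subset_rej, function(rej) {
    purrr::map(seq_len(K), function(k) {
      Reduce(`&`, rej[purrr::map_lgl(subsets, ~ k %in% .x)])
    })
  })

  true_null <- which(mu == mu0)
  false_null <- setdiff(seq_len(K), true_null)
  rate <- function(elem, arms) {
    if (length(arms) == 0L) return(c(NA_real_, NA_real_))
    p <- mean(Reduce(`|`, elem[arms]))
    c(100 * p, 100 * sqrt(p * (1 - p) / n_reps))
  }
  out <- dplyr::bind_rows(purrr::imap(elementary, function(elem, m) {
    e <- rate(elem, true_null)
    p <- rate(elem, false_null)
    tibble::tibble(method = m, error = e[1L], error_se = e[2L],
                   power = p[1L], power_se = p[2L], n_reps = n_reps)
  }))
  out <- structure(out, class = c("oc_summary", class(out)),
                   scenario = list(mu = mu, mu0 = mu0, scheme = scheme,
                                   gamma = gamma, threshold = threshold,
                                   alpha = alpha, seed = seed))
  if ("statistics" %in% keep) {
    attr(out, "statistics") <- list(
      adjusted = do.call(cbind, t_adj[singles]),
      naive = do.call(cbind, nav[singles])
    )
  }
  if ("min_weight" %in% keep) {
    attr(out, "min_weight") <- Reduce(pmin, purrr::map(adj, "wmin"))
  }
  out
}

#' @export
print.oc_summary <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat("Operating characteristics (", sc$scheme, " scheme, mu = ",
      paste(sc$mu, collapse = ", "), ", alpha = ", sc$alpha, ")\n", sep = "")
  print(tibble::as_tibble(x))
  invisible(x)
}

#' @export
tidy.oc_summary <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.oc_summary <- function(x, ...) {
  sc <- attr(x, "scenario")
  tibble::tibble(
    scheme = sc$scheme, mu = paste(sc$mu, collapse = ","),
    alpha = sc$alpha, n_reps = x$n_reps[1L]
  )
}
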