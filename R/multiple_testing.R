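#' Closed pooled z-test over all intersection hypotheses
#'
#' For every nonempty subset \eqn{\mathcal{K} \subseteq \{1,\dots,K\}} the
#' observations of the arms in \eqn{\mathcal{K}} are pooled, block by block,
#' into a single pseudo-arm (burn-in, auxiliary and realized counts summed;
#' responses concatenated) and tested against the control at level `alpha`
#' — with the variance-matched adjusted statistic (`method = "adjusted"`)
#' or the naive z-statistic (`method = "naive"`). The elementary hypothesis
#' \eqn{H_k: \mu_k = \mu_0} is rejected if and only if every intersection
#' containing \eqn{k} is rejected (closed testing), which controls the
#' familywise error rate strongly whenever each subset test is a valid
#' level-\eqn{\alpha} test.
#'
#' @inheritParams adjusted_z_test
#' @param alpha One-sided level for every intersection test; defaults to the
#'   design's.
#' @param method `"adjusted"` (requires `aux`) or `"naive"`.
#' @return A `closed_test` object: list with `subsets` (tibble: subset
#'   label, statistic, critical value, rejected) and `decisions` (tibble:
#'   arm, statistic, p.value, rejected).
#' @examples
#' d <- trial_design(K = 2, burn_in = 2, block_sizes = c(4, 4),
#'                   control_block_sizes = c(3, 3))
#' trial <- simulate_trial(d, mu = c(1, 1), scheme = "fixed", seed = 1)
#' closed_test_pooled_z(trial$data, d, trial$aux)
#' @export
closed_test_pooled_z <- function(data, design, aux = NULL,
                                 alpha = design$alpha,
                                 method = c("adjusted", "naive"),
                                 sigma2 = design$sigma2) {
  method <- match.arg(method)
  K <- design$K
  cells <- block_summaries(data, design)
  ctrl <- dplyr::filter(cells, .data$arm == 0L)
  control_mean <- sum(ctrl$sum) / sum(ctrl$n)
  n0 <- design$n0
  if (method == "adjusted") {
    if (is.null(aux)) abort("`aux` is required for the adjusted method.")
    check_aux(aux, design)
  }
  subsets <- all_subsets(K)
  crit <- qnorm(1 - alpha)
  stat_of <- function(s) {
    pooled <- dplyr::summarise(
      dplyr::group_by(
        dplyr::filter(cells, .data$arm %in% s), .data$block
      ),
      n = sum(.data$n), sum = sum(.data$sum), .groups = "drop"
    )
    pooled <- dplyr::arrange(pooled, .data$block)
    if (method == "adjusted") {
      adjusted_core(
        aux_counts = rowSums(aux$counts[, s, drop = FALSE]),
        realized_counts = pooled$n[-1L],
        burn_in = sum(aux$burn_in[s]),
        means = pooled$sum / pooled$n,
        control_mean = control_mean, n0 = n0, sigma2 = sigma2
      )$statistic
    } else {
      n_tot <- sum(pooled$n)
      (sum(pooled$sum) / n_tot - control_mean) /
        sqrt(sigma2 / n_tot + sigma2 / n0)
    }
  }
  stats <- purrr::map_dbl(subsets, stat_of)
  rejected <- stats >= crit
  elementary <- purrr::map_lgl(seq_len(K), function(k) {
    all(rejected[purrr::map_lgl(subsets, ~ k %in% .x)])
  })
  single <- match(as.list(seq_len(K)), subsets)
  new_closed_test(
    subsets = tibble::tibble(
      subset = purrr::map_chr(subsets, paste, collapse = ","),
      statistic = stats, critical = crit, rejected = rejected
    ),
    decisions = tibble::tibble(
      arm = seq_len(K),
      statistic = stats[single],
      p.value = pnorm(stats[single], lower.tail = FALSE),
      rejected = elementary
    ),
    method = paste0("closed-pooled-z-", method), alpha = alpha
  )
}

#' Closed max-z test and its Bonferroni-Holm shortcut
#'
#' Given per-arm statistics \eqn{\tilde T_1, \dots, \tilde T_K} (each
#' standard normal under its null), the intersection \eqn{H_\mathcal{K}} is
#' rejected when \eqn{\max_{k \in \mathcal{K}} \tilde T_k \ge
#' \Phi^{-1}(1 - \alpha/|\mathcal{K}|)}. The full closure of these
#' Bonferroni tests is equivalent to the Holm step-down procedure on the
#' one-sided p-values; both routes are implemented and agree exactly
#' (`shortcut = FALSE` enumerates all \eqn{2^K - 1} subsets, the default
#' uses the explicit closure for \eqn{K \le 10} and Holm beyond).
#'
#' @param statistics Numeric vector of per-arm z-scale statistics.
#' @param alpha One-sided familywise level.
#' @param shortcut `NULL` (auto), `TRUE` (Holm step-down), or `FALSE`
#'   (explicit closure).
#' @return A `closed_test` object as in [closed_test_pooled_z()] (the
#'   `subsets` component is `NULL` when the shortcut is used).
#' @examples
#' closed_test_holm(c(3, 0), alpha = 0.05)$decisions
#' @export
closed_test_holm <- function(statistics, alpha = 0.05, shortcut = NULL) {
  if (any(!is.finite(statistics))) abort("`statistics` must be finite.")
  K <- length(statistics)
  if (is.null(shortcut)) shortcut <- K > 10L
  p <- pnorm(statistics, lower.tail = FALSE)
  if (shortcut) {
    rejected <- holm_step_down(p, alpha)
    subsets_tbl <- NULL
  } else {
    subsets <- all_subsets(K)
    crit <- qnorm(1 - alpha / lengths(subsets))
    stats <- purrr::map_dbl(subsets, ~ max(statistics[.x]))
    rej <- stats >= crit
    rejected <- purrr::map_lgl(seq_len(K), function(k) {
      all(rej[purrr::map_lgl(subsets, ~ k %in% .x)])
    })
    subsets_tbl <- tibble::tibble(
      subset = purrr::map_chr(subsets, paste, collapse = ","),
      statistic = stats, critical = crit, rejected = rej
    )
  }
  new_closed_test(
    subsets = subsets_tbl,
    decisions = tibble::tibble(
      arm = seq_len(K), statistic = statistics, p.value = p,
      rejected = rejected
    ),
    method = "holm", alpha = alpha
  )
}

# Holm step-down on one-sided p-values at familywise level alpha.
holm_step_down <- function(p, alpha) {
  K <- length(p)
  ord <- order(p)
  thresh <- alpha / (K - seq_len(K) + 1L)
  below <- p[ord] <= thresh
  n_rej <- if (all(below)) K else (which.min(below) - 1L)
  rejected <- logical(K)
  if (n_rej > 0L) rejected[ord[seq_len(n_rej)]] <- TRUE
  rejected
}

all_subsets <- function(K) {
  unlist(
    purrr::map(seq_len(K), ~ utils::combn(K, .x, simplify = FALSE)),
    recursive = FALSE
  )
}

new_closed_test <- function(subsets, decisions, method, alpha) {
  structure(
    list(subsets = subsets, decisions = decisions, method = method,
         alpha = alpha),
    class = "closed_test"
  )
}

#' @export
print.closed_test <- function(x, ...) {
  cat("Closed test (", x$method, "), one-sided alpha = ", x$alpha, "\n",
      sep = "")
  print(x$decisions)
  invisible(x)
}

#' @export
tidy.closed_test <- function(x, ...) x$decisions

#' @export
glance.closed_test <- function(x, ...) {
  tibble::tibble(
    method = x$method, alpha = x$alpha,
    n_rejected = sum(x$decisions$rejected)
  )
}

#' Bonferroni alpha-spending plan for interim monitoring
#'
#' Splits the one-sided level \eqn{\alpha} over pre-specified looks (blocks)
#' \eqn{S_1 < \dots < S_L}, the last of which is the final block. Testing
#' \eqn{\tilde T(S_l) \ge \Phi^{-1}(1 - \alpha_l)} at each look controls the
#' overall level at \eqn{\sum_l \alpha_l = \alpha} by the Bonferroni
#' inequality; no sharper boundary is available because the correlation
#' between interim and final statistics depends on weights that are unknown
#' at the interim.
#'
#' @param levels Per-look spending levels \eqn{\alpha_l \ge 0}.
#' @param looks Strictly increasing block indices at which looks occur (the
#'   last is the final analysis).
#' @return A `spending_plan` object.
#' @examples
#' spending_plan(c(0.01, 0.04), looks = c(1, 3))
#' @export
spending_plan <- function(levels, looks) {
  if (length(levels) != length(looks)) {
    abort("`levels` and `looks` must have the same length.")
  }
  if (any(levels < 0)) abort("spending levels must be non-negative.")
  if (is.unsorted(looks, strictly = TRUE)) {
    abort("`looks` must be strictly increasing block indices.")
  }
  structure(
    list(levels = levels, looks = as.integer(looks), alpha = sum(levels)),
    class = "spending_plan"
  )
}

#' @export
print.spending_plan <- function(x, ...) {
  cat("Bonferroni alpha-spending plan, total alpha =", x$alpha, "\n")
  print(tibble::tibble(look = x$looks, level = x$levels))
  invisible(x)
}

#' Apply a spending plan to interim statistics
#'
#' @param plan A [spending_plan()].
#' @param statistics Named or plain numeric vector of the statistics
#'   \eqn{\tilde T(S_l)} at exactly the planned looks, in look order (use
#'   [interim_adjusted_z_test()] for interim looks and [adjusted_z_test()]
#'   for the final one). Supplying statistics for unplanned looks is
#'   refused: testing at data-dependent times breaks the error guarantee.
#' @param looks Block indices the statistics belong to; must equal
#'   `plan$looks`.
#' @return Tibble with one row per look: `look`, `level`, `statistic`,
#'   `critical`, `reject`, and `stopped` (`TRUE` from the first rejection
#'   onwards; later looks would not be performed).
#' @examples
#' plan <- spending_plan(c(0.01, 0.04), looks = c(1, 2))
#' alpha_spending_monitor(plan, c(2.0, 1.8))
#' @export
alpha_spending_monitor <- function(plan, statistics, looks = plan$looks) {
  stopifnot(inherits(plan, "spending_plan"))
  if (!identical(as.integer(looks), plan$looks)) {
    abort("statistics supplied for looks not in the plan; interim looks must be pre-specified.")
  }
  if (length(statistics) != length(plan$looks)) {
    abort("one statistic per planned look is required.")
  }
  critical <- qnorm(1 - plan$levels)
  reject <- statistics >= critical
  tibble::tibble(
    look = plan$looks, level = plan$levels,
    statistic = statistics, critical = critical, reject = reject,
    stopped = cumsum(reject) > 0L
  )
}
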