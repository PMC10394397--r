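#' Read per-patient trial records
#'
#' Reads a delimited text table with header `block,arm,response`: `block`
#' is 0 for the burn-in and 1..B for the adaptive blocks, `arm` is 0 for
#' control and 1..K for the experimental arms, `response` is the numeric
#' outcome.
#'
#' @param path Path to a CSV file.
#' @return Tibble with integer `block`, `arm` and double `response`.
#' @export
read_trial_data <- function(path) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  data <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("block", "arm", "response")
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    abort(paste0("trial data is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  dplyr::mutate(data[required],
                block = as.integer(.data$block),
                arm = as.integer(.data$arm),
                response = as.numeric(.data$response))
}

#' Read a design/scheme configuration file
#'
#' Reads a YAML configuration with keys `K`, `burn_in_per_arm`,
#' `aux_block_totals`, `control_block_sizes`, `alpha`, `sigma2`, `scheme`,
#' `gamma`, `seed` (plus optional `control_burn_in`, `threshold`,
#' `favored_arm`). The first five are required; `sigma2` defaults to 1,
#' `scheme` to `"bar"` and `gamma` to 0.5.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` object: list with `design` (a [trial_design()])
#'   and the scheme settings.
#' @export
read_design_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  required <- c("K", "burn_in_per_arm", "aux_block_totals",
                "control_block_sizes", "alpha")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    abort(paste0("config is missing required key(s): ",
                 paste(missing, collapse = ", ")))
  }
  design <- trial_design(
    K = cfg$K, burn_in = cfg$burn_in_per_arm,
    block_sizes = unlist(cfg$aux_block_totals),
    control_block_sizes = unlist(cfg$control_block_sizes),
    alpha = cfg$alpha, sigma2 = cfg$sigma2 %||% 1,
    control_burn_in = cfg$control_burn_in %||% cfg$burn_in_per_arm
  )
  scheme <- cfg$scheme %||% "bar"
  if (!scheme %in% c("bar", "inflator", "fixed")) {
    abort("config key `scheme` must be one of bar, inflator, fixed.")
  }
  structure(
    list(design = design, scheme = scheme, gamma = cfg$gamma %||% 0.5,
         threshold = cfg$threshold %||% 0.5,
         favored_arm = cfg$favored_arm %||% 1L, seed = cfg$seed),
    class = "run_config"
  )
}

#' Full analysis of one realized trial
#'
#' Runs the adjusted and naive per-arm tests plus both closed testing
#' procedures (pooled closed z-test and Bonferroni-Holm) on a realized
#' trial against its pre-specified auxiliary design.
#'
#' @inheritParams adjusted_z_test
#' @param alpha One-sided familywise level (defaults to the design's).
#' @return A `rar_analysis` object: list with `tests` (per-arm tibble:
#'   method, arm, statistic, p.value, v_sum), `decisions` (tibble: method,
#'   arm, rejected — closed-test decisions for all four method
#'   combinations) and `weights` (per-arm weight traces, one tibble).
#' @examples
#' d <- trial_design(K = 2, burn_in = 2, block_sizes = c(4, 4),
#'                   control_block_sizes = c(3, 3))
#' trial <- simulate_trial(d, mu = c(0, 1), scheme = "bar", seed = 2)
#' fit <- analyze_trial(trial$data, d, trial$aux)
#' tidy(fit)
#' @export
analyze_trial <- function(data, design, aux, alpha = design$alpha,
                          sigma2 = design$sigma2, estimate = FALSE) {
  adj <- adjusted_z_test(data, design, aux, sigma2 = sigma2,
                         estimate = estimate)
  sigma2_used <- attr(adj, "sigma2")
  nav <- naive_z_test(data, design, sigma2 = sigma2_used)
  tests <- dplyr::bind_rows(
    dplyr::mutate(tidy(adj), method = "adjusted", .before = 1L),
    dplyr::mutate(tidy(nav), method = "naive", .before = 1L)
  )
  decisions <- dplyr::bind_rows(
    dplyr::mutate(
      closed_test_pooled_z(data, design, aux, alpha = alpha,
                           method = "adjusted",
                           sigma2 = sigma2_used)$decisions,
      method = "new_closed_z", .before = 1L
    ),
    dplyr::mutate(
      closed_test_pooled_z(data, design, alpha = alpha, method = "naive",
                           sigma2 = sigma2_used)$decisions,
      method = "naive_closed_z", .before = 1L
    ),
    dplyr::mutate(
      closed_test_holm(adj$statistic, alpha = alpha)$decisions,
      method = "new_holm", .before = 1L
    ),
    dplyr::mutate(
      closed_test_holm(nav$statistic, alpha = alpha)$decisions,
      method = "naive_holm", .before = 1L
    )
  )
  weights <- dplyr::bind_rows(
    purrr::imap(adj$weights, ~ dplyr::mutate(.x, arm = .y, .before = 1L))
  )
  structure(
    list(tests = tests, decisions = decisions, weights = weights,
         alpha = alpha, sigma2 = sigma2_used),
    class = "rar_analysis"
  )
}

#' @export
print.rar_analysis <- function(x, ...) {
  cat("Block-RAR trial analysis (one-sided alpha =", x$alpha, ")\n\n")
  print(x$tests)
  cat("\nClosed-test decisions:\n")
  wide <- tidyr::pivot_wider(x$decisions[c("method", "arm", "rejected")],
                             names_from = "arm", names_prefix = "H",
                             values_from = "rejected")
  print(wide)
  invisible(x)
}

#' @export
tidy.rar_analysis <- function(x, ...) x$tests

#' @export
glance.rar_analysis <- function(x, ...) {
  tibble::tibble(
    arms = length(unique(x$tests$arm)),
    alpha = x$alpha,
    sigma2 = x$sigma2,
    n_rejected_adjusted = sum(
      x$decisions$rejected[x$decisions$method == "new_closed_z"]
    )
  )
}

#' Write an analysis to CSV
#'
#' Writes the per-arm test table (joined with the summed contribution
#' coefficients and per-block weights spread into columns `w0..wB`).
#'
#' @param x A `rar_analysis`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_analysis_csv <- function(x, path) {
  stopifnot(inherits(x, "rar_analysis"))
  w <- tidyr::pivot_wider(x$weights[c("arm", "block", "w")],
                          names_from = "block", values_from = "w",
                          names_prefix = "w")
  out <- dplyr::left_join(x$tests, w, by = "arm")
  readr::write_csv(out, path)
  invisible(path)
}
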