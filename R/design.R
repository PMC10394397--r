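#' Specify a block-randomized trial design with a fixed control allocation
#'
#' A trial has `K` experimental arms and a common control arm. Patients are
#' recruited in a burn-in block (block 0, fixed equal allocation) followed by
#' `B` adaptive blocks. In every adaptive block the number of *experimental*
#' patients is fixed by design (`block_sizes`) but their split across arms may
#' be response-adaptive; the number of *control* patients per block
#' (`control_block_sizes`) is always fixed and never adapted.
#'
#' @param K Number of experimental arms (integer, at least 1).
#' @param burn_in Patients per experimental arm in block 0.
#' @param block_sizes Integer vector of length `B`: total experimental
#'   patients in blocks 1..B.
#' @param control_block_sizes Integer vector of length `B`: control patients
#'   in blocks 1..B.
#' @param alpha One-sided test level, in (0, 1).
#' @param sigma2 Known response variance (default 1).
#' @param control_burn_in Control patients in block 0; defaults to `burn_in`.
#'
#' @return An object of class `trial_design`: a list with the validated
#'   fields plus `B` (number of adaptive blocks) and `n0` (total control
#'   sample size).
#'
#' @examples
#' trial_design(K = 2)
#' @export
trial_design <- function(K, burn_in = 5L, block_sizes = c(40L, 40L, 40L),
                         control_block_sizes = c(20L, 20L, 20L),
                         alpha = 0.05, sigma2 = 1,
                         control_burn_in = burn_in) {
  check_count(K, "K")
  check_count(burn_in, "burn_in")
  check_count(control_burn_in, "control_burn_in")
  check_counts(block_sizes, "block_sizes")
  check_counts(control_block_sizes, "control_block_sizes")
  if (length(block_sizes) != length(control_block_sizes)) {
    abort("`block_sizes` and `control_block_sizes` must have the same length.")
  }
  if (length(block_sizes) < 1L) abort("at least one adaptive block is required.")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1).")
  }
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 <= 0) {
    abort("`sigma2` must be a single positive number.")
  }
  structure(
    list(
      K = as.integer(K),
      burn_in = as.integer(burn_in),
      control_burn_in = as.integer(control_burn_in),
      block_sizes = as.integer(block_sizes),
      control_block_sizes = as.integer(control_block_sizes),
      alpha = alpha,
      sigma2 = sigma2,
      B = length(block_sizes),
      n0 = as.integer(control_burn_in + sum(control_block_sizes))
    ),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Block-RAR trial design\n")
  cat("  experimental arms (K):", x$K, "\n")
  cat("  burn-in per arm:", x$burn_in,
      "(control:", paste0(x$control_burn_in, ")"), "\n")
  cat("  adaptive blocks (B):", x$B,
      " experimental sizes:", paste(x$block_sizes, collapse = ", "), "\n")
  cat("  control block sizes:", paste(x$control_block_sizes, collapse = ", "),
      " (n0 =", x$n0, "total)\n")
  cat("  one-sided alpha:", x$alpha, "  sigma2:", x$sigma2, "\n")
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
      x != round(x)) {
    abort(paste0("`", name, "` must be a single positive integer."))
  }
}

check_counts <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) || any(x < 1) ||
      any(x != round(x))) {
    abort(paste0("`", name, "` must be a vector of positive integers."))
  }
}

#' Tail sums of per-block sample sizes
#'
#' For per-block counts \eqn{n_1, \dots, n_B} returns
#' \eqn{m_j = n_j + \dots + n_B}, the number of patients still to be
#' allocated from block \eqn{j} onwards in the auxiliary design (with the
#' convention \eqn{m_{B+1} = 0}).
#'
#' @param counts Numeric vector of per-block counts.
#' @return Numeric vector of the same length; element `j` is the sum of
#'   `counts[j:B]`.
#' @examples
#' tail_sums(c(40, 40, 40)) # 120 80 40
#' @export
tail_sums <- function(counts) {
  if (length(counts) < 1L) abort("`counts` must be non-empty.")
  rev(cumsum(rev(as.numeric(counts))))
}

#' Generate a uniform auxiliary design
#'
#' The auxiliary design is a hypothetical randomization list fixed before the
#' trial: every experimental patient in each adaptive block is assigned an
#' arm uniformly at random on `1:K`. Under it the standard z-test is valid,
#' and the realized response-adaptive trial is analyzed by matching its test
#' statistic's conditional variances to this design
#' (see [adjusted_z_test()]). If a uniform draw leaves some arms of a block
#' empty, the last-drawn patients of that block are reassigned to the empty
#' arms so that every arm receives at least one patient (the same guard the
#' adaptive allocators use); this keeps all weight denominators positive.
#'
#' Uses the current RNG state; call `set.seed()` (or pass `seed`) for
#' reproducibility.
#'
#' @param design A [trial_design()].
#' @param seed Optional integer seed set before drawing.
#' @return An object of class `aux_design`: list with `counts` (B x K matrix
#'   of \eqn{n_{j,k}}), `burn_in` (length-K vector \eqn{n_{0,k}}),
#'   `tail_sums` (B x K matrix of \eqn{m_{j,k}}), `totals` (length-K vector
#'   \eqn{n_k}), and `labels` (list of per-block arm label vectors).
#' @examples
#' d <- trial_design(K = 2)
#' aux <- generate_auxiliary_design(d, seed = 1)
#' colSums(aux$counts) + aux$burn_in # totals n_k
#' @export
generate_auxiliary_design <- function(design, seed = NULL) {
  stopifnot(inherits(design, "trial_design"))
  if (!is.null(seed)) set.seed(seed)
  K <- design$K
  if (any(design$block_sizes < K)) {
    abort("every block size must be at least K so each arm can receive a patient.")
  }
  labels <- purrr::map(design$block_sizes, function(bs) {
    allocate_block_fixed(bs, K)
  })
  counts <- do.call(rbind, purrr::map(labels, ~ tabulate(.x, nbins = K)))
  new_aux_design(counts, rep(design$burn_in, K), labels)
}

new_aux_design <- function(counts, burn_in, labels = NULL) {
  counts <- matrix(as.integer(counts), nrow = NROW(counts))
  ts <- apply(counts, 2L, function(x) tail_sums(x))
  if (is.null(dim(ts))) ts <- matrix(ts, nrow = nrow(counts))
  structure(
    list(
      counts = counts,
      burn_in = as.integer(burn_in),
      tail_sums = ts,
      totals = as.integer(burn_in + colSums(counts)),
      labels = labels
    ),
    class = "aux_design"
  )
}

#' @export
print.aux_design <- function(x, ...) {
  cat("Auxiliary design:", ncol(x$counts), "arms,", nrow(x$counts),
      "adaptive blocks\n")
  cat("  burn-in n0k:", paste(x$burn_in, collapse = ", "), "\n")
  cat("  totals nk:  ", paste(x$totals, collapse = ", "), "\n")
  print(x$counts)
  invisible(x)
}

#' Build an auxiliary design from explicit per-block counts
#'
#' Mostly useful for re-analysis of a trial whose pre-specified randomization
#' list is known, and in tests.
#'
#' @param counts B x K matrix (or vector for K = 1) of per-block arm counts.
#' @param burn_in Length-K vector (or scalar) of burn-in counts per arm.
#' @return An `aux_design` object.
#' @export
auxiliary_design <- function(counts, burn_in) {
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = 1L)
  if (any(counts < 1)) {
    bad <- which(counts < 1, arr.ind = TRUE)[1L, ]
    abort(paste0("auxiliary count must be >= 1 (block ", bad[1L],
                 ", arm ", bad[2L], ")."))
  }
  burn_in <- rep_len(burn_in, ncol(counts))
  if (any(burn_in < 1)) abort("burn-in counts must be >= 1.")
  new_aux_design(counts, burn_in)
}
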