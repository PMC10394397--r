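#' Bayesian adaptive randomization probabilities
#'
#' Computes the block-randomized BAR allocation probabilities
#' \deqn{\pi_k \propto P(\mu_k > \mu_0 \mid x)^\gamma,}
#' normalized to sum to one, where the posterior probability that arm `k`
#' beats control is evaluated under a conjugate normal model with known
#' variance and flat priors:
#' \eqn{P(\mu_k > \mu_0 \mid x) = \Phi\{(\bar x_k - \bar x_0) /
#' \sqrt{\sigma^2/\tilde n_k + \sigma^2/n_0}\}} on all data accumulated so
#' far (burn-in included). The tempering exponent `gamma` interpolates
#' between fixed equal randomization (`gamma = 0`) and greedier allocation.
#'
#' @param counts Per-arm accumulated sample sizes (length K, all >= 1).
#' @param means Per-arm accumulated mean responses (length K).
#' @param control_count,control_mean Accumulated control sample size and mean.
#' @param gamma Tempering exponent, >= 0 (default 0.5).
#' @param sigma2 Known response variance.
#' @return Numeric vector of K allocation probabilities in (0, 1), summing
#'   to 1.
#' @examples
#' bar_probabilities(c(10, 10), c(0.2, 0.2), 10, 0) # symmetric: 0.5, 0.5
#' @export
bar_probabilities <- function(counts, means, control_count, control_mean,
                              gamma = 0.5, sigma2 = 1) {
  if (any(counts < 1) || control_count < 1) {
    abort("every arm and the control need at least one observation.")
  }
  if (gamma < 0) abort("`gamma` must be non-negative.")
  post <- pnorm((means - control_mean) /
                  sqrt(sigma2 / counts + sigma2 / control_count))
  pw <- post^gamma # gamma = 0 gives exactly uniform probabilities
  pw / sum(pw)
}

#' Allocate one block of patients to experimental arms
#'
#' `allocate_block_bar()` draws each patient independently from the given
#' allocation probabilities; `allocate_block_fixed()` is the special case of
#' equal probabilities. Both then apply the minimum-one guard: if `K*` arms
#' received no patient, the last `K*` drawn patients are reassigned, one to
#' each empty arm, so every arm ends the block with at least one patient.
#' `allocate_block_error_inflator()` implements an adversarial rule that
#' concentrates patients on a favored arm until its running mean response
#' crosses a threshold (see [simulate_trial()]); it is used to demonstrate
#' type I error inflation of the naive z-test.
#'
#' @param block_size Number of experimental patients in the block
#'   (at least K).
#' @param probs Allocation probabilities (length K, summing to 1).
#' @param K Number of experimental arms.
#' @param crossed Logical: has the favored arm's running mean already
#'   crossed the threshold at a previous block boundary? The crossing state
#'   is absorbing and must be evaluated by the caller at block boundaries
#'   (a running mean greater than or equal to the threshold counts as
#'   crossed).
#' @param favored_arm Index of the favored arm (default 1).
#' @return Integer vector of `block_size` arm labels in `1:K`, each arm
#'   appearing at least once.
#' @examples
#' set.seed(1)
#' table(allocate_block_bar(40, c(0.9, 0.1)))
#' table(allocate_block_error_inflator(40, K = 2, crossed = FALSE)) # 39, 1
#' @export
allocate_block_bar <- function(block_size, probs) {
  K <- length(probs)
  if (block_size < K) abort("`block_size` must be at least K.")
  if (K == 1L) return(rep(1L, block_size))
  # findInterval on the cumulative probabilities; identical code path for
  # all probability vectors so gamma = 0 matches the fixed allocator draw
  # for draw on a shared RNG stream.
  u <- runif(block_size)
  labels <- findInterval(u, cumsum(probs[-K])) + 1L
  guard_min_one(labels, K)
}

#' @rdname allocate_block_bar
#' @export
allocate_block_fixed <- function(block_size, K) {
  allocate_block_bar(block_size, rep(1 / K, K))
}

#' @rdname allocate_block_bar
#' @export
allocate_block_error_inflator <- function(block_size, K, crossed,
                                          favored_arm = 1L) {
  if (block_size < K) abort("`block_size` must be at least K.")
  if (!favored_arm %in% seq_len(K)) abort("`favored_arm` must be in 1..K.")
  others <- setdiff(seq_len(K), favored_arm)
  if (!crossed) {
    # one token patient per non-favored arm, the rest on the favored arm
    labels <- c(rep(favored_arm, block_size - (K - 1L)), others)
  } else if (K == 1L) {
    labels <- rep(1L, block_size)
  } else {
    # one token patient on the favored arm, the rest split uniformly
    rest <- others[findInterval(runif(block_size - 1L),
                                seq_len(K - 2L) / (K - 1L)) + 1L]
    if (K > 2L) rest <- guard_subset_min_one(rest, others)
    labels <- c(rest, favored_arm)
  }
  as.integer(labels)
}

# Crossing-state update for the error-inflator rule, evaluated at block
# boundaries on the favored arm's running mean over blocks 0..j-1. A mean
# at or above the threshold ("remains below" fails) counts as crossed, and
# the state is absorbing.
update_crossed <- function(crossed, running_mean, threshold = 0.5) {
  crossed | (running_mean >= threshold)
}

# Reassign the last-drawn patients so every arm in 1:K appears at least
# once. Iterates in the (pathological) case where a reassignment empties
# another arm.
guard_min_one <- function(labels, K) {
  n <- length(labels)
  repeat {
    empty <- setdiff(seq_len(K), unique(labels))
    if (length(empty) == 0L) return(as.integer(labels))
    labels[(n - length(empty) + 1L):n] <- empty
  }
}

guard_subset_min_one <- function(labels, arms) {
  n <- length(labels)
  repeat {
    empty <- setdiff(arms, unique(labels))
    if (length(empty) == 0L) return(as.integer(labels))
    labels[(n - length(empty) + 1L):n] <- empty
  }
}
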