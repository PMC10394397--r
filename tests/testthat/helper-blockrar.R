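# Shared fixture builders. Everything is generated in code at test time.

small_design <- function(K = 2) {
  trial_design(
    K = K, burn_in = 2, block_sizes = c(4 * K, 4 * K),
    control_block_sizes = c(3, 3)
  )
}

paper_design <- function(K = 2) trial_design(K = K)

# A trial whose realized allocation equals the auxiliary design exactly
# (the "no adaptation" case where the adjusted test must reduce to the
# standard z-test).
trivial_trial <- function(design, seed = 1) {
  set.seed(seed)
  aux <- generate_auxiliary_design(design)
  K <- design$K
  rows <- list(tibble::tibble(
    block = 0L,
    arm = c(rep(0L, design$control_burn_in),
            rep(seq_len(K), each = design$burn_in)),
    response = rnorm(design$control_burn_in + K * design$burn_in)
  ))
  for (j in seq_len(design$B)) {
    lab <- aux$labels[[j]]
    nc <- design$control_block_sizes[j]
    rows[[j + 1L]] <- tibble::tibble(
      block = j, arm = c(lab, rep(0L, nc)),
      response = rnorm(length(lab) + nc)
    )
  }
  list(data = dplyr::bind_rows(rows), aux = aux, design = design)
}

# Rebuild the vectorized engine's sufficient-statistic layout (R = 1) from
# a per-patient trial, so the two implementation routes can be compared.
run_from_trial <- function(trial) {
  design <- trial$design
  K <- design$K
  B <- design$B
  cells <- dplyr::summarise(
    dplyr::group_by(trial$data, block, arm),
    n = dplyr::n(), s = sum(response), .groups = "drop"
  )
  run <- list(
    aux_counts = array(0L, c(1, K, B)), rel_counts = array(0L, c(1, K, B)),
    rel_sums = array(0, c(1, K, B)), burn_sums = matrix(0, 1, K),
    burn_in = design$burn_in, sigma2 = design$sigma2,
    B = B, K = K, R = 1L, n0 = design$n0
  )
  for (k in seq_len(K)) {
    run$aux_counts[1, k, ] <- trial$aux$counts[, k]
    run$burn_sums[1, k] <- cells$s[cells$block == 0 & cells$arm == k]
    for (j in seq_len(B)) {
      run$rel_counts[1, k, j] <- cells$n[cells$block == j & cells$arm == k]
      run$rel_sums[1, k, j] <- cells$s[cells$block == j & cells$arm == k]
    }
  }
  ctrl <- cells[cells$arm == 0, ]
  run$ctrl_mean <- sum(ctrl$s) / sum(ctrl$n)
  run
}

# Independent oracle for the weight recursion: solve each block's
# conditional-variance-matching equation numerically with uniroot.
uniroot_weights <- function(aux_counts, realized_counts, burn_in) {
  B <- length(aux_counts)
  n_k <- burn_in + sum(aux_counts)
  m <- c(rev(cumsum(rev(aux_counts))), 0)
  w <- numeric(B + 1)
  w[1] <- n_k
  for (j in seq_len(B)) {
    mnext <- m[j + 1]
    f <- function(wj) {
      (realized_counts[j] + mnext) / wj^2 -
        (aux_counts[j] + mnext) / w[j]^2
    }
    w[j + 1] <- stats::uniroot(f, c(1e-8, 1e8), tol = 1e-14)$root
  }
  w
}
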