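#' Plot the per-block weights of an analyzed trial
#'
#' Shows, per arm, the adjusted per-block weights \eqn{w_j} next to the
#' auxiliary total \eqn{n_k} (the weight each block would get without
#' adaptation) and the realized per-block sample sizes. Blocks where the
#' adaptive rule allocated more patients than the auxiliary design get
#' up-weighted and vice versa, while all weights stay strictly positive.
#'
#' @param object A `rar_analysis` from [analyze_trial()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rar_analysis <- function(object, ...) {
  w <- dplyr::mutate(object$weights, arm = factor(.data$arm))
  ggplot2::ggplot(w, ggplot2::aes(x = .data$block, y = .data$w,
                                  colour = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(ggplot2::aes(y = .data$realized_n),
                        shape = 1) +
    ggplot2::labs(
      x = "block", y = "weight",
      title = "Variance-matched block weights",
      subtitle = "filled: weights w_j; open: realized block sample sizes"
    ) +
    ggplot2::theme_minimal()
}

#' Plot operating characteristics
#'
#' Bar chart of FWER and disjunctive power by analysis method, with
#' 3-standard-error Monte-Carlo bars and the nominal level marked on the
#' error panel.
#'
#' @param object An `oc_summary` from [operating_characteristics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oc_summary <- function(object, ...) {
  sc <- attr(object, "scenario")
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("error", "power"),
    names_to = "measure", values_to = "estimate"
  )
  long$se <- ifelse(long$measure == "error", object$error_se[
    match(long$method, object$method)
  ], object$power_se[match(long$method, object$method)])
  long <- dplyr::filter(long, !is.na(.data$estimate))
  nominal <- tibble::tibble(measure = "error", level = 100 * sc$alpha)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method,
                                     y = .data$estimate)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$estimate - 3 * .data$se,
                   ymax = .data$estimate + 3 * .data$se),
      width = 0.2
    ) +
    ggplot2::geom_hline(data = nominal,
                        ggplot2::aes(yintercept = .data$level),
                        linetype = 2) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "percent",
                  title = "FWER and disjunctive power") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
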