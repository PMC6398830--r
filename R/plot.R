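#' Plot a fitted model
#'
#' `type = "intervals"` draws posterior means and 95% credible intervals of
#' the pollutant coefficients; `type = "trace"` draws trace plots of the
#' monitored scalar parameters (one facet per parameter, colored by chain).
#'
#' @param object An `h2m_fit`.
#' @param type `"intervals"` or `"trace"`.
#' @param pars Parameter subset for traces (regular expression); default the
#'   pollutant coefficients.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot h2m_fit
#' @export
autoplot.h2m_fit <- function(object, type = c("intervals", "trace"),
                             pars = "^beta_", ...) {
  type <- match.arg(type)
  if (type == "intervals") {
    td <- tidy(object, pars = "beta")
    td$term <- sub("^beta_", "", td$term)
    return(
      ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
        ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
        ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                              xmax = .data$conf.high)) +
        ggplot2::labs(x = "log relative risk per unit concentration",
                      y = NULL, title = paste("Posterior 95% CI:", object$model)) +
        ggplot2::theme_minimal()
    )
  }
  long <- purrr::imap(object$samples, function(ch, i) {
    m <- as.matrix(ch)
    keep <- grep(pars, colnames(m), value = TRUE)
    tibble::tibble(chain = factor(i), iteration = seq_len(nrow(m))) |>
      dplyr::bind_cols(tibble::as_tibble(m[, keep, drop = FALSE])) |>
      tidyr::pivot_longer(dplyr::all_of(keep), names_to = "term")
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     colour = .data$chain)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "retained iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot simulation-study metrics
#'
#' Dot plot of per-coefficient bias and 95% CI coverage by estimator; the
#' dashed lines mark zero bias and nominal 95% coverage.
#'
#' @param object An `mp_study` from [run_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mp_study
#' @export
autoplot.mp_study <- function(object, ...) {
  m <- object$metrics |>
    dplyr::select(.data$estimator, .data$term, .data$bias, .data$ci95_coverage) |>
    tidyr::pivot_longer(c("bias", "ci95_coverage"), names_to = "metric")
  ref <- tibble::tibble(metric = c("bias", "ci95_coverage"), y = c(0, 95))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$term, y = .data$value,
                                  colour = .data$estimator)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = .data$y),
                        linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
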