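#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulated PK profile
#'
#' @param x A `pk_profile`.
#' @param amounts Include one column per compartment amount (ug)?
#' @param ... Unused.
#' @return A tibble with `time_h`, `plasma_ng_mL`, `stomach_free_ng_mL` and
#'   optionally the compartment amounts.
#' @export
tidy.pk_profile <- function(x, amounts = FALSE, ...) {
  out <- x$data
  if (amounts) {
    amt <- tibble::as_tibble(as.data.frame(x$amounts))
    names(amt) <- paste0("amt_", names(amt))
    out <- dplyr::bind_cols(out, amt)
  }
  out
}

#' @rdname tidy.pk_profile
#' @export
glance.pk_profile <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(compound = x$compound$name,
                   dose_mg = x$regimen$dose_mg),
    compute_pk_metrics(x),
    tibble::tibble(mass_balance_rel_err = x$mass_balance_rel_err)
  )
}

#' @rdname tidy.pk_profile
#' @export
tidy.pd_profile <- function(x, ...) x$data

#' @rdname tidy.pk_profile
#' @param threshold,window_h Endpoint definition for the PD summary.
#' @export
glance.pd_profile <- function(x, threshold = 4, window_h = 24, ...) {
  tibble::tibble(
    compound = x$potency$name,
    dose_mg = x$regimen$dose_mg,
    holding_time_pct = holding_time_percentage(x, threshold, window_h),
    onset_h = onset_time(x, threshold),
    threshold = threshold, window_h = window_h
  )
}

#' Plot methods for simulation results
#'
#' `autoplot.pk_profile()` draws the plasma concentration-time course (with
#' the stomach free concentration optionally overlaid),
#' `autoplot.pd_profile()` the gastric pH trajectory against the clinical
#' threshold, and `autoplot.screening_result()` the holding-time
#' dose-response per compound.
#'
#' @param object Result object.
#' @param stomach Overlay the stomach free concentration?
#' @param log_y Log-scale the concentration axis?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pk_profile <- function(object, stomach = FALSE, log_y = FALSE, ...) {
  df <- tidyr::pivot_longer(object$data, -"time_h",
                            names_to = "series", values_to = "conc")
  if (!stomach) df <- dplyr::filter(df, .data$series == "plasma_ng_mL")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$conc,
                                        colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "concentration (ng/mL)",
                  title = sprintf("%s, %g mg oral", object$compound$name,
                                  object$regimen$dose_mg)) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @rdname autoplot.pk_profile
#' @export
autoplot.pd_profile <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time_h, .data$ph)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 4, linetype = "dashed") +
    ggplot2::labs(x = "time (h)", y = "gastric pH",
                  title = sprintf("%s: simulated gastric pH",
                                  object$potency$name)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pk_profile
#' @export
autoplot.screening_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$dose_mg,
                                       .data$holding_time_pct,
                                       colour = .data$compound)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10(breaks = unique(object$dose_mg)) +
    ggplot2::labs(x = "dose (mg)", y = "pH > 4 holding time (%)") +
    ggplot2::theme_minimal()
}
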