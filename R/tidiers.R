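#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and summarize mean-height curves
#'
#' `tidy()` returns the curve grid as a plain tibble; `glance()` returns a
#' one-row summary combining [curve_summary()] and the [classify_curve()]
#' label.
#'
#' @param x An `hbar_curve`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy hbar_curve
#' @export
tidy.hbar_curve <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("N", "hbar", if ("sigma_h" %in% names(x)) "sigma_h")])
}

#' @rdname tidy.hbar_curve
#' @method glance hbar_curve
#' @export
glance.hbar_curve <- function(x, ...) {
  dplyr::bind_cols(curve_summary(x), classify_curve(x))
}

#' Tidy and summarize ensemble results
#'
#' `tidy()` returns the per-landscape records. `glance()` returns one row of
#' ensemble aggregates: the multi-peak and two-peak fractions, peak density,
#' curve-shape class frequencies among multi-peak landscapes, the
#' overall-increasing share among two-peak landscapes, the differential
#' accessibility category frequencies with their conditional accuracies, and
#' the mean largest-to-other extremum amplitude ratio.
#'
#' @param x An `ensemble_result` from [run_ensemble()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ensemble_result
#' @export
tidy.ensemble_result <- function(x, ...) x$per_landscape

#' @rdname tidy.ensemble_result
#' @method glance ensemble_result
#' @export
glance.ensemble_result <- function(x, ...) {
  pl <- x$per_landscape
  np <- x$n_peaks_all
  out <- tibble::tibble(
    n_generated = x$n_generated,
    n_analysed = nrow(pl),
    frac_multipeak = mean(np > 1),
    frac_twopeak_of_multi = if (any(np > 1)) mean(np[np > 1] == 2) else NA_real_,
    peak_density = mean(np) / 2^x$config$L
  )
  if ("label" %in% names(pl)) {
    multi <- pl[pl$n_peaks > 1, ]
    if (nrow(multi) > 0) {
      out$frac_monotonic_increasing <- mean(multi$label == "monotonic_increasing")
      out$frac_one_maximum <- mean(multi$label == "one_maximum")
      out$mean_delta_hbar <- mean(multi$delta_hbar)
      out$mean_overshoot <- mean(multi$overshoot)
      rn <- sum(multi$amp_ratio_n)
      out$amp_ratio_mean <- if (rn > 0) sum(multi$amp_ratio_sum) / rn else NA_real_
    }
    two <- pl[pl$n_peaks == 2 & !is.na(pl$hbar_1), ]
    if (nrow(two) > 0) {
      out$frac_overall_increasing_two_peak <- mean(two$overall == "increasing")
    }
  }
  if ("prediction" %in% names(pl) && "overall" %in% names(pl)) {
    two <- pl[!is.na(pl$prediction), ]
    if (nrow(two) > 0) {
      pos <- two$prediction == "predict_increasing"
      neg <- two$prediction == "predict_decreasing"
      zero <- two$prediction == "undetermined_both_zero"
      out$frac_predict_increasing <- mean(pos)
      out$frac_predict_decreasing <- mean(neg)
      out$frac_both_zero <- mean(zero)
      out$frac_conflict <- mean(two$prediction == "undetermined_conflict")
      out$acc_predict_increasing <-
        if (any(pos)) mean(two$overall[pos] == "increasing") else NA_real_
      out$acc_predict_decreasing <-
        if (any(neg)) mean(two$overall[neg] == "decreasing") else NA_real_
      out$frac_zero_increasing <-
        if (any(zero)) mean(two$overall[zero] == "increasing") else NA_real_
    }
  }
  out
}

#' Plot a mean-height curve
#'
#' Mean height of the first encountered peak versus population size, on a
#' logarithmic `N` axis, with the large-`N` anchor marked.
#'
#' @param object An `hbar_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hbar_curve
#' @export
autoplot.hbar_curve <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$N, y = .data$hbar)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(size = 1.2, colour = "#2c7fb8") +
    ggplot2::geom_hline(
      yintercept = df$hbar[nrow(df)],
      linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "population size N",
      y = expression(bar(h)),
      title = sprintf("Mean first-peak fitness (%s walk)", attr(object, "walk"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot ensemble curve-shape class frequencies
#'
#' Bar chart of the behaviour classes of `hbar` versus `N` among multi-peak
#' landscapes of an ensemble.
#'
#' @param object An `ensemble_result` with curve classifications.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ensemble_result
#' @export
autoplot.ensemble_result <- function(object, ...) {
  pl <- object$per_landscape
  if (!"label" %in% names(pl)) {
    stop("ensemble was run in 'peaks' mode; no curve classes to plot", call. = FALSE)
  }
  multi <- pl[pl$n_peaks > 1, ]
  df <- dplyr::count(multi, .data$label)
  df$freq <- df$n / sum(df$n)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, -.data$freq), y = .data$freq)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(
      x = NULL, y = "frequency among multi-peak landscapes",
      title = sprintf(
        "Population-size dependence classes (%s walk)", object$config$walk
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
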