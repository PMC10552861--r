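# Percent-error reporting against ground-truth dimensions, in the layout
# of the device's test-bench tables.

#' Percent-error report against ground truth
#'
#' Computes per-item percent errors `100 * (predicted - true) / true`
#' and, per object group, their mean and sample (N - 1) standard
#' deviation — the summary layout used in bench evaluations of the
#' device.
#'
#' @param results Tibble with columns `object` and `predicted_cm`, plus
#'   `original_cm` if `truth` is not given. Extra columns (condition
#'   descriptors such as `height_cm`, `pitch_deg`, `dtof_mm`) are kept.
#' @param truth Optional tibble with columns `object` and `original_cm`;
#'   joined to `results` by `object`. Every result must match a truth
#'   row.
#' @param group Column(s) defining the summary groups (default
#'   `"object"`).
#' @return A tibble of class `dishmetry_errors`: the input rows plus
#'   `error_pct`, `group_mean_pct`, `group_sd_pct`.
#' @examples
#' error_report(tibble::tibble(
#'   object = c("plate", "plate"), predicted_cm = c(17.5, 18.4),
#'   original_cm = 18
#' ))
#' @export
error_report <- function(results, truth = NULL, group = "object") {
  results <- tibble::as_tibble(results)
  if (!is.null(truth)) {
    truth <- tibble::as_tibble(truth)
    stopifnot(all(c("object", "original_cm") %in% names(truth)))
    unmatched <- setdiff(results$object, truth$object)
    if (length(unmatched) > 0) {
      stop("results have no matching truth rows: ",
           paste(unique(unmatched), collapse = ", "), call. = FALSE)
    }
    results <- dplyr::left_join(results, truth[, c("object", "original_cm")],
                                by = "object")
  }
  stopifnot(all(c("object", "predicted_cm", "original_cm") %in% names(results)))
  out <- results |>
    dplyr::mutate(
      error_pct = 100 * (.data$predicted_cm - .data$original_cm) /
        .data$original_cm
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::mutate(
      group_mean_pct = mean(.data$error_pct, na.rm = TRUE),
      group_sd_pct = stats::sd(.data$error_pct, na.rm = TRUE)
    ) |>
    dplyr::ungroup()
  class(out) <- c("dishmetry_errors", class(out))
  attr(out, "group") <- group
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an error report
#'
#' @param x A `dishmetry_errors` tibble from [error_report()].
#' @param ... Unused.
#' @return `tidy()` gives one row per object group with `mean_pct`,
#'   `sd_pct` and `n`; `glance()` gives a one-row overall summary.
#' @export
tidy.dishmetry_errors <- function(x, ...) {
  group <- attr(x, "group")
  x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(
      mean_pct = mean(.data$error_pct, na.rm = TRUE),
      sd_pct = stats::sd(.data$error_pct, na.rm = TRUE),
      n = sum(!is.na(.data$error_pct)),
      .groups = "drop"
    )
}

#' @rdname tidy.dishmetry_errors
#' @export
glance.dishmetry_errors <- function(x, ...) {
  tibble::tibble(
    mean_pct = mean(x$error_pct, na.rm = TRUE),
    sd_pct = stats::sd(x$error_pct, na.rm = TRUE),
    mean_abs_pct = mean(abs(x$error_pct), na.rm = TRUE),
    n = sum(!is.na(x$error_pct))
  )
}

#' Plot an error report
#'
#' Percent error per object, coloured by pitch angle and faceted by
#' camera height when those condition columns are present.
#'
#' @param object A `dishmetry_errors` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dishmetry_errors <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$object, y = .data$error_pct))
  if ("pitch_deg" %in% names(object)) {
    p <- p + ggplot2::aes(colour = factor(.data$pitch_deg)) +
      ggplot2::labs(colour = "pitch (deg)")
  }
  p <- p +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "error (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  if ("height_cm" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(~height_cm, labeller = ggplot2::label_both)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
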