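#' Descriptive summary of a numeric vector
#'
#' The summary row used throughout the pipeline's tables: n, mean, sample
#' SD (n-1 denominator; reported as 0 for a singleton), median, quartiles
#' by linear interpolation between order statistics (`quantile()` type 7),
#' and range.
#'
#' @param values Non-empty numeric vector of finite values.
#' @return A one-row tibble with columns `n`, `mean`, `sd`, `median`,
#'   `q1`, `q3`, `min`, `max`.
#' @examples
#' summarize_values(c(1, 2, 3, 4)) # median 2.5, q1 1.75, q3 3.25
#' @export
summarize_values <- function(values) {
  if (length(values) == 0) stop("`values` must be non-empty", call. = FALSE)
  if (any(!is.finite(values))) {
    stop("`values` must be finite", call. = FALSE)
  }
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  tibble::tibble(
    n = length(values),
    mean = mean(values),
    sd = if (length(values) > 1) sd(values) else 0,
    median = q[2], q1 = q[1], q3 = q[3],
    min = min(values), max = max(values)
  )
}

#' Grouped descriptive summaries
#'
#' One [summarize_values()] row per level of a grouping dimension plus an
#' `overall` row, mirroring the layout of day-of-week / region /
#' session-length travel-distance tables. Group sizes sum to the total by
#' construction.
#'
#' @param data A data frame.
#' @param value_col Name of the numeric column to summarise.
#' @param group_col Name of the grouping column (e.g. `"region"`,
#'   `"duration_class"`, `"day_class"`), or `NULL` for the overall row
#'   only.
#' @return A tibble with a `group` column followed by the summary columns.
#' @export
grouped_summary <- function(data, value_col, group_col = NULL) {
  stopifnot(is.data.frame(data))
  if (!value_col %in% names(data)) {
    stop(sprintf("unknown value column: %s", value_col), call. = FALSE)
  }
  overall <- dplyr::bind_cols(tibble::tibble(group = "overall"),
                              summarize_values(data[[value_col]]))
  if (is.null(group_col)) return(overall)
  if (!group_col %in% names(data)) {
    stop(sprintf("unknown grouping dimension: %s", group_col), call. = FALSE)
  }
  per_group <- data |>
    dplyr::group_by(group = as.character(.data[[group_col]])) |>
    dplyr::reframe(summarize_values(.data[[value_col]])) |>
    dplyr::arrange(.data$group)
  dplyr::bind_rows(per_group, overall)
}

#' Box plot of round-trip travel distance by group
#'
#' Optional figure output: standard box plots (whiskers at 1.5 IQR)
#' of a numeric column by a grouping column. Requires ggplot2.
#'
#' @inheritParams grouped_summary
#' @return A ggplot object.
#' @export
distance_boxplot <- function(data, value_col = "round_trip_miles",
                             group_col = "region") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data[[group_col]], y = .data[[value_col]]
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "Round-trip travel distance (miles)") +
    ggplot2::theme_minimal()
}
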