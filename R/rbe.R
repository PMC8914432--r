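#' Relative biological effectiveness from paired dose metrics
#'
#' RBE is the ratio of the reference-radiation dose to the test-radiation
#' dose producing the same biological effect:
#' `RBE = D_reference / D_test`. It is invariant to a common rescaling of
#' both dose axes.
#'
#' @param reference_metric,test_metric Positive dose-like metrics in Gy
#'   computed at the same endpoint on the reference (photon) and test (ion)
#'   survival curves.
#'
#' @return Dimensionless RBE (vectorised).
#' @examples
#' rbe(reference_metric = 5, test_metric = 2.5)
#' @export
rbe <- function(reference_metric, test_metric) {
  if (any(reference_metric <= 0) || any(test_metric <= 0)) {
    rlang::abort("Both dose metrics must be positive.")
  }
  reference_metric / test_metric
}

#' RBE endpoints
#'
#' The four dose-metric endpoints at which per-cell-line RBEs are computed:
#' dose at 10% survival (`sf10`), mean inactivation dose from the RCR closed
#' form (`dbar_param`) and from the trapezoidal AUC (`dbar_auc`), and the
#' limiting slope (`d0`).
#'
#' @return Character vector of endpoint codes.
#' @export
rbe_endpoints <- function() c("sf10", "dbar_param", "dbar_auc", "d0")

metric_col_for_endpoint <- c(sf10 = "d10", dbar_param = "dbar_param",
                             dbar_auc = "dbar_auc", d0 = "d0")

#' Endpoint-wise RBE table for a cell-line panel
#'
#' Pairs reference and test survival fits by cell line, computes the four
#' endpoint metrics on each side (see [rbe_endpoints()]) and their ratios,
#' and summarises each endpoint across cell lines (mean, sample SD, CV).
#' All values are carried at full precision; rounding is a display concern.
#'
#' @param fits_reference,fits_test Tibbles as returned by
#'   [fit_survival_curves()] (one row per cell line, columns `cell_line,
#'   d10, dbar_param, dbar_auc, d0`), for the reference (photon) and test
#'   (ion) radiation qualities. Cell-line sets must match exactly.
#'
#' @return An `rbe_table` object: list with `records` (tibble `cell_line,
#'   endpoint, reference_metric, test_metric, rbe`) and `summary` (tibble
#'   `endpoint, mean, sd, cv`; `sd`/`cv` are `NA` when only one cell line is
#'   present). `tidy()` returns the records.
#' @export
rbe_table <- function(fits_reference, fits_test) {
  need <- c("cell_line", unname(metric_col_for_endpoint))
  stopifnot(all(need %in% names(fits_reference)),
            all(need %in% names(fits_test)))
  ref_lines <- sort(fits_reference$cell_line)
  test_lines <- sort(fits_test$cell_line)
  if (!identical(ref_lines, test_lines)) {
    only_ref <- setdiff(ref_lines, test_lines)
    only_test <- setdiff(test_lines, ref_lines)
    rlang::abort(paste0(
      "Reference and test fits must cover the same cell lines. ",
      if (length(only_ref)) paste0("Only in reference: ",
                                   paste(only_ref, collapse = ", "), ". "),
      if (length(only_test)) paste0("Only in test: ",
                                    paste(only_test, collapse = ", "), ".")))
  }

  to_long <- function(df, value_name) {
    df |>
      dplyr::select("cell_line", dplyr::all_of(unname(metric_col_for_endpoint))) |>
      tidyr::pivot_longer(-"cell_line", names_to = "metric",
                          values_to = value_name) |>
      dplyr::mutate(endpoint = names(metric_col_for_endpoint)[
        match(.data$metric, metric_col_for_endpoint)]) |>
      dplyr::select("cell_line", "endpoint", dplyr::all_of(value_name))
  }
  records <- to_long(fits_reference, "reference_metric") |>
    dplyr::inner_join(to_long(fits_test, "test_metric"),
                      by = c("cell_line", "endpoint")) |>
    dplyr::mutate(rbe = rbe(.data$reference_metric, .data$test_metric),
                  endpoint = factor(.data$endpoint, levels = rbe_endpoints())) |>
    dplyr::arrange(.data$endpoint, .data$cell_line)

  structure(list(records = records, summary = rbe_summary(records)),
            class = "rbe_table")
}

#' Summarise endpoint-wise RBE records
#'
#' Mean, sample (n-1) standard deviation and coefficient of variation
#' (`cv = sd / mean`) of the RBE values per endpoint. With a single cell
#' line the SD is undefined and emitted as `NA`, not zero.
#'
#' @param records Tibble with columns `endpoint` and `rbe` (e.g. the
#'   `records` element of an [rbe_table()]).
#'
#' @return Tibble `endpoint, n, mean, sd, cv`.
#' @export
rbe_summary <- function(records) {
  stopifnot(all(c("endpoint", "rbe") %in% names(records)))
  records |>
    dplyr::group_by(.data$endpoint) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$rbe),
      sd = if (dplyr::n() > 1) stats::sd(.data$rbe) else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(cv = .data$sd / .data$mean)
}

#' @exportS3Method generics::tidy
tidy.rbe_table <- function(x, ...) x$records

#' @exportS3Method generics::glance
glance.rbe_table <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "endpoint",
                       values_from = c("mean", "sd", "cv"), id_cols = NULL) |>
    dplyr::mutate(n_cell_lines = x$summary$n[1], .before = 1)
}

#' @export
print.rbe_table <- function(x, digits = 2, ...) {
  wide <- x$records |>
    dplyr::select("cell_line", "endpoint", "rbe") |>
    tidyr::pivot_wider(names_from = "endpoint", values_from = "rbe",
                       names_prefix = "rbe_")
  cat("<rbe_table> endpoint-wise RBEs (reference / test)\n")
  print(wide |> dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                            ~ round(.x, digits))))
  cat("\nSummary:\n")
  print(x$summary |> dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                                 ~ round(.x, digits))))
  invisible(x)
}
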