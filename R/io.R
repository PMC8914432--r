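clonogenic_cols <- c("cell_line", "quality", "dose_Gy", "cells_seeded",
                     "colonies", "replicate")

#' Read and validate a clonogenic-assay CSV
#'
#' Expects the header `cell_line,quality,dose_Gy,cells_seeded,colonies,
#' replicate`. Validation is row-diagnostic: non-numeric or negative fields
#' are reported with their row numbers, and every (cell line, quality)
#' stratum must contain at least one dose-0 control so plating efficiency is
#' computable.
#'
#' @param path Path to the CSV file.
#'
#' @return A tibble of typed clonogenic records (empty, with a warning, for
#'   a header-only file).
#' @export
read_clonogenic <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("No such file: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(
    cell_line = readr::col_character(),
    quality = readr::col_character(),
    dose_Gy = readr::col_double(),
    cells_seeded = readr::col_double(),
    colonies = readr::col_double(),
    replicate = readr::col_integer()
  ))
  missing_cols <- setdiff(clonogenic_cols, names(df))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  df <- df[clonogenic_cols]
  if (nrow(df) == 0) {
    rlang::warn("Clonogenic file contains a header but no records.")
    return(df)
  }
  probs <- readr::problems(df)
  bad <- which(!stats::complete.cases(df))
  if (nrow(probs) > 0 || length(bad) > 0) {
    rlang::abort(paste0("Non-numeric or missing fields in row(s): ",
                        paste(utils::head(unique(c(probs$row, bad)), 10),
                              collapse = ", ")))
  }
  neg <- which(df$dose_Gy < 0 | df$cells_seeded < 1 | df$colonies < 0)
  if (length(neg) > 0) {
    rlang::abort(paste0("Invalid values (negative dose/colonies or cells_seeded < 1) in row(s): ",
                        paste(utils::head(neg, 10), collapse = ", ")))
  }
  no_control <- df |>
    dplyr::group_by(.data$cell_line, .data$quality) |>
    dplyr::summarise(has0 = any(.data$dose_Gy == 0), .groups = "drop") |>
    dplyr::filter(!.data$has0)
  if (nrow(no_control) > 0) {
    rlang::abort(paste0("No dose-0 control for: ",
                        paste(no_control$cell_line, no_control$quality,
                              sep = "/", collapse = ", ")))
  }
  df
}

#' Write a clonogenic record table
#'
#' @param data Clonogenic records (see [read_clonogenic()] for the dialect).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_clonogenic <- function(data, path) {
  stopifnot(all(clonogenic_cols %in% names(data)))
  readr::write_csv(data[clonogenic_cols], path)
  invisible(path)
}

#' Read an expression matrix and its sample labels
#'
#' The expression CSV holds gene ids in the first column and one column per
#' sample; the label CSV is two columns, `sample,group`. Samples are aligned
#' to the label order.
#'
#' @param expr_path,labels_path CSV paths.
#' @return List with `expr` (matrix genes x samples) and `labels` (tibble
#'   `sample, group`).
#' @export
read_expression <- function(expr_path, labels_path) {
  edf <- readr::read_csv(expr_path, col_types = readr::cols(
    .default = readr::col_double(), gene = readr::col_character()))
  if (names(edf)[1] != "gene") {
    rlang::abort("Expression CSV must have `gene` as its first column.")
  }
  labels <- readr::read_csv(labels_path, col_types = readr::cols(
    sample = readr::col_character(), group = readr::col_character()))
  if (!all(c("sample", "group") %in% names(labels))) {
    rlang::abort("Label CSV must have columns `sample` and `group`.")
  }
  missing <- setdiff(labels$sample, names(edf)[-1])
  if (length(missing) > 0) {
    rlang::abort(paste0("Samples in labels but not in matrix: ",
                        paste(missing, collapse = ", ")))
  }
  expr <- as.matrix(edf[labels$sample])
  rownames(expr) <- edf$gene
  grp <- labels$group
  if (all(unique(grp) %in% sensitivity_levels())) {
    grp <- factor(grp, levels = sensitivity_levels())
  } else {
    grp <- factor(grp)
  }
  list(expr = expr, labels = tibble::tibble(sample = labels$sample,
                                            group = droplevels(grp)))
}

#' Write an expression matrix and its sample labels
#'
#' @param expr Matrix, genes x samples, with dimnames.
#' @param labels Tibble `sample, group` matching the matrix columns.
#' @param expr_path,labels_path Output CSV paths.
#' @return `expr_path`, invisibly.
#' @export
write_expression <- function(expr, labels, expr_path, labels_path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)),
            identical(colnames(expr), labels$sample))
  edf <- tibble::as_tibble(expr, rownames = "gene")
  readr::write_csv(edf, expr_path)
  readr::write_csv(tibble::tibble(sample = labels$sample,
                                  group = as.character(labels$group)),
                   labels_path)
  invisible(expr_path)
}

fit_cols <- c("cell_line", "quality", "a", "b", "c", "rss_log",
              "sf2", "sf35", "d10", "dbar_param", "dbar_auc", "d0")

#' Write / read survival-curve fit tables
#'
#' The fit CSV dialect is one row per (cell line, quality) curve with the
#' RCR parameters, the log-space residual sum of squares and the derived
#' radiosensitivity metrics — the column layout of [fit_survival_curves()].
#'
#' @param fits A [fit_survival_curves()] result (list-columns are dropped).
#' @param path CSV path.
#' @return `path` invisibly for the writer; a typed tibble for the reader.
#' @export
write_fits <- function(fits, path) {
  stopifnot(all(fit_cols %in% names(fits)))
  readr::write_csv(fits[fit_cols], path)
  invisible(path)
}

#' @rdname write_fits
#' @export
read_fits <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    cell_line = readr::col_character(),
    quality = readr::col_character(),
    .default = readr::col_double()))
}
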