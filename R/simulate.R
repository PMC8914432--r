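#' Design of a simulated clonogenic assay
#'
#' Describes the dose grid, seeding, plating efficiency and replication of a
#' clonogenic experiment to simulate. Defaults follow the photon dose grid
#' 0/1/2/4/6/8 Gy with cells seeded escalating geometrically from 100 at
#' 0 Gy to 10^4 at the top dose (so expected colony counts stay countable),
#' and triplicate flasks.
#'
#' @param doses Non-negative, strictly increasing dose grid in Gy; must
#'   include 0 so plating efficiency is computable downstream.
#' @param cells_seeded Positive integer vector, one per dose (recycled from a
#'   geometric escalation if `NULL`).
#' @param plating_efficiency Fraction of unirradiated cells forming colonies,
#'   in (0, 1].
#' @param replicates Number of flasks per dose, `>= 1`.
#' @param seed Optional integer seed making the simulation reproducible.
#'
#' @return A `clonogenic_design` list.
#' @export
clonogenic_design <- function(doses = c(0, 1, 2, 4, 6, 8),
                              cells_seeded = NULL,
                              plating_efficiency = 0.5,
                              replicates = 3,
                              seed = NULL) {
  if (length(doses) == 0) rlang::abort("`doses` must be non-empty.")
  if (any(doses < 0)) rlang::abort("`doses` must be non-negative.")
  if (is.unsorted(doses, strictly = TRUE)) {
    rlang::abort("`doses` must be strictly increasing (sorted, unique).")
  }
  if (plating_efficiency <= 0 || plating_efficiency > 1) {
    rlang::abort("`plating_efficiency` must lie in (0, 1].")
  }
  if (replicates < 1) rlang::abort("`replicates` must be >= 1.")
  if (is.null(cells_seeded)) {
    span <- max(doses) - min(doses)
    frac <- if (span > 0) (doses - min(doses)) / span else rep(0, length(doses))
    cells_seeded <- round(100 * (1e4 / 100)^frac)
  }
  if (length(cells_seeded) == 1) {
    cells_seeded <- rep(cells_seeded, length(doses))
  }
  if (length(cells_seeded) != length(doses) || any(cells_seeded < 1)) {
    rlang::abort("`cells_seeded` must be positive, one value per dose.")
  }
  structure(list(doses = doses, cells_seeded = as.integer(round(cells_seeded)),
                 plating_efficiency = plating_efficiency,
                 replicates = as.integer(replicates), seed = seed),
            class = "clonogenic_design")
}

#' Simulate a Poisson-noised clonogenic assay
#'
#' Draws colony counts for each flask from a Poisson law with mean
#' `cells_seeded * plating_efficiency * S(d)`, where `S` is the RCR survival
#' curve of the true parameters (S = 1 at dose 0). Colony formation is a
#' count process, so Poisson noise is the standard radiobiology assumption.
#'
#' @param true_params [rcr_params] generating the underlying survival.
#' @param design A [clonogenic_design].
#' @param cell_line,quality Identifier tags copied into the records.
#'
#' @return A tibble of clonogenic records: `cell_line, quality, dose_Gy,
#'   cells_seeded, colonies, replicate`.
#' @examples
#' sim <- simulate_clonogenic(rcr_params(0.4, 0.8, 1.2),
#'                            clonogenic_design(seed = 1))
#' head(sim)
#' @export
simulate_clonogenic <- function(true_params, design,
                                cell_line = "simulated", quality = "reference") {
  true_params <- as_rcr_params(true_params)
  if (!inherits(design, "clonogenic_design")) {
    rlang::abort("`design` must be a clonogenic_design().")
  }
  surv <- rcr_survival(true_params, design$doses)
  surv[design$doses == 0] <- 1
  grid <- tidyr::expand_grid(
    replicate = seq_len(design$replicates),
    idx = seq_along(design$doses))
  mu <- design$cells_seeded[grid$idx] * design$plating_efficiency * surv[grid$idx]
  draw <- function() stats::rpois(nrow(grid), mu)
  colonies <- if (is.null(design$seed)) draw() else withr::with_seed(design$seed, draw())
  tibble::tibble(
    cell_line = cell_line,
    quality = quality,
    dose_Gy = design$doses[grid$idx],
    cells_seeded = design$cells_seeded[grid$idx],
    colonies = colonies,
    replicate = grid$replicate
  ) |>
    dplyr::arrange(.data$replicate, .data$dose_Gy)
}

#' Design of a simulated expression matrix with radiosensitivity groups
#'
#' Describes a genes-by-samples log-intensity matrix in which a subset of
#' informative genes carries group-specific mean shifts across the four
#' radiosensitivity cohorts S/MS/MR/R, and all remaining genes are pure
#' Gaussian noise. Defaults mimic a 38-sample cell-line panel
#' (13/12/10/3 samples in S/MS/MR/R) with adjacent-group shifts of twice the
#' noise standard deviation.
#'
#' @param n_genes Total number of genes.
#' @param n_informative Number of group-informative genes, `<= n_genes`.
#' @param samples_per_group Four positive integers, samples in S, MS, MR, R.
#' @param group_shift Four per-group mean offsets (log-intensity units) added
#'   to informative genes.
#' @param noise_sd Gaussian noise standard deviation, `> 0`.
#' @param seed Optional integer seed.
#'
#' @return An `expression_design` list.
#' @export
expression_design <- function(n_genes = 1000, n_informative = 40,
                              samples_per_group = c(13, 12, 10, 3),
                              group_shift = c(0, 2, 4, 6),
                              noise_sd = 1, seed = NULL) {
  if (n_informative > n_genes) {
    rlang::abort("`n_informative` must not exceed `n_genes`.")
  }
  if (n_informative < 0 || n_genes < 1) {
    rlang::abort("`n_genes` must be >= 1 and `n_informative` >= 0.")
  }
  if (length(samples_per_group) != 4 || any(samples_per_group < 1)) {
    rlang::abort("`samples_per_group` must be four positive integers (S, MS, MR, R).")
  }
  if (length(group_shift) != 4) {
    rlang::abort("`group_shift` must have one offset per group (S, MS, MR, R).")
  }
  if (noise_sd <= 0) rlang::abort("`noise_sd` must be positive.")
  structure(list(n_genes = as.integer(n_genes),
                 n_informative = as.integer(n_informative),
                 samples_per_group = as.integer(samples_per_group),
                 group_shift = as.numeric(group_shift),
                 noise_sd = noise_sd, seed = seed),
            class = "expression_design")
}

#' Radiosensitivity cohort labels, in sensitivity order
#'
#' @return `c("S", "MS", "MR", "R")` — sensitive, moderately sensitive,
#'   moderately resistant, resistant.
#' @export
sensitivity_levels <- function() c("S", "MS", "MR", "R")

#' Simulate a group-structured expression matrix
#'
#' The first `n_informative` genes receive the per-group mean offsets of the
#' design on top of a common baseline of 8 log-intensity units; every gene
#' gets i.i.d. Gaussian noise. Sample labels follow the S/MS/MR/R scheme.
#'
#' @param design An [expression_design].
#'
#' @return A list with `expr` (numeric matrix, genes x samples, dimnames
#'   set), `labels` (tibble `sample, group` with `group` a factor levelled
#'   S < MS < MR < R) and `informative` (character vector of informative
#'   gene ids).
#' @examples
#' sim <- simulate_expression(expression_design(n_genes = 50, seed = 1))
#' dim(sim$expr)
#' @export
simulate_expression <- function(design) {
  if (!inherits(design, "expression_design")) {
    rlang::abort("`design` must be an expression_design().")
  }
  n <- sum(design$samples_per_group)
  groups <- factor(rep(sensitivity_levels(), design$samples_per_group),
                   levels = sensitivity_levels())
  genes <- sprintf("gene%04d", seq_len(design$n_genes))
  samples <- sprintf("sample%02d", seq_len(n))
  draw <- function() {
    expr <- matrix(stats::rnorm(design$n_genes * n, mean = 8,
                                sd = design$noise_sd),
                   nrow = design$n_genes, ncol = n,
                   dimnames = list(genes, samples))
    if (design$n_informative > 0) {
      shift <- design$group_shift[as.integer(groups)]
      expr[seq_len(design$n_informative), ] <-
        expr[seq_len(design$n_informative), , drop = FALSE] +
        matrix(shift, nrow = design$n_informative, ncol = n, byrow = TRUE)
    }
    expr
  }
  expr <- if (is.null(design$seed)) draw() else withr::with_seed(design$seed, draw())
  list(expr = expr,
       labels = tibble::tibble(sample = samples, group = groups),
       informative = genes[seq_len(design$n_informative)])
}

#' The 38-line HNSCC radiosensitivity panel
#'
#' Fitted surviving fractions at 2 and 3.5 Gy, plating efficiencies and
#' anatomical sites for a panel of 38 head-and-neck squamous cell carcinoma
#' cell lines assayed by clonogenic survival under photon irradiation. SF3.5
#' is the basis of the radiosensitivity cohort clustering (see
#' [cluster_sf35()]).
#'
#' @return A 38-row tibble: `cell_line, sf2, sf35, plating_efficiency, site`.
#' @examples
#' hnscc_panel()
#' @export
hnscc_panel <- function() {
  path <- system.file("extdata", "hnscc_panel.csv", package = "radresp",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    cell_line = readr::col_character(),
    sf2 = readr::col_double(),
    sf35 = readr::col_double(),
    plating_efficiency = readr::col_double(),
    site = readr::col_character()
  ))
}
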