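#' RCR survival-model parameters
#'
#' Construct the parameter triple of the repairable conditionally repairable
#' (RCR) cell-survival model,
#' \deqn{S(d) = e^{-ad} + b\,d\,e^{-cd},}
#' where `d` is dose in Gy. The first term is the fraction of cells escaping
#' lethal damage; the second is the fraction sustaining potentially lethal
#' damage that is conditionally repaired. `S(0) = 1` for every valid triple.
#'
#' @param a Per-Gy rate of the undamaged-survival exponential; `a >= 0`.
#' @param b Per-Gy amplitude of the repaired-damage term; `b >= 0`.
#' @param c Per-Gy decay rate of the repaired-damage term; `c > 0`.
#'
#' @return An object of class `rcr_params`.
#' @examples
#' p <- rcr_params(a = 0.4, b = 0.8, c = 1.2)
#' rcr_survival(p, c(0, 2, 4))
#' @export
rcr_params <- function(a, b, c) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            length(a) == 1, length(b) == 1, length(c) == 1)
  if (is.na(a) || is.na(b) || is.na(c)) {
    rlang::abort("RCR parameters must be non-missing numbers.")
  }
  if (a < 0) rlang::abort("RCR parameter `a` must be >= 0.")
  if (b < 0) rlang::abort("RCR parameter `b` must be >= 0.")
  if (c <= 0) rlang::abort("RCR parameter `c` must be > 0.")
  structure(list(a = a, b = b, c = c), class = "rcr_params")
}

#' @export
print.rcr_params <- function(x, ...) {
  cat(sprintf("<rcr_params> a = %.6g, b = %.6g, c = %.6g\n", x$a, x$b, x$c))
  invisible(x)
}

as_rcr_params <- function(x) {
  if (inherits(x, "rcr_params")) return(x)
  if (inherits(x, "rcr_fit")) return(x$params)
  if (is.numeric(x) && length(x) == 3) return(rcr_params(x[[1]], x[[2]], x[[3]]))
  rlang::abort("Cannot interpret `x` as RCR parameters.")
}

#' Evaluate RCR survival at given doses
#'
#' @param params An [rcr_params] object (or an [fit_rcr] result).
#' @param dose Numeric vector of doses in Gy; all `>= 0`.
#'
#' @return Numeric vector of surviving fractions.
#' @examples
#' rcr_survival(rcr_params(0.5, 1, 1), 2) # exp(-1) + 2*exp(-2)
#' @export
rcr_survival <- function(params, dose) {
  params <- as_rcr_params(params)
  if (!is.numeric(dose) || any(is.na(dose))) {
    rlang::abort("`dose` must be a numeric vector without missing values.")
  }
  if (any(dose < 0)) rlang::abort("`dose` must be non-negative.")
  exp(-params$a * dose) + params$b * dose * exp(-params$c * dose)
}

#' Surviving fraction from colony counts
#'
#' Converts a clonogenic-assay observation into a surviving fraction:
#' `SF = colonies / (plating_efficiency * cells_seeded)`. Values above 1 can
#' occur for noisy counts and are deliberately not clipped.
#'
#' @param colonies Non-negative colony counts.
#' @param cells_seeded Cells plated per flask; `>= 1`.
#' @param plating_efficiency Fraction of unirradiated cells forming colonies,
#'   in (0, 1].
#'
#' @return Numeric vector of surviving fractions.
#' @examples
#' compute_sf(colonies = 25, cells_seeded = 1000, plating_efficiency = 0.1)
#' @export
compute_sf <- function(colonies, cells_seeded, plating_efficiency) {
  if (any(plating_efficiency <= 0) || any(plating_efficiency > 1)) {
    rlang::abort("`plating_efficiency` must lie in (0, 1].")
  }
  if (any(cells_seeded < 1)) rlang::abort("`cells_seeded` must be >= 1.")
  if (any(colonies < 0)) rlang::abort("`colonies` must be non-negative.")
  colonies / (plating_efficiency * cells_seeded)
}

rcr_objective <- function(par, d, s, objective) {
  surv <- exp(-par[1] * d) + par[2] * d * exp(-par[3] * d)
  if (objective == "log") {
    sum((log(s) - log(surv))^2)
  } else {
    # relative (1/SF^2-weighted) least squares in linear space
    sum(((s - surv) / s)^2)
  }
}

#' Fit the RCR survival model to dose--survival data
#'
#' Minimises the sum of squared residuals of `ln SF` (default) against the RCR
#' model subject to `a >= 0`, `b >= 0`, `c > 0`, using bounded L-BFGS-B from a
#' multi-start grid: `a0` from the log-slope of the two lowest-dose points,
#' `b0` in {0, 0.5, 1, 2} and `c0` in {0.5, 1, 2, 4} times `a0`. The best
#' converged start by residual sum of squares wins; near-ties go to the
#' smaller `b` (the survival surface is multimodal in `b`/`c`).
#'
#' All replicate points are fitted jointly. Surviving fractions of exactly 0
#' cannot enter a log-space fit and are dropped with a warning; negative
#' values are rejected.
#'
#' @param data Data frame of dose--survival observations.
#' @param dose,sf Columns of `data` holding dose (Gy) and surviving fraction
#'   (tidy-eval; defaults `dose` and `sf`).
#' @param objective `"log"` (least squares on log survival, the radiobiology
#'   convention) or `"linear"` (relative least squares on the linear scale,
#'   for data containing zeros).
#' @param quality Optional radiation-quality tag stored with the fit.
#'
#' @return An object of class `rcr_fit` with elements `params`, `rss_log`,
#'   `converged`, `n_points`, `dose_range`, `quality`, `data`. Use [tidy()],
#'   [glance()] and [survival_metrics()] on it.
#' @examples
#' d <- c(0, 1, 2, 4, 6, 8)
#' df <- data.frame(dose = d, sf = rcr_survival(rcr_params(0.4, 0.8, 1.2), d))
#' fit <- fit_rcr(df)
#' tidy(fit)
#' @export
fit_rcr <- function(data, dose = dose, sf = sf,
                    objective = c("log", "linear"), quality = NULL) {
  objective <- match.arg(objective)
  stopifnot(is.data.frame(data))
  d <- dplyr::pull(data, {{ dose }})
  s <- dplyr::pull(data, {{ sf }})
  keep <- !is.na(d) & !is.na(s)
  d <- d[keep]; s <- s[keep]
  if (any(d < 0)) rlang::abort("Doses must be non-negative.")
  if (any(s < 0)) rlang::abort("Surviving fractions must be non-negative.")
  if (objective == "log" && any(s == 0)) {
    n0 <- sum(s == 0)
    rlang::warn(sprintf(
      "Dropping %d observation(s) with SF = 0 from the log-space fit; use objective = \"linear\" to keep them.",
      n0))
    d <- d[s > 0]; s <- s[s > 0]
  }
  if (length(unique(d)) < 4) {
    rlang::abort("At least 4 distinct dose levels are required to fit 3 parameters.")
  }

  # initial `a` from the log-slope across the two lowest distinct doses
  ud <- sort(unique(d))
  m <- vapply(ud[1:2], function(x) mean(s[d == x]), numeric(1))
  a0 <- -(log(m[2]) - log(max(m[1], 1e-12))) / (ud[2] - ud[1])
  if (!is.finite(a0) || a0 <= 0) a0 <- 0.1
  starts <- expand.grid(a = a0, b = c(0, 0.5, 1, 2),
                        c = a0 * c(0.5, 1, 2, 4))

  fits <- purrr::pmap(starts, function(a, b, c) {
    res <- tryCatch(
      stats::optim(c(a, b, c), rcr_objective, d = d, s = s,
                   objective = objective, method = "L-BFGS-B",
                   lower = c(0, 0, 1e-8), upper = c(50, 1e3, 50),
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    res
  })
  fits <- purrr::compact(fits)
  ok <- purrr::keep(fits, ~ .x$convergence == 0 && is.finite(.x$value))
  if (length(ok) == 0) {
    rlang::abort("RCR fit failed to converge from every start of the grid.")
  }
  vals <- purrr::map_dbl(ok, "value")
  best_val <- min(vals)
  near <- ok[vals <= best_val + 1e-9 * (1 + abs(best_val))]
  best <- near[[which.min(purrr::map_dbl(near, ~ .x$par[2]))]]

  params <- rcr_params(best$par[1], best$par[2], best$par[3])
  rss_log <- sum((log(s) - log(rcr_survival(params, d)))^2)
  structure(list(
    params = params,
    objective = objective,
    rss_log = rss_log,
    converged = TRUE,
    n_points = length(d),
    dose_range = c(0, max(d)),
    quality = quality,
    data = tibble::tibble(dose = d, sf = s)
  ), class = "rcr_fit")
}

#' @export
print.rcr_fit <- function(x, ...) {
  cat(sprintf(
    "<rcr_fit>%s  a = %.4g, b = %.4g, c = %.4g  (rss_log = %.3g, n = %d)\n",
    if (is.null(x$quality)) "" else paste0(" [", x$quality, "]"),
    x$params$a, x$params$b, x$params$c, x$rss_log, x$n_points))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.rcr_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c"),
                 estimate = c(x$params$a, x$params$b, x$params$c))
}

#' @exportS3Method generics::glance
glance.rcr_fit <- function(x, ...) {
  tibble::tibble(rss_log = x$rss_log, n_points = x$n_points,
                 d_max = x$dose_range[2], objective = x$objective,
                 converged = x$converged)
}

#' Dose at a target surviving fraction
#'
#' Finds the smallest positive dose where the RCR curve crosses `s_target`.
#' The bracket's upper bound grows geometrically until survival falls below
#' the target; a coarse scan locates the first crossing, which is then
#' polished to `|S(d) - s_target| < 1e-10`.
#'
#' @inheritParams rcr_survival
#' @param s_target Target surviving fraction in (0, 1).
#'
#' @return Dose in Gy.
#' @examples
#' dose_at_survival(rcr_params(log(10) / 5, 0, 1), 0.1) # 5 Gy
#' @export
dose_at_survival <- function(params, s_target) {
  params <- as_rcr_params(params)
  if (!is.numeric(s_target) || length(s_target) != 1 ||
      s_target <= 0 || s_target >= 1) {
    rlang::abort("`s_target` must be a single number in (0, 1).")
  }
  hi <- 1
  while (rcr_survival(params, hi) > s_target) {
    hi <- hi * 2
    if (hi > 1e6) rlang::abort("Survival never falls below `s_target`; check parameters.")
  }
  # first sign change on a coarse grid so the smallest root is bracketed
  grid <- seq(0, hi, length.out = 4097)
  sg <- rcr_survival(params, grid) - s_target
  i <- which(sg <= 0)[1]
  root <- stats::uniroot(function(d) rcr_survival(params, d) - s_target,
                         lower = grid[i - 1], upper = grid[i],
                         tol = 1e-13, maxiter = 1000)$root
  root
}

#' Mean inactivation dose from RCR parameters (closed form)
#'
#' The area under the RCR survival curve has the closed form
#' \eqn{\bar D = 1/a + b/c^2}. Requires `a > 0`; for `a = 0` the first term's
#' integral diverges.
#'
#' @inheritParams rcr_survival
#' @return Mean inactivation dose in Gy.
#' @examples
#' mean_inactivation_dose_param(rcr_params(0.5, 1, 1)) # 3 Gy
#' @export
mean_inactivation_dose_param <- function(params) {
  params <- as_rcr_params(params)
  if (params$a <= 0) {
    rlang::abort("`a` must be > 0: the survival integral diverges for a = 0.")
  }
  1 / params$a + params$b / params$c^2
}

#' Mean inactivation dose by trapezoidal area under the curve
#'
#' Trapezoidal sum of the fitted survival curve on a uniform dose grid.
#' By default the grid extends to the dose where survival drops below 1e-8
#' with a 0.01 Gy step, which reproduces the closed form to ~1e-3 Gy.
#'
#' @inheritParams rcr_survival
#' @param d_max Upper integration limit in Gy; default: dose where S < 1e-8.
#' @param step Grid step in Gy (default 0.01).
#'
#' @return Mean inactivation dose in Gy.
#' @export
mean_inactivation_dose_auc <- function(params, d_max = NULL, step = 0.01) {
  params <- as_rcr_params(params)
  if (is.null(d_max)) {
    d_max <- 1
    while (rcr_survival(params, d_max) >= 1e-8) d_max <- d_max * 2
  }
  if (step <= 0) rlang::abort("`step` must be positive.")
  if (step > d_max) rlang::abort("`step` must not exceed `d_max`.")
  grid <- seq(0, d_max, by = step)
  if (grid[length(grid)] < d_max) grid <- c(grid, d_max)
  s <- rcr_survival(params, grid)
  sum(diff(grid) * (s[-1] + s[-length(s)]) / 2)
}

#' Limiting slope D0 of the survival curve
#'
#' D0 is the dose that reduces survival e-fold on the terminal, log-linear
#' portion of the curve: `-1/slope` of an ordinary least-squares line through
#' `ln S(d)` sampled densely on a distal dose window. As the window moves out,
#' D0 approaches `1/min(a, c)` (the slower mode dominates distally).
#'
#' @inheritParams rcr_survival
#' @param window Length-2 numeric `[d_lo, d_hi]`, `d_hi > d_lo >= 0`.
#' @param n_points Number of sample points on the window.
#'
#' @return D0 in Gy, or `NA` with a warning when the fitted slope is
#'   non-negative (non-physical on the chosen window).
#' @export
limiting_slope_d0 <- function(params, window, n_points = 201) {
  params <- as_rcr_params(params)
  if (length(window) != 2 || window[2] <= window[1] || window[1] < 0) {
    rlang::abort("`window` must be [d_lo, d_hi] with d_hi > d_lo >= 0.")
  }
  d <- seq(window[1], window[2], length.out = n_points)
  y <- log(rcr_survival(params, d))
  slope <- stats::cov(d, y) / stats::var(d)
  if (slope >= 0) {
    rlang::warn("Non-physical (non-negative) log-survival slope on the window; returning NA.")
    return(NA_real_)
  }
  -1 / slope
}

#' Radiosensitivity metrics of a fitted survival curve
#'
#' Computes, from an `rcr_fit` (or raw parameters plus a maximum dose), the
#' per-curve metrics used for RBE estimation: fitted SF2 and SF3.5, the dose
#' at 10% survival (D10), the mean inactivation dose by closed form and by
#' trapezoidal AUC, and the limiting slope D0. The default D0 window is the
#' distal 40% of the data's dose range.
#'
#' @param fit An `rcr_fit`, or an [rcr_params] (then `d_max` is required).
#' @param d_max Maximum dose of the data in Gy (taken from the fit if absent).
#' @param d0_window D0 regression window; default `c(0.6, 1) * d_max`.
#' @param auc_step Trapezoid step for the AUC mean inactivation dose.
#'
#' @return A one-row tibble: `sf2, sf35, d10, dbar_param, dbar_auc, d0`.
#' @export
survival_metrics <- function(fit, d_max = NULL, d0_window = NULL,
                             auc_step = 0.01) {
  if (inherits(fit, "rcr_fit") && is.null(d_max)) d_max <- fit$dose_range[2]
  if (is.null(d_max)) {
    rlang::abort("`d_max` is required when `fit` is a bare parameter set.")
  }
  params <- as_rcr_params(fit)
  if (is.null(d0_window)) d0_window <- c(0.6 * d_max, d_max)
  tibble::tibble(
    sf2 = rcr_survival(params, 2),
    sf35 = rcr_survival(params, 3.5),
    d10 = dose_at_survival(params, 0.1),
    dbar_param = mean_inactivation_dose_param(params),
    dbar_auc = mean_inactivation_dose_auc(params, step = auc_step),
    d0 = limiting_slope_d0(params, d0_window)
  )
}

#' Fit survival curves for every cell line and radiation quality
#'
#' Groups a clonogenic record table (with surviving fractions, see
#' [clonogenic_sf()]) by cell line and quality, fits the RCR model to each
#' group, and returns one row per curve with parameters, diagnostics and the
#' derived radiosensitivity metrics.
#'
#' @param data Data frame with columns `cell_line`, `quality`, `dose_Gy`, `sf`.
#' @inheritParams fit_rcr
#'
#' @return A tibble with columns `cell_line, quality, a, b, c, rss_log, sf2,
#'   sf35, d10, dbar_param, dbar_auc, d0` and a list-column `fit`.
#' @export
fit_survival_curves <- function(data, objective = c("log", "linear")) {
  objective <- match.arg(objective)
  stopifnot(all(c("cell_line", "quality", "dose_Gy", "sf") %in% names(data)))
  data |>
    dplyr::group_by(.data$cell_line, .data$quality) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::mutate(
      fit = purrr::map(.data$data, function(df) {
        fit_rcr(df, dose = dose_Gy, sf = sf, objective = objective)
      }),
      coefs = purrr::map(.data$fit, function(f) {
        tibble::tibble(a = f$params$a, b = f$params$b, c = f$params$c,
                       rss_log = f$rss_log)
      }),
      metrics = purrr::map(.data$fit, survival_metrics)
    ) |>
    dplyr::select(-"data") |>
    tidyr::unnest(c("coefs", "metrics")) |>
    dplyr::relocate("fit", .after = dplyr::last_col())
}

#' Add surviving fractions to a clonogenic record table
#'
#' Derives each flask's surviving fraction via [compute_sf()]. The plating
#' efficiency of every (cell line, quality) stratum is estimated from its
#' dose-0 control flasks (pooled colonies over pooled cells seeded) unless
#' supplied explicitly.
#'
#' @param data Clonogenic records: `cell_line`, `quality`, `dose_Gy`,
#'   `cells_seeded`, `colonies` (and usually `replicate`).
#' @param plating_efficiency Optional data frame `cell_line, quality,
#'   plating_efficiency` overriding the dose-0 estimate.
#'
#' @return The input tibble with columns `plating_efficiency` and `sf` added.
#' @export
clonogenic_sf <- function(data, plating_efficiency = NULL) {
  stopifnot(all(c("cell_line", "quality", "dose_Gy", "cells_seeded",
                  "colonies") %in% names(data)))
  if (is.null(plating_efficiency)) {
    pe <- data |>
      dplyr::filter(.data$dose_Gy == 0) |>
      dplyr::group_by(.data$cell_line, .data$quality) |>
      dplyr::summarise(
        plating_efficiency = sum(.data$colonies) / sum(.data$cells_seeded),
        .groups = "drop")
    missing <- data |>
      dplyr::distinct(.data$cell_line, .data$quality) |>
      dplyr::anti_join(pe, by = c("cell_line", "quality"))
    if (nrow(missing) > 0) {
      rlang::abort(paste0(
        "No dose-0 control records to estimate plating efficiency for: ",
        paste(missing$cell_line, missing$quality, sep = "/", collapse = ", ")))
    }
    plating_efficiency <- pe
  }
  data |>
    dplyr::left_join(plating_efficiency, by = c("cell_line", "quality")) |>
    dplyr::mutate(sf = compute_sf(.data$colonies, .data$cells_seeded,
                                  .data$plating_efficiency)) |>
    tibble::as_tibble()
}
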