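#' In silico tumour specification
#'
#' A spherical tumour of clonogenic cells distributed equally across voxels.
#' Defaults: radius 0.6203 cm (volume 1 cm^3) holding 10^8 cells in a single
#' compartment — with uniform dose, the voxelised tumour-control sum is
#' identical for any voxel count, so one voxel is the economical default
#' while the voxel machinery stays available for heterogeneous extensions.
#'
#' @param n_cells Total clonogen count (default 1e8).
#' @param radius Tumour radius in cm (default 0.6203).
#' @param n_vox Number of voxels the cells are split across (default 1).
#'
#' @return A `tumor_spec` list with `n_cells`, `radius`, `volume` (cm^3,
#'   `4/3 * pi * radius^3`) and `n_vox`.
#' @examples
#' tumor_spec()$volume # ~= 1 cm^3
#' @export
tumor_spec <- function(n_cells = 1e8, radius = 0.6203, n_vox = 1) {
  if (n_cells < 1) rlang::abort("`n_cells` must be >= 1.")
  if (radius <= 0) rlang::abort("`radius` must be positive.")
  if (n_vox < 1) rlang::abort("`n_vox` must be >= 1.")
  structure(list(n_cells = n_cells, radius = radius,
                 volume = 4 / 3 * pi * radius^3, n_vox = as.integer(n_vox)),
            class = "tumor_spec")
}

#' Survival after n equal fractions
#'
#' Under fractionated irradiation with a constant dose per fraction `d`, the
#' surviving fraction after `n` fractions is `S(d)^n` with `S` the
#' single-fraction RCR survival. `n` may be non-integer (continuous
#' fractionation is used for dose finding).
#'
#' @inheritParams rcr_survival
#' @param d Dose per fraction in Gy, `> 0`.
#' @param n Number of fractions, real `>= 0` (vectorised).
#'
#' @return Surviving fraction(s).
#' @examples
#' survival_after_fractions(rcr_params(1, 0, 1), d = 1, n = 20) # exp(-20)
#' @export
survival_after_fractions <- function(params, d, n) {
  params <- as_rcr_params(params)
  if (length(d) != 1 || d <= 0) rlang::abort("`d` must be a single positive dose.")
  if (any(n < 0)) rlang::abort("`n` must be non-negative.")
  s1 <- rcr_survival(params, d)
  exp(n * log(s1))
}

#' Tumour control probability under fractionation
#'
#' Poisson TCP: the probability that no clonogen survives,
#' `TCP = exp(-sum_i N_i * S(d)^n)` over voxels `i` with `N_i` cells each.
#' With uniform dose and cells distributed equally, the voxel sum reduces to
#' `exp(-n_cells * S(d)^n)` for any voxel count.
#'
#' @inheritParams survival_after_fractions
#' @param tumor A [tumor_spec()].
#'
#' @return Probability in `[0, 1]` (vectorised over `n`).
#' @examples
#' tcp(rcr_params(1, 0, 1), d = 1, n = 20) # ~0.814
#' @export
tcp <- function(params, d, n, tumor = tumor_spec()) {
  stopifnot(inherits(tumor, "tumor_spec"))
  s_n <- survival_after_fractions(params, d, n)
  n_i <- tumor$n_cells / tumor$n_vox
  expected_survivors <- vapply(s_n, function(s) sum(rep(n_i, tumor$n_vox)) * s,
                               numeric(1))
  exp(-expected_survivors)
}

#' TCP curve over a fraction-number grid
#'
#' Evaluates [tcp()] across a grid of fraction numbers at a constant dose
#' per fraction. The dose axis is the physical total dose `n * d`, or the
#' photon-equivalent total `n * d * rbe` (GyE) when `dose_axis = "GyE"` and
#' an RBE is supplied.
#'
#' @inheritParams tcp
#' @param n_grid Non-negative, increasing grid of fraction numbers.
#' @param rbe RBE used for the GyE axis (required when `dose_axis = "GyE"`).
#' @param dose_axis `"physical"` or `"GyE"`.
#'
#' @return A tibble (class `tcp_curve`): `n_fractions, total_dose, tcp`,
#'   with attributes `dose_axis`, `dose_per_fraction`, `rbe`.
#' @export
tcp_curve <- function(params, d, n_grid, tumor = tumor_spec(), rbe = NULL,
                      dose_axis = c("physical", "GyE")) {
  dose_axis <- match.arg(dose_axis)
  if (length(n_grid) == 0) rlang::abort("`n_grid` must be non-empty.")
  if (any(n_grid < 0) || is.unsorted(n_grid)) {
    rlang::abort("`n_grid` must be non-negative and increasing.")
  }
  if (dose_axis == "GyE" && is.null(rbe)) {
    rlang::abort("A `rbe` is required for a GyE dose axis.")
  }
  scale <- if (dose_axis == "GyE") d * rbe else d
  out <- tibble::tibble(
    n_fractions = n_grid,
    total_dose = n_grid * scale,
    tcp = tcp(params, d, n_grid, tumor))
  attr(out, "dose_axis") <- dose_axis
  attr(out, "dose_per_fraction") <- d
  attr(out, "rbe") <- rbe
  class(out) <- c("tcp_curve", class(out))
  out
}

#' Total dose achieving a target TCP
#'
#' Solves `exp(-n_cells * S(d)^n) = target` for the continuous fraction
#' number, `n* = ln(-ln(target) / n_cells) / ln S(d)`, and returns the total
#' physical dose `n* d` (and the GyE total when an RBE is given). The
#' round trip `tcp(params, d, n*)` recovers the target to ~1e-9.
#'
#' @inheritParams tcp_curve
#' @param target Target control probability in (0, 1).
#'
#' @return One-row tibble: `n_fractions, total_physical_Gy, total_GyE`
#'   (`NA` without an RBE), `tcp_achieved`.
#' @examples
#' dose_for_tcp(rcr_params(1, 0, 1), d = 1, target = 0.7) # ~19.45 Gy
#' @export
dose_for_tcp <- function(params, d, target, tumor = tumor_spec(), rbe = NULL) {
  if (length(target) != 1 || target <= 0 || target >= 1) {
    rlang::abort("`target` must be a single probability in (0, 1).")
  }
  params <- as_rcr_params(params)
  s1 <- rcr_survival(params, d)
  if (s1 >= 1) {
    rlang::abort("Survival per fraction is >= 1 at this dose; no finite schedule reaches the target.")
  }
  n_star <- log(-log(target) / tumor$n_cells) / log(s1)
  tibble::tibble(
    n_fractions = n_star,
    total_physical_Gy = n_star * d,
    total_GyE = if (is.null(rbe)) NA_real_ else n_star * d * rbe,
    tcp_achieved = tcp(params, d, n_star, tumor))
}

#' Fixed-RBE vs. actual-RBE underdosing report
#'
#' When a photon-equivalent (GyE) prescription is converted to physical ion
#' dose with a fixed generic RBE, a cell line whose actual RBE is lower
#' receives less biological dose than prescribed. The report carries the
#' identities `physical = gye_fixed / rbe_fixed`,
#' `gye_actual = physical * rbe_actual` and
#' `difference = gye_fixed - gye_actual`, all at full precision (round only
#' for display).
#'
#' @param cell_line Identifier(s).
#' @param gye_fixed GyE prescription(s) under the fixed RBE.
#' @param rbe_actual Cell-line-specific RBE(s).
#' @param rbe_fixed Generic clinical RBE (default 3).
#'
#' @return Tibble `cell_line, gye_fixed, rbe_fixed, physical_dose_Gy,
#'   rbe_actual, gye_actual, difference_GyE`.
#' @examples
#' underdose_report("SCC9", gye_fixed = 86.9, rbe_actual = 2.55)
#' @export
underdose_report <- function(cell_line, gye_fixed, rbe_actual, rbe_fixed = 3) {
  if (any(gye_fixed <= 0) || any(rbe_actual <= 0) || any(rbe_fixed <= 0)) {
    rlang::abort("Doses and RBEs must be positive.")
  }
  physical <- gye_fixed / rbe_fixed
  gye_actual <- physical * rbe_actual
  tibble::tibble(
    cell_line = cell_line,
    gye_fixed = gye_fixed,
    rbe_fixed = rbe_fixed,
    physical_dose_Gy = physical,
    rbe_actual = rbe_actual,
    gye_actual = gye_actual,
    difference_GyE = gye_fixed - gye_actual)
}

#' Required total dose per cell line and fractionation schedule
#'
#' For each cell line's survival parameters and each schedule, finds the
#' total dose reaching the target TCP. Schedules prescribed in GyE (with an
#' attached RBE) are converted to physical dose per fraction
#' (`d = GyE / rbe`) before solving.
#'
#' @param params_by_line Named list of [rcr_params] (or `rcr_fit`s), one per
#'   cell line.
#' @param schedules Data frame: `name`, `dose_per_fraction`, `unit` (`"Gy"`
#'   or `"GyE"`), `rbe` (`NA` for physical prescriptions).
#' @param target Target TCP in (0, 1), default 0.7.
#' @param tumor A [tumor_spec()].
#'
#' @return Tibble: `cell_line, schedule, dose_per_fraction_Gy, n_fractions,
#'   total_physical_Gy, total_GyE`.
#' @export
schedule_comparison <- function(params_by_line, schedules, target = 0.7,
                                tumor = tumor_spec()) {
  stopifnot(all(c("name", "dose_per_fraction", "unit") %in% names(schedules)))
  if (!"rbe" %in% names(schedules)) schedules$rbe <- NA_real_
  purrr::imap_dfr(params_by_line, function(par, line) {
    purrr::pmap_dfr(schedules, function(name, dose_per_fraction, unit, rbe, ...) {
      if (!unit %in% c("Gy", "GyE")) {
        rlang::abort("Schedule `unit` must be \"Gy\" or \"GyE\".")
      }
      if (unit == "GyE" && (is.na(rbe) || rbe <= 0)) {
        rlang::abort(sprintf("Schedule \"%s\" is in GyE but has no valid RBE.", name))
      }
      d_phys <- if (unit == "GyE") dose_per_fraction / rbe else dose_per_fraction
      res <- dose_for_tcp(par, d_phys, target, tumor,
                          rbe = if (is.na(rbe)) NULL else rbe)
      tibble::tibble(cell_line = line, schedule = name,
                     dose_per_fraction_Gy = d_phys,
                     n_fractions = res$n_fractions,
                     total_physical_Gy = res$total_physical_Gy,
                     total_GyE = res$total_GyE)
    })
  })
}
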