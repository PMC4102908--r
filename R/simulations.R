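# Simulation experiments: control-vs-liberated comparison and sweeps over
# gap radius, stand LAI and stand height, plus the successional-stand
# scenario table. All runs are deterministic given their inputs.

#' Default gap-radius grid
#'
#' Zero (intact canopy) followed by `n` log-spaced radii from `r_min` to
#' `r_max`; gap-radius responses saturate quickly, so a log grid resolves
#' the informative small-radius region.
#'
#' @param n number of positive radii; default 16.
#' @param r_min,r_max grid range in metres; defaults 0.05 and 2.5.
#' @return numeric vector of radii (m), strictly increasing.
#' @export
default_gap_radii <- function(n = 16, r_min = 0.05, r_max = 2.5) {
  c(0, exp(seq(log(r_min), log(r_max), length.out = n)))
}

run_crown <- function(tree, physiology, stand, r_gap, sky, grid) {
  sc <- scene(tree, stand, gap_cylinder(r_gap))
  crown_photosynthesis(sc, physiology, sky, grid)
}

result_row <- function(r_gap, res) {
  data.frame(gap_radius = r_gap, Phi = res$Phi, P = res$P,
             Phi_area = res$Phi_area, P_area = res$P_area)
}

#' Liberation experiment: control vs gap
#'
#' Runs the identical scene twice, intact (`radius = 0`) and with the gap,
#' and reports both results with absolute and per-leaf-area deltas.
#'
#' @param tree a [build_tree()] object.
#' @param physiology a [species_physiology()].
#' @param stand a [vegetation_stand()].
#' @param r_gap liberation gap radius (m); the field treatment used 0.5 m.
#' @param sky a [build_sky()] model.
#' @param grid a [crown_quadrature()]; built once and shared when `NULL`.
#' @return list with `control` and `liberated` [crown_photosynthesis()]
#'   results and a one-row `delta` data frame (`dPhi`, `dP`, `dPhi_area`,
#'   `dP_area`).
#' @export
simulate_liberation <- function(tree, physiology, stand, r_gap = 0.5,
                                sky = build_sky(), grid = NULL) {
  stopifnot(r_gap >= 0)
  if (is.null(grid)) grid <- crown_quadrature(tree)
  ctrl <- run_crown(tree, physiology, stand, 0, sky, grid)
  lib <- if (r_gap == 0) ctrl else
    run_crown(tree, physiology, stand, r_gap, sky, grid)
  list(control = ctrl, liberated = lib,
       delta = data.frame(
         gap_radius = r_gap,
         dPhi = lib$Phi - ctrl$Phi, dP = lib$P - ctrl$P,
         dPhi_area = lib$Phi_area - ctrl$Phi_area,
         dP_area = lib$P_area - ctrl$P_area))
}

#' Sweep over gap radius
#'
#' Whole-crown light capture and photosynthesis across a grid of gap
#' radii, with percent-of-reference columns normalized to the value at
#' `normalization_radius` (computed additionally when it is not on the
#' grid).
#'
#' @inheritParams simulate_liberation
#' @param radii strictly increasing radii (m); default
#'   [default_gap_radii()].
#' @param normalization_radius radius whose value defines 100% (m);
#'   default 2.5.
#' @param species optional label added as a first column.
#' @return data frame with columns `gap_radius`, `Phi`, `P`, `Phi_area`,
#'   `P_area`, `Phi_pct`, `P_pct`.
#' @export
gap_radius_sweep <- function(tree, physiology, stand,
                             radii = default_gap_radii(),
                             normalization_radius = 2.5,
                             sky = build_sky(), grid = NULL,
                             species = NULL) {
  stopifnot(all(diff(radii) > 0), all(radii >= 0))
  if (is.null(grid)) grid <- crown_quadrature(tree)
  rows <- lapply(radii, function(r)
    result_row(r, run_crown(tree, physiology, stand, r, sky, grid)))
  out <- do.call(rbind, rows)
  i <- match(TRUE, abs(radii - normalization_radius) < 1e-9)
  ref <- if (!is.na(i)) out[i, ] else
    result_row(normalization_radius,
               run_crown(tree, physiology, stand, normalization_radius,
                         sky, grid))
  out$Phi_pct <- 100 * out$Phi / ref$Phi
  out$P_pct <- 100 * out$P / ref$P
  if (!is.null(species)) out <- cbind(species = species, out)
  out
}

sweep_modes <- function(mode) {
  mode <- match.arg(mode, c("both", "control", "liberated"))
  if (mode == "both") c("control", "liberated") else mode
}

#' Sweep over stand leaf area index
#'
#' Varies the LAI of the surrounding vegetation at fixed stand height, in
#' the intact (`control`) and/or gap (`liberated`, fixed radius) situation.
#'
#' @inheritParams simulate_liberation
#' @param stand_height vegetation height (m), held fixed.
#' @param lai_values LAI grid (m^2 m^-2), non-negative.
#' @param mode `"both"` (default), `"control"` or `"liberated"`.
#' @param fixed_gap_radius gap radius for the liberated mode (m),
#'   default 0.5.
#' @return data frame with columns `mode`, `lai`, `Phi`, `P`, `Phi_area`,
#'   `P_area`.
#' @export
lai_sweep <- function(tree, physiology, stand_height, lai_values,
                      mode = "both", fixed_gap_radius = 0.5,
                      sky = build_sky(), grid = NULL) {
  stopifnot(all(lai_values >= 0), stand_height > 0)
  if (is.null(grid)) grid <- crown_quadrature(tree)
  modes <- sweep_modes(mode)
  rows <- lapply(modes, function(m) {
    r <- if (m == "control") 0 else fixed_gap_radius
    do.call(rbind, lapply(lai_values, function(lai) {
      stand <- vegetation_stand(stand_height, lai)
      cbind(mode = m, lai = lai,
            result_row(r, run_crown(tree, physiology, stand, r, sky,
                                    grid)))
    }))
  })
  do.call(rbind, rows)
}

#' Sweep over stand height at constant leaf area density
#'
#' Varies the vegetation height with LAI recomputed as
#' `lad_veg * height`, so the vegetation keeps a constant leaf area
#' density while growing taller (and denser in total).
#'
#' @inheritParams lai_sweep
#' @param lad_veg vegetation leaf area density (m^2 m^-3), held constant.
#' @param heights stand height grid (m), positive.
#' @return data frame with columns `mode`, `height`, `lai`, `Phi`, `P`,
#'   `Phi_area`, `P_area`, plus attribute `first_negative`: per mode, the
#'   first grid height at which P < 0 (NA if none).
#' @export
height_sweep <- function(tree, physiology, lad_veg, heights,
                         mode = "both", fixed_gap_radius = 0.5,
                         sky = build_sky(), grid = NULL) {
  stopifnot(all(heights > 0), lad_veg >= 0)
  if (is.null(grid)) grid <- crown_quadrature(tree)
  modes <- sweep_modes(mode)
  rows <- lapply(modes, function(m) {
    r <- if (m == "control") 0 else fixed_gap_radius
    do.call(rbind, lapply(heights, function(h) {
      stand <- vegetation_stand(h, lad_veg * h)
      cbind(mode = m, height = h, lai = lad_veg * h,
            result_row(r, run_crown(tree, physiology, stand, r, sky,
                                    grid)))
    }))
  })
  out <- do.call(rbind, rows)
  first_neg <- vapply(modes, function(m) {
    p <- out[out$mode == m, ]
    i <- match(TRUE, p$P < 0)
    if (is.na(i)) NA_real_ else p$height[i]
  }, numeric(1))
  attr(out, "first_negative") <- first_neg
  out
}

#' Liberation in successional stands
#'
#' Gap-radius response of each species in each stand, with photosynthesis
#' expressed both as percent of the intact-canopy control (radius 0) and
#' as percent of the value at `normalization_radius`.
#'
#' @param species_list named list as returned by [species_setup()]; each
#'   element holds `name`, `tree`, `physiology`.
#' @param stands data frame with columns `stand`, `lai`, `height`
#'   (default [stands_table1()]).
#' @param radii gap radii to evaluate (m); 0 and `normalization_radius`
#'   are added when absent.
#' @inheritParams gap_radius_sweep
#' @return data frame with columns `stand`, `species`, `gap_radius`,
#'   `Phi`, `P`, `P_pct_control`, `P_pct_max`.
#' @export
stand_scenarios <- function(species_list = species_setup(),
                            stands = stands_table1(),
                            radii = c(0, 0.5, 1, 2.5),
                            normalization_radius = 2.5,
                            sky = build_sky(), grid_resolution = 16) {
  radii <- sort(unique(c(0, normalization_radius, radii)))
  rows <- list()
  for (i in seq_len(nrow(stands))) {
    stand <- vegetation_stand(stands$height[i], stands$lai[i])
    for (sp in species_list) {
      grid <- crown_quadrature(sp$tree, grid_resolution)
      res <- lapply(radii, function(r)
        run_crown(sp$tree, sp$physiology, stand, r, sky, grid))
      P <- vapply(res, `[[`, numeric(1), "P")
      Phi <- vapply(res, `[[`, numeric(1), "Phi")
      P0 <- P[1]
      Pmax <- P[abs(radii - normalization_radius) < 1e-9]
      rows[[length(rows) + 1L]] <- data.frame(
        stand = stands$stand[i], species = sp$name, gap_radius = radii,
        Phi = Phi, P = P,
        P_pct_control = 100 * P / P0,
        P_pct_max = 100 * P / Pmax)
    }
  }
  do.call(rbind, rows)
}
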