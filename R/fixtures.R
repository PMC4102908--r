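# Packaged parameter tables for the three Euphorbiaceae pioneer species
# (Mallotus microcarpus, Mallotus paniculatus, Macaranga denticulata) and
# the successional stands they grow in, plus a seeded synthetic-scene
# generator. Values are transcribed means +/- SE from the field study;
# golden copies live in inst/extdata/ as plain CSV.

#' Species parameter table (means +/- SE)
#'
#' Crown allometry, leaf-angle fractions (classes 15/45/75 degrees) and
#' leaf physiology of the three pioneer species in the 1.5-year-old stand.
#' The printed leaf-angle fractions of *Macaranga denticulata* sum to 1.01;
#' they are stored verbatim here and renormalized when a
#' [leaf_angle_distribution()] is built from them. Dark respiration is
#' carried in micromol m^-2 s^-1 (the printed table's "mmol" unit is a
#' typo at these magnitudes). Biomass is informational only; the model
#' does not consume it.
#'
#' @return data frame with one row per species; `se_*` columns hold the
#'   standard errors.
#' @export
species_table2 <- function() {
  data.frame(
    species = c("Mallotus microcarpus", "Mallotus paniculatus",
                "Macaranga denticulata"),
    height = c(1.26, 0.94, 1.07),
    se_height = c(0.07, 0.01, 0.03),
    biomass = c(52.70, 12.22, 27.22),
    se_biomass = c(8.48, 0.56, 1.17),
    leaf_area = c(0.29, 0.06, 0.11),
    se_leaf_area = c(0.02, 0.00, 0.00),
    frac15 = c(0.23, 0.13, 0.37),
    frac45 = c(0.48, 0.41, 0.40),
    frac75 = c(0.29, 0.46, 0.24),
    crown_volume = c(0.04, 0.01, 0.03),
    se_crown_volume = c(0.00, 0.00, 0.00),
    lw_ratio = c(1.18, 2.00, 1.42),
    se_lw_ratio = c(0.03, 0.03, 0.02),
    lad = c(6.72, 4.94, 4.35),
    se_lad = c(0.27, 0.15, 0.15),
    N_o = c(94.28, 79.33, 82.52),
    se_N_o = c(1.25, 0.84, 0.72),
    pmax_slope = c(0.17, 0.10, 0.18),
    se_pmax_slope = c(0.05, 0.05, 0.06),
    R_d = c(1.04, 0.24, 0.53),
    se_R_d = c(0.02, 0.01, 0.01),
    quantum_yield = c(0.03, 0.03, 0.04),
    se_quantum_yield = c(0.00, 0.00, 0.00)
  )
}

#' Successional stand table (means +/- SE)
#'
#' Leaf area index and canopy height of three successional vegetation
#' stands, roughly 0.5, 1 and 1.5 years after field abandonment.
#'
#' @return data frame with one row per stand.
#' @export
stands_table1 <- function() {
  data.frame(
    stand = c("I", "II", "III"),
    age_years = c(0.5, 1, 1.5),
    lai = c(3.03, 5.46, 3.73),
    se_lai = c(1.74, 0.91, 0.75),
    height = c(0.61, 0.99, 1.40),
    se_height = c(0.18, 0.31, 0.41)
  )
}

#' Observed growth of liberated and control trees (means +/- SE)
#'
#' Height and above-ground biomass growth over the 174 days following
#' liberation (gap radius 0.5 m) for the three species, by treatment.
#'
#' @return data frame with one row per species x treatment.
#' @export
growth_table3 <- function() {
  data.frame(
    species = rep(c("Mallotus microcarpus", "Mallotus paniculatus",
                    "Macaranga denticulata"), each = 2),
    treatment = rep(c("liberated", "control"), 3),
    mean_height = c(180.00, 184.82, 121.00, 139.13, 133.14, 153.65),
    se_mean_height = c(9.51, 9.27, 1.58, 2.07, 3.13, 2.72),
    height_growth = c(0.31, 0.41, 0.19, 0.28, 0.16, 0.26),
    se_height_growth = c(0.01, 0.02, 0.01, 0.01, 0.01, 0.00),
    mean_biomass = c(121.41, 93.56, 56.26, 41.12, 68.57, 54.97),
    se_mean_biomass = c(12.00, 13.79, 4.46, 2.26, 3.79, 2.87),
    biomass_growth = c(0.35, 0.28, 0.25, 0.17, 0.25, 0.16),
    se_biomass_growth = c(0.03, 0.04, 0.02, 0.01, 0.02, 0.01)
  )
}

#' Relative growth reduction (control vs liberated)
#'
#' `(control - liberated) / control` per species for a growth metric of
#' [growth_table3()]; positive values mean the liberated trees grew less.
#'
#' @param metric `"height_growth"` (cm/day) or `"biomass_growth"` (g/day).
#' @return named numeric vector, one value per species.
#' @export
relative_reduction <- function(metric = c("height_growth", "biomass_growth")) {
  metric <- match.arg(metric)
  g <- growth_table3()
  ctrl <- g[g$treatment == "control", ]
  lib <- g[g$treatment == "liberated", ]
  lib <- lib[match(ctrl$species, lib$species), ]
  stats::setNames((ctrl[[metric]] - lib[[metric]]) / ctrl[[metric]],
                  ctrl$species)
}

#' Tree geometry and physiology objects for the packaged species
#'
#' Builds [build_tree()] and [species_physiology()] objects from the
#' [species_table2()] means.
#'
#' @param species character vector of species names (default all three).
#' @param theta light-response curvature passed to the physiology objects.
#' @return named list; each element has `name`, `tree`, `physiology`.
#' @examples
#' sp <- species_setup()
#' sp[["Mallotus microcarpus"]]$tree
#' @export
species_setup <- function(species = NULL, theta = 0.7) {
  tab <- species_table2()
  if (is.null(species)) species <- tab$species
  missing <- setdiff(species, tab$species)
  if (length(missing))
    stop("unknown species: ", paste(missing, collapse = ", "))
  out <- lapply(species, function(sp) {
    r <- tab[tab$species == sp, ]
    tree <- build_tree(
      height = r$height, crown_volume = r$crown_volume,
      lw_ratio = r$lw_ratio, leaf_area = r$leaf_area, lad = r$lad,
      leaf_angles = leaf_angle_distribution(
        c(15, 45, 75), c(r$frac15, r$frac45, r$frac75)))
    phys <- species_physiology(
      N_o = r$N_o, pmax_slope = r$pmax_slope, R_d = r$R_d,
      quantum_yield = r$quantum_yield, theta = theta)
    list(name = sp, tree = tree, physiology = phys)
  })
  stats::setNames(out, species)
}

#' Stand object for a packaged successional stand
#'
#' @param label `"I"`, `"II"` or `"III"` from [stands_table1()].
#' @return a [vegetation_stand()] with spherical leaf angles.
#' @export
stand_setup <- function(label = "III") {
  tab <- stands_table1()
  r <- tab[tab$stand == label, ]
  if (nrow(r) != 1L) stop("unknown stand label: ", label)
  vegetation_stand(height = r$height, lai = r$lai)
}

#' Seeded random scene generator
#'
#' Draws a plausible young-tree scene — tree height, crown volume and
#' shape, leaf area, stand LAI and height, gap radius — uniformly within
#' `ranges`, together with a random species physiology. The crown
#' length:width ratio is truncated so the crown always fits above the
#' ground; the leaf area density is tied to `leaf_area / crown_volume`
#' within a factor \[0.5, 2\]. The caller's RNG state is left untouched.
#'
#' @param seed integer seed; the same seed reproduces the scene exactly.
#' @param ranges named list of length-2 numeric ranges; any of
#'   `tree_height`, `crown_volume`, `lw_ratio`, `leaf_area`, `stand_lai`,
#'   `stand_height`, `gap_radius`, `N_o`, `pmax_slope`, `R_d`,
#'   `quantum_yield`. Defaults cover the field ranges (heights 0.3-3 m,
#'   LAI 0-8, crown volumes 0.005-0.2 m^3).
#' @return list with `scene` and `physiology`.
#' @export
random_scene <- function(seed, ranges = list()) {
  defaults <- list(
    tree_height = c(0.3, 3), crown_volume = c(0.005, 0.2),
    lw_ratio = c(0.8, 2.5), leaf_area = c(0.02, 1),
    stand_lai = c(0, 8), stand_height = c(0.3, 3),
    gap_radius = c(0, 2.5),
    N_o = c(60, 120), pmax_slope = c(0.05, 0.25),
    R_d = c(0.1, 1.5), quantum_yield = c(0.02, 0.06))
  unknown <- setdiff(names(ranges), names(defaults))
  if (length(unknown))
    stop("unknown range name(s): ", paste(unknown, collapse = ", "))
  rg <- utils::modifyList(defaults, ranges)
  bad <- vapply(rg, function(r) length(r) != 2L || r[1] > r[2], logical(1))
  if (any(bad))
    stop("invalid range(s): ", paste(names(rg)[bad], collapse = ", "))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  h <- stats::runif(1, rg$tree_height[1], rg$tree_height[2])
  # crown fits above ground: l = (6 V rho^2 / pi)^(1/3) <= h, so the
  # volume is drawn jointly feasible with the height at the smallest
  # admissible length:width ratio
  v_hi <- min(rg$crown_volume[2], 0.95 * pi * h^3 / (6 * rg$lw_ratio[1]^2))
  if (v_hi < rg$crown_volume[1])
    stop("infeasible ranges: crown longer than tree for all lw_ratio")
  V <- stats::runif(1, rg$crown_volume[1], v_hi)
  rho_max <- sqrt(pi * h^3 / (6 * V))
  rho_hi <- min(rg$lw_ratio[2], 0.99 * rho_max)
  rho <- stats::runif(1, rg$lw_ratio[1], rho_hi)
  la <- stats::runif(1, rg$leaf_area[1], rg$leaf_area[2])
  lad <- la / V * stats::runif(1, 0.5, 2)
  tree <- build_tree(height = h, crown_volume = V, lw_ratio = rho,
                     leaf_area = la, lad = lad)
  stand <- vegetation_stand(
    height = stats::runif(1, rg$stand_height[1], rg$stand_height[2]),
    lai = stats::runif(1, rg$stand_lai[1], rg$stand_lai[2]))
  gp <- gap_cylinder(stats::runif(1, rg$gap_radius[1], rg$gap_radius[2]))
  phys <- species_physiology(
    N_o = stats::runif(1, rg$N_o[1], rg$N_o[2]),
    pmax_slope = stats::runif(1, rg$pmax_slope[1], rg$pmax_slope[2]),
    R_d = stats::runif(1, rg$R_d[1], rg$R_d[2]),
    quantum_yield = stats::runif(1, rg$quantum_yield[1],
                                 rg$quantum_yield[2]))
  list(scene = scene(tree, stand, gp), physiology = phys)
}
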