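# Structured-text configuration (YAML or JSON) and result writers.
# Units in files are metres and SI throughout; angles in degrees.

cfg_fail <- function(key, msg) stop("config error at '", key, "': ", msg,
                                    call. = FALSE)

cfg_num <- function(x, key, min = -Inf, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(NULL)
    cfg_fail(key, "missing required key")
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    cfg_fail(key, "must be a single number")
  if (x < min) cfg_fail(key, paste0("must be >= ", min))
  x
}

cfg_check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    cfg_fail(paste0(where, ".", extra[1]), "unknown key")
}

cfg_leaf_angles <- function(x, key) {
  if (is.null(x) || identical(x, "spherical"))
    return(leaf_angle_distribution("spherical"))
  cfg_check_keys(x, c("angles", "fractions"), key)
  ang <- x$angles
  fr <- x$fractions
  if (is.null(ang) || is.null(fr))
    cfg_fail(key, "needs 'angles' and 'fractions' (or the string \"spherical\")")
  if (!is.numeric(unlist(ang)) || !is.numeric(unlist(fr)))
    cfg_fail(key, "angles and fractions must be numeric")
  tryCatch(leaf_angle_distribution(unlist(ang), unlist(fr)),
           error = function(e) cfg_fail(key, conditionMessage(e)))
}

#' Read and validate a run configuration
#'
#' Parses a YAML (or JSON) configuration describing species, stand, gap,
#' sky and numerical settings, validates it against the schema (unknown
#' keys are rejected, errors name the offending key) and builds the model
#' objects.
#'
#' Schema (all lengths metres, angles degrees):
#' ```yaml
#' species:
#'   - name: Mallotus microcarpus
#'     tree: {height: 1.26, crown_volume: 0.04, lw_ratio: 1.18,
#'            leaf_area: 0.29, lad: 6.72,
#'            leaf_angle_fractions: {angles: [15, 45, 75],
#'                                   fractions: [0.23, 0.48, 0.29]}}
#'     physiology: {N_o: 94.28, pmax_slope: 0.17, R_d: 1.04,
#'                  quantum_yield: 0.03, theta: 0.7}
#' stand: {height: 1.40, lai: 3.73, leaf_angle_fractions: spherical}
#' gap: {radius: 0.5}
#' sky: {type: uoc, n_elevation: 9, n_azimuth: 12, io: 1000}
#' numerics: {crown_grid: 16}
#' ```
#' `sky` and `numerics` are optional (defaults shown); `lad` defaults to
#' `leaf_area / crown_volume`; `leaf_angle_fractions` defaults to
#' `"spherical"`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return object of class `pholiage_config`: list with `species` (a
#'   [species_setup()]-style list), `stand`, `gap`, `sky`,
#'   `grid_resolution`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE) else
      yaml::read_yaml(path)
  cfg_check_keys(raw, c("species", "stand", "gap", "sky", "numerics"),
                 "config")
  if (is.null(raw$species) || !length(raw$species))
    cfg_fail("species", "at least one species is required")
  if (is.data.frame(raw$species))      # jsonlite may simplify to a df
    raw$species <- split(raw$species, seq_len(nrow(raw$species)))

  species <- lapply(seq_along(raw$species), function(i) {
    sp <- raw$species[[i]]
    where <- paste0("species[", i, "]")
    cfg_check_keys(sp, c("name", "tree", "physiology"), where)
    if (is.null(sp$name)) cfg_fail(paste0(where, ".name"), "missing")
    tr <- sp$tree
    kt <- paste0(where, ".tree")
    if (is.null(tr)) cfg_fail(kt, "missing")
    cfg_check_keys(tr, c("height", "crown_volume", "lw_ratio", "leaf_area",
                         "lad", "leaf_angle_fractions"), kt)
    tree <- tryCatch(build_tree(
      height = cfg_num(tr$height, paste0(kt, ".height"), min = 1e-12),
      crown_volume = cfg_num(tr$crown_volume,
                             paste0(kt, ".crown_volume"), min = 1e-12),
      lw_ratio = cfg_num(tr$lw_ratio, paste0(kt, ".lw_ratio"),
                         min = 1e-12),
      leaf_area = cfg_num(tr$leaf_area, paste0(kt, ".leaf_area"),
                          min = 1e-12),
      lad = cfg_num(tr$lad, paste0(kt, ".lad"), min = 1e-12,
                    allow_null = TRUE),
      leaf_angles = cfg_leaf_angles(tr$leaf_angle_fractions,
                                    paste0(kt, ".leaf_angle_fractions"))),
      error = function(e) cfg_fail(kt, conditionMessage(e)))
    ph <- sp$physiology
    kp <- paste0(where, ".physiology")
    if (is.null(ph)) cfg_fail(kp, "missing")
    cfg_check_keys(ph, c("N_o", "pmax_slope", "R_d", "quantum_yield",
                         "theta", "pmax_intercept"), kp)
    phys <- tryCatch(species_physiology(
      N_o = cfg_num(ph$N_o, paste0(kp, ".N_o"), min = 1e-12),
      pmax_slope = cfg_num(ph$pmax_slope, paste0(kp, ".pmax_slope"),
                           min = 1e-12),
      R_d = cfg_num(ph$R_d, paste0(kp, ".R_d"), min = 0),
      quantum_yield = cfg_num(ph$quantum_yield,
                              paste0(kp, ".quantum_yield"), min = 1e-12),
      theta = cfg_num(ph$theta, paste0(kp, ".theta"), min = 0,
                      allow_null = TRUE) %||% 0.7,
      pmax_intercept = cfg_num(ph$pmax_intercept,
                               paste0(kp, ".pmax_intercept"),
                               allow_null = TRUE) %||% 0),
      error = function(e) cfg_fail(kp, conditionMessage(e)))
    list(name = sp$name, tree = tree, physiology = phys)
  })
  names(species) <- vapply(species, `[[`, character(1), "name")

  st <- raw$stand
  if (is.null(st)) cfg_fail("stand", "missing required key")
  cfg_check_keys(st, c("height", "lai", "leaf_angle_fractions"), "stand")
  stand <- vegetation_stand(
    height = cfg_num(st$height, "stand.height", min = 1e-12),
    lai = cfg_num(st$lai, "stand.lai", min = 0),
    leaf_angles = cfg_leaf_angles(st$leaf_angle_fractions,
                                  "stand.leaf_angle_fractions"))

  gp <- raw$gap
  if (is.null(gp)) cfg_fail("gap", "missing required key")
  cfg_check_keys(gp, "radius", "gap")
  gap <- gap_cylinder(cfg_num(gp$radius, "gap.radius", min = 0))

  sk <- raw$sky
  if (!is.null(sk))
    cfg_check_keys(sk, c("type", "n_elevation", "n_azimuth", "io"), "sky")
  sky_type <- sk$type %||% "uoc"
  if (!sky_type %in% c("uoc", "soc")) cfg_fail("sky.type", "must be uoc or soc")
  sky <- build_sky(
    n_elevation = cfg_num(sk$n_elevation, "sky.n_elevation",
                          min = 1, allow_null = TRUE) %||% 9,
    n_azimuth = cfg_num(sk$n_azimuth, "sky.n_azimuth",
                        min = 1, allow_null = TRUE) %||% 12,
    sky_type = sky_type,
    I_o = cfg_num(sk$io, "sky.io", min = 0, allow_null = TRUE) %||% 1000)

  nm <- raw$numerics
  if (!is.null(nm)) cfg_check_keys(nm, "crown_grid", "numerics")
  grid_resolution <- cfg_num(nm$crown_grid, "numerics.crown_grid",
                             min = 2, allow_null = TRUE) %||% 16

  out <- list(species = species, stand = stand, gap = gap, sky = sky,
              grid_resolution = grid_resolution)
  class(out) <- "pholiage_config"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the liberation comparison described by a configuration
#'
#' Evaluates each configured species in the configured stand, intact and
#' with the configured gap, and returns a tidy table.
#'
#' @param config a [read_config()] object.
#' @return data frame with columns `species`, `gap_radius`, `Phi_umol_s`,
#'   `P_umol_s`, `Phi_area`, `P_area` (one control and one liberated row
#'   per species).
#' @export
run_config <- function(config) {
  stopifnot(inherits(config, "pholiage_config"))
  rows <- lapply(config$species, function(sp) {
    grid <- crown_quadrature(sp$tree, config$grid_resolution)
    lib <- simulate_liberation(sp$tree, sp$physiology, config$stand,
                               r_gap = config$gap$radius,
                               sky = config$sky, grid = grid)
    data.frame(
      species = sp$name,
      gap_radius = c(0, config$gap$radius),
      Phi_umol_s = c(lib$control$Phi, lib$liberated$Phi),
      P_umol_s = c(lib$control$P, lib$liberated$P),
      Phi_area = c(lib$control$Phi_area, lib$liberated$Phi_area),
      P_area = c(lib$control$P_area, lib$liberated$P_area))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a result table to CSV or JSON
#'
#' CSV is comma-separated UTF-8 with a `.` decimal mark and a mandatory
#' header row; JSON is an array of row objects. [read_results()] inverts
#' either format without loss.
#'
#' @param table a data frame.
#' @param path output path.
#' @param format `"csv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(table))
  if (format == "csv") {
    utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(table, path, dataframe = "rows", digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path path to a `.csv` or `.json` result file.
#' @return data frame.
#' @export
read_results <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  else
    utils::read.csv(path, fileEncoding = "UTF-8")
}
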