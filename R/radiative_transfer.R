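# Radiative transfer: discretized overcast sky, leaf-angle projection
# (G) functions, Beer-Lambert transmittance along rays, absorbed PPFD at
# crown points and whole-crown light capture.

# ---- sky model ----------------------------------------------------------

#' Discretize an overcast sky hemisphere
#'
#' The hemisphere is split into `n_elevation` rings of equal solid angle
#' (uniform spacing in sin(elevation)), each cut into `n_azimuth` sectors.
#' Each sector carries a beam of irradiance `B_s` (on a plane normal to the
#' beam) from its centroid direction. Radiance is constant for the uniform
#' overcast sky (`"uoc"`) and proportional to `(1 + 2 sin(beta)) / 3` for
#' the standard overcast sky (`"soc"`, brighter at the zenith by 3:1).
#' Beams are normalized so the horizontal irradiance above the canopy,
#' `sum(B_s * sin(beta_s))`, equals `I_o` exactly.
#'
#' The horizon ring has positive mid-elevation, so no sector sits at
#' elevation zero.
#'
#' @param n_elevation number of elevation rings (>= 1).
#' @param n_azimuth number of azimuth sectors per ring (>= 1).
#' @param sky_type `"uoc"` (default) or `"soc"`.
#' @param I_o horizontal photosynthetic photon flux density above the
#'   canopy (micromol m^-2 s^-1); default 1000.
#' @return an object of class `sky_model`: a data frame of sectors with
#'   columns `elevation`, `azimuth` (degrees), `B` (beam irradiance), and
#'   attributes `sky_type`, `I_o`.
#' @examples
#' sky <- build_sky(9, 12)
#' sum(sky$B * sin(sky$elevation * pi / 180))  # = 1000
#' @export
build_sky <- function(n_elevation = 9, n_azimuth = 12,
                      sky_type = c("uoc", "soc"), I_o = 1000) {
  sky_type <- match.arg(sky_type)
  stopifnot(n_elevation >= 1, n_azimuth >= 1, is.numeric(I_o), I_o >= 0)
  # ring i spans sin(beta) in [(i-1)/n, i/n]; centroid at the midpoint
  sin_mid <- (seq_len(n_elevation) - 0.5) / n_elevation
  beta <- asin(sin_mid)                      # radians
  az <- (seq_len(n_azimuth) - 0.5) * 2 * pi / n_azimuth
  grid <- expand.grid(beta = beta, az = az)
  d_omega <- 2 * pi / (n_elevation * n_azimuth)
  radiance <- switch(sky_type,
                     uoc = rep(1, nrow(grid)),
                     soc = (1 + 2 * sin(grid$beta)) / 3)
  B <- radiance * d_omega
  norm <- sum(B * sin(grid$beta))
  B <- if (norm > 0) B * I_o / norm else B * 0
  out <- data.frame(elevation = grid$beta * 180 / pi,
                    azimuth = grid$az * 180 / pi,
                    B = B)
  attr(out, "sky_type") <- sky_type
  attr(out, "I_o") <- I_o
  class(out) <- c("sky_model", "data.frame")
  out
}

# n x 3 matrix of unit beam directions (from the sector toward the scene
# reversed: stored as the upward direction a ray travels toward the sector)
sky_directions <- function(sky) {
  b <- sky$elevation * pi / 180
  a <- sky$azimuth * pi / 180
  cbind(cos(b) * cos(a), cos(b) * sin(a), sin(b))
}

# ---- projection (G) functions ------------------------------------------

#' Projection of a single leaf inclination class onto a beam
#'
#' Mean of |cos(angle between leaf normal and beam)| over uniformly
#' distributed leaf azimuth, for leaves inclined `alpha` degrees from
#' horizontal and a beam at elevation `beta` degrees. Closed form:
#' `cos(alpha) sin(beta)` when `beta >= alpha`, else
#' `(2/pi) * (sin(beta) cos(alpha) asin(tan(beta)/tan(alpha)) +
#' sqrt(sin(alpha)^2 - sin(beta)^2))`.
#'
#' @param alpha leaf inclination from horizontal, degrees in \[0, 90\].
#' @param beta beam elevation, degrees in (0, 90\]. Vectorized over both.
#' @return dimensionless projection G.
#' @examples
#' projection_single(0, 30)    # horizontal leaves: sin(30 deg) = 0.5
#' projection_single(45, 90)   # vertical beam: cos(45 deg)
#' @export
projection_single <- function(alpha, beta) {
  stopifnot(all(alpha >= 0 & alpha <= 90), all(beta > 0 & beta <= 90))
  n <- max(length(alpha), length(beta))
  alpha <- rep_len(alpha * pi / 180, n)
  beta <- rep_len(beta * pi / 180, n)
  g <- cos(alpha) * sin(beta)
  steep <- beta < alpha
  if (any(steep)) {
    a <- alpha[steep]; b <- beta[steep]
    g[steep] <- (2 / pi) *
      (sin(b) * cos(a) * asin(tan(b) / tan(a)) +
         sqrt(pmax(0, sin(a)^2 - sin(b)^2)))
  }
  g
}

#' Projection function of a leaf angle distribution
#'
#' Fraction-weighted sum of [projection_single()] over the inclination
#' classes; the spherical preset returns 1/2 exactly for all elevations.
#'
#' @param leaf_angles a [leaf_angle_distribution()].
#' @param beta beam elevation, degrees in (0, 90\]; vectorized.
#' @return dimensionless G, same length as `beta`.
#' @export
g_function <- function(leaf_angles, beta) {
  stopifnot(is_leaf_angle_distribution(leaf_angles))
  if (leaf_angles$spherical) return(rep(0.5, length(beta)))
  vapply(beta, function(b)
    sum(leaf_angles$fractions * projection_single(leaf_angles$angles, b)),
    numeric(1))
}

# ---- transmittance and absorbed light ----------------------------------

#' Beam transmittance from a point to the sky
#'
#' Beer-Lambert transmittance through the vegetation and the tree's own
#' crown along an upward ray: `T = exp(-a (G_veg lad_veg s_veg +
#' G_tree lad_tree s_crown))` with path lengths from the scene geometry,
#' projection functions at the beam elevation, and leaf absorptance
#' multiplier `a` (1 for black leaves).
#'
#' @param origin length-3 point (m).
#' @param direction upward unit vector.
#' @param scene a [scene()].
#' @return transmittance in \[0, 1\].
#' @export
beam_transmittance <- function(origin, direction, scene) {
  stopifnot(inherits(scene, "scene"))
  direction <- check_ray(origin, direction)
  beta <- asin(direction[3]) * 180 / pi
  p <- scene_path_lengths(matrix(origin, 1), direction, scene)
  gv <- g_function(scene$stand$leaf_angles, beta)
  gt <- g_function(scene$tree$leaf_angles, beta)
  exp(-scene$absorptance *
        (gv * scene$stand$lad_veg * p$s_veg +
           gt * scene$tree$lad * p$s_crown))
}

# Absorbed PPFD per unit leaf area at many points at once.
# Returns list(phi_p, rel_light, phi_top).
crown_field <- function(points, scene, sky) {
  dirs <- sky_directions(sky)
  gt <- g_function(scene$tree$leaf_angles, sky$elevation)
  gv <- g_function(scene$stand$leaf_angles, sky$elevation)
  kt <- scene$absorptance * scene$tree$lad
  kv <- scene$absorptance * scene$stand$lad_veg
  phi <- numeric(nrow(points))
  for (s in seq_len(nrow(sky))) {
    p <- scene_path_lengths(points, dirs[s, ], scene)
    tau <- exp(-(gv[s] * kv * p$s_veg + gt[s] * kt * p$s_crown))
    phi <- phi + sky$B[s] * gt[s] * tau
  }
  phi_top <- sum(sky$B * gt)
  list(phi_p = phi,
       rel_light = if (phi_top > 0) phi / phi_top else phi * 0,
       phi_top = phi_top)
}

#' Absorbed PPFD and relative light at a crown point
#'
#' Sums absorbed flux over all sky sectors: `phi_p = sum(B_s G_tree(beta_s)
#' T_s)`. The relative light `I/I_o` is referenced to an unshaded leaf with
#' the same angle distribution (`phi_top = sum(B_s G_tree(beta_s))`), so a
#' fully exposed point has `rel_light = 1`.
#'
#' @param point length-3 position (m), normally inside the crown.
#' @param scene a [scene()].
#' @param sky a [build_sky()] model.
#' @return list with `phi_p` (micromol m^-2 s^-1), `rel_light` in \[0, 1\]
#'   and `phi_top`.
#' @export
point_absorbed_ppfd <- function(point, scene, sky) {
  stopifnot(inherits(scene, "scene"), inherits(sky, "sky_model"),
            is.numeric(point), length(point) == 3L)
  f <- crown_field(matrix(point, 1), scene, sky)
  list(phi_p = f$phi_p[1], rel_light = min(1, f$rel_light[1]),
       phi_top = f$phi_top)
}

# ---- crown quadrature ---------------------------------------------------

#' Volume quadrature over the crown ellipsoid
#'
#' Product rule in ball coordinates mapped to the ellipsoid: Gauss-Legendre
#' nodes in radius (weighted r^2) and in the cosine of the polar angle,
#' midpoint nodes in azimuth, `resolution` nodes per axis. Weights sum to
#' the crown volume exactly (up to round-off).
#'
#' @param tree a [build_tree()] object.
#' @param resolution nodes per axis (>= 2); default 16.
#' @return object of class `crown_quadrature`: list with `points`
#'   (n x 3 matrix, m) and `weights` (m^3).
#' @export
crown_quadrature <- function(tree, resolution = 16) {
  stopifnot(inherits(tree, "tree_geometry"), resolution >= 2)
  ell <- crown_ellipsoid(tree)
  gr <- pracma::gaussLegendre(resolution, 0, 1)     # radius in [0,1]
  gm <- pracma::gaussLegendre(resolution, -1, 1)    # cos(polar)
  phi <- (seq_len(resolution) - 0.5) * 2 * pi / resolution
  w_phi <- 2 * pi / resolution
  g <- expand.grid(ir = seq_len(resolution), im = seq_len(resolution),
                   ip = seq_len(resolution))
  r <- gr$x[g$ir]; mu <- gm$x[g$im]; ph <- phi[g$ip]
  st <- sqrt(1 - mu^2)
  ux <- r * st * cos(ph); uy <- r * st * sin(ph); uz <- r * mu
  pts <- cbind(ell$center[1] + ell$semi[1] * ux,
               ell$center[2] + ell$semi[2] * uy,
               ell$center[3] + ell$semi[3] * uz)
  w <- gr$w[g$ir] * r^2 * gm$w[g$im] * w_phi * prod(ell$semi)
  out <- list(points = pts, weights = w, resolution = resolution)
  class(out) <- "crown_quadrature"
  out
}

# ---- whole-crown light capture -----------------------------------------

#' Whole-crown light capture
#'
#' Integrates absorbed PPFD over the crown:
#' `Phi = leaf_area * mean_V(phi_p)` (micromol photons s^-1), the
#' volume-weighted mean absorbed rate times the crown's leaf area, and the
#' size-corrected rate per unit leaf area `Phi_area = Phi / leaf_area`.
#'
#' The crown's optical density (self-shading) is set by `lad`; the leaf
#' area carrying the absorbed flux is `leaf_area`. When the two are
#' consistent (`lad = leaf_area / V`) this is exactly
#' `sum_p w_p lad phi_p`; keeping them separate lets group-mean parameter
#' tables, where the mean lad and mean leaf area do not multiply out,
#' preserve both measured quantities.
#'
#' @param scene a [scene()] (the tree inside it is the target crown).
#' @param sky a [build_sky()] model.
#' @param grid a [crown_quadrature()]; built at the default resolution
#'   when `NULL`.
#' @return list with `Phi`, `Phi_area`, `phi_top` and the `grid` used.
#' @export
crown_light_capture <- function(scene, sky, grid = NULL) {
  stopifnot(inherits(scene, "scene"), inherits(sky, "sky_model"))
  if (is.null(grid)) grid <- crown_quadrature(scene$tree)
  f <- crown_field(grid$points, scene, sky)
  mean_phi <- sum(grid$weights * f$phi_p) / sum(grid$weights)
  Phi <- scene$tree$leaf_area * mean_phi
  list(Phi = Phi, Phi_area = Phi / scene$tree$leaf_area,
       phi_top = f$phi_top, grid = grid)
}
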