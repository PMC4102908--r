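# Scene geometry: ellipsoidal tree crown, homogeneous vegetation slab,
# cylindrical liberation gap, and the ray path-length computations the
# light model consumes.
#
# Frame: z up, ground at z = 0, all lengths in metres. The stem axis sits
# at tree$stem_xy (default the horizontal origin); the gap cylinder shares
# that axis. Angles are degrees at the interface, radians internally.

# ---- leaf angle distribution -------------------------------------------

#' Leaf angle distribution over inclination classes
#'
#' Discrete distribution of one-sided leaf area over leaf inclination
#' classes (angle of the blade from horizontal), with uniformly distributed
#' leaf azimuth within a class. The preset `"spherical"` denotes the
#' spherical (uniform over the sphere) distribution, for which the
#' projection function is exactly 1/2 at all beam elevations.
#'
#' Fraction vectors are accepted when they sum to 1 within 0.01 (field
#' tables are often printed to two decimals) and renormalized to sum to 1
#' exactly.
#'
#' @param angles numeric vector of class midpoint inclinations in degrees
#'   (each in \[0, 90\]), or the string `"spherical"`.
#' @param fractions fraction of leaf area in each class; same length as
#'   `angles`, each in \[0, 1\].
#' @return an object of class `leaf_angle_distribution`.
#' @examples
#' leaf_angle_distribution("spherical")
#' leaf_angle_distribution(c(15, 45, 75), c(0.23, 0.48, 0.29))
#' @export
leaf_angle_distribution <- function(angles, fractions = NULL) {
  if (is.character(angles)) {
    if (length(angles) != 1L || angles != "spherical")
      stop("unknown leaf angle preset: ", angles)
    out <- list(spherical = TRUE, angles = numeric(0), fractions = numeric(0))
    class(out) <- "leaf_angle_distribution"
    return(out)
  }
  stopifnot(is.numeric(angles), is.numeric(fractions),
            length(angles) == length(fractions), length(angles) >= 1L)
  if (any(angles < 0 | angles > 90))
    stop("leaf inclination angles must lie in [0, 90] degrees")
  if (any(fractions < 0 | fractions > 1))
    stop("leaf angle fractions must lie in [0, 1]")
  s <- sum(fractions)
  if (abs(s - 1) > 0.01 + 1e-9)
    stop("leaf angle fractions must sum to 1 (got ", format(s), ")")
  out <- list(spherical = FALSE, angles = as.numeric(angles),
              fractions = as.numeric(fractions) / s)
  class(out) <- "leaf_angle_distribution"
  out
}

#' @export
print.leaf_angle_distribution <- function(x, ...) {
  if (x$spherical) {
    cat("Leaf angle distribution: spherical\n")
  } else {
    cat("Leaf angle distribution:\n")
    print(stats::setNames(round(x$fractions, 4), paste0(x$angles, "°")))
  }
  invisible(x)
}

is_leaf_angle_distribution <- function(x) inherits(x, "leaf_angle_distribution")

# ---- tree geometry ------------------------------------------------------

#' Build an ellipsoidal tree crown from volume and length:width ratio
#'
#' Crown dimensions of young trees are commonly summarized as crown volume
#' V and the length:width ratio rho of the (axisymmetric) ellipsoid, from
#' which the width and length follow as `w = (6 V / (pi rho))^(1/3)` and
#' `l = rho w`. The crown is attached at the top of the stem, so its base
#' sits at `height - l`.
#'
#' @param height total tree height, ground to crown top (m).
#' @param crown_volume crown ellipsoid volume V (m^3).
#' @param lw_ratio crown length:width ratio rho (dimensionless).
#' @param leaf_area one-sided leaf area of the crown (m^2).
#' @param lad leaf area density within the crown (m^2 m^-3); defaults to
#'   `leaf_area / crown_volume`. A warning is issued when `leaf_area`
#'   differs from `lad * crown_volume` by more than a factor 2 (group-mean
#'   parameter tables are internally inconsistent at that level).
#' @param leaf_angles a [leaf_angle_distribution()]; default spherical.
#' @param stem_xy horizontal stem position (m), length-2 numeric.
#' @return an object of class `tree_geometry` with fields `stem_xy`,
#'   `height_total`, `crown_length`, `crown_width`, `crown_base`,
#'   `crown_volume`, `leaf_area`, `lad`, `leaf_angles`.
#' @examples
#' # unit ellipsoid: V = pi/6, rho = 1 gives w = l = 1
#' build_tree(height = 2, crown_volume = pi / 6, lw_ratio = 1, leaf_area = 1)
#' @export
build_tree <- function(height, crown_volume, lw_ratio, leaf_area,
                       lad = NULL,
                       leaf_angles = leaf_angle_distribution("spherical"),
                       stem_xy = c(0, 0)) {
  stopifnot(is.numeric(height), height > 0,
            is.numeric(crown_volume), crown_volume > 0,
            is.numeric(lw_ratio), lw_ratio > 0,
            is.numeric(leaf_area), leaf_area > 0,
            is_leaf_angle_distribution(leaf_angles),
            is.numeric(stem_xy), length(stem_xy) == 2L)
  w <- (6 * crown_volume / (pi * lw_ratio))^(1 / 3)
  l <- lw_ratio * w
  if (l > height + 1e-12)
    stop("crown longer than tree height (crown length ",
         format(l), " m > height ", format(height), " m)")
  crown_base <- height - l
  if (is.null(lad)) lad <- leaf_area / crown_volume
  stopifnot(is.numeric(lad), lad > 0)
  implied <- lad * crown_volume
  if (leaf_area > 2 * implied || leaf_area < implied / 2)
    warning("leaf_area (", format(leaf_area),
            " m^2) differs from lad * crown_volume (", format(implied),
            " m^2) by more than a factor 2")
  out <- list(stem_xy = as.numeric(stem_xy), height_total = height,
              crown_length = l, crown_width = w, crown_base = crown_base,
              crown_volume = crown_volume, leaf_area = leaf_area,
              lad = lad, leaf_angles = leaf_angles)
  class(out) <- "tree_geometry"
  out
}

#' @export
print.tree_geometry <- function(x, ...) {
  cat(sprintf(paste0(
    "Tree crown: height %.3g m, crown %.3g m long x %.3g m wide ",
    "(base %.3g m)\n  leaf area %.3g m^2, lad %.3g m^2 m^-3\n"),
    x$height_total, x$crown_length, x$crown_width, x$crown_base,
    x$leaf_area, x$lad))
  invisible(x)
}

# semi-axes (a, a, c) and centre of the crown ellipsoid
crown_ellipsoid <- function(tree) {
  list(center = c(tree$stem_xy, tree$crown_base + tree$crown_length / 2),
       semi = c(tree$crown_width / 2, tree$crown_width / 2,
                tree$crown_length / 2))
}

# ---- vegetation stand and gap ------------------------------------------

#' Homogeneous vegetation stand (turbid slab)
#'
#' The vegetation surrounding the tree is a horizontally homogeneous layer
#' from the ground to `height`, with uniform leaf area density
#' `lai / height`.
#'
#' @param height stand canopy height (m).
#' @param lai leaf area index of the stand (m^2 m^-2).
#' @param leaf_angles a [leaf_angle_distribution()]; default spherical.
#' @return an object of class `vegetation_stand` with fields `height`,
#'   `lai`, `lad_veg`, `leaf_angles`.
#' @export
vegetation_stand <- function(height, lai,
                             leaf_angles = leaf_angle_distribution("spherical")) {
  stopifnot(is.numeric(height), height > 0, is.numeric(lai), lai >= 0,
            is_leaf_angle_distribution(leaf_angles))
  out <- list(height = height, lai = lai, lad_veg = lai / height,
              leaf_angles = leaf_angles)
  class(out) <- "vegetation_stand"
  out
}

#' Cylindrical liberation gap
#'
#' Vertical cylinder of cleared vegetation, axis through the stem, from the
#' soil to the top of the vegetation layer. `radius = 0` is the intact
#' (control) canopy.
#'
#' @param radius gap radius (m), >= 0.
#' @return an object of class `gap_cylinder`.
#' @export
gap_cylinder <- function(radius = 0) {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius >= 0)
  out <- list(radius = radius)
  class(out) <- "gap_cylinder"
  out
}

#' Assemble a scene: tree, stand and gap
#'
#' The vegetation turbid medium occupies the slab `0 <= z <= stand$height`
#' minus the gap cylinder and minus the crown ellipsoid — the crown
#' displaces vegetation rather than adding to it, so foliage is never
#' counted twice.
#'
#' @param tree a [build_tree()] object.
#' @param stand a [vegetation_stand()].
#' @param gap a [gap_cylinder()]; default no gap.
#' @param absorptance leaf absorptance multiplier applied to the extinction
#'   coefficients; default 1 (black, fully absorbing leaves).
#' @return an object of class `scene`.
#' @export
scene <- function(tree, stand, gap = gap_cylinder(0), absorptance = 1) {
  stopifnot(inherits(tree, "tree_geometry"),
            inherits(stand, "vegetation_stand"),
            inherits(gap, "gap_cylinder"),
            is.numeric(absorptance), absorptance > 0, absorptance <= 1)
  out <- list(tree = tree, stand = stand, gap = gap,
              absorptance = absorptance)
  class(out) <- "scene"
  out
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf(paste0(
    "Scene: stand %.3g m tall, LAI %.3g; gap radius %.3g m\n"),
    x$stand$height, x$stand$lai, x$gap$radius))
  print(x$tree)
  invisible(x)
}

# ---- ray utilities ------------------------------------------------------

check_ray <- function(origin, direction) {
  stopifnot(is.numeric(origin), length(origin) == 3L,
            is.numeric(direction), length(direction) == 3L)
  n <- sqrt(sum(direction^2))
  if (abs(n - 1) > 1e-9) direction <- direction / n
  if (direction[3] <= 0)
    stop("ray direction must point upward (positive z component)")
  direction
}

# direction from elevation/azimuth in degrees
ray_direction <- function(elevation, azimuth = 0) {
  b <- elevation * pi / 180
  a <- azimuth * pi / 180
  c(cos(b) * cos(a), cos(b) * sin(a), sin(b))
}

# ---- vectorized t-interval primitives ----------------------------------
# Each takes an n x 3 matrix of origins O and one unit direction d with
# d[3] > 0, and returns an n x 2 matrix of [t_lo, t_hi] clipped to t >= 0;
# empty intersections collapse to t_lo = t_hi.

interval_empty <- function(n) matrix(0, n, 2)

iv_clip_nonneg <- function(iv) {
  iv[, 1] <- pmax(iv[, 1], 0)
  iv[, 2] <- pmax(iv[, 2], iv[, 1])
  iv
}

iv_len <- function(iv) pmax(0, iv[, 2] - iv[, 1])

iv_intersect <- function(a, b) {
  lo <- pmax(a[, 1], b[, 1])
  hi <- pmin(a[, 2], b[, 2])
  cbind(lo, pmax(hi, lo))
}

# slab 0 <= z <= z_top
iv_slab <- function(O, d, z_top) {
  dz <- d[3]
  t_lo <- pmax(0, (0 - O[, 3]) / dz)
  t_hi <- (z_top - O[, 3]) / dz
  bad <- t_hi < t_lo
  t_hi[bad] <- t_lo[bad]
  cbind(t_lo, t_hi)
}

# axis-aligned ellipsoid with given centre and semi-axes
iv_ellipsoid <- function(O, d, center, semi) {
  n <- nrow(O)
  px <- (O[, 1] - center[1]) / semi[1]
  py <- (O[, 2] - center[2]) / semi[2]
  pz <- (O[, 3] - center[3]) / semi[3]
  dx <- d[1] / semi[1]; dy <- d[2] / semi[2]; dz <- d[3] / semi[3]
  a <- dx^2 + dy^2 + dz^2
  b <- 2 * (px * dx + py * dy + pz * dz)
  cc <- px^2 + py^2 + pz^2 - 1
  disc <- b^2 - 4 * a * cc
  iv <- interval_empty(n)
  hit <- disc > 0
  if (any(hit)) {
    sq <- sqrt(disc[hit])
    t1 <- (-b[hit] - sq) / (2 * a)
    t2 <- (-b[hit] + sq) / (2 * a)
    iv[hit, 1] <- t1
    iv[hit, 2] <- t2
  }
  iv_clip_nonneg(iv)
}

# infinite vertical cylinder, axis at cxy, radius r
iv_cylinder <- function(O, d, cxy, r) {
  n <- nrow(O)
  if (r <= 0) return(interval_empty(n))
  px <- O[, 1] - cxy[1]
  py <- O[, 2] - cxy[2]
  a <- d[1]^2 + d[2]^2
  iv <- interval_empty(n)
  if (a < 1e-24) {
    inside <- px^2 + py^2 < r^2
    iv[inside, 2] <- Inf
    return(iv)
  }
  b <- 2 * (px * d[1] + py * d[2])
  cc <- px^2 + py^2 - r^2
  disc <- b^2 - 4 * a * cc
  hit <- disc > 0
  if (any(hit)) {
    sq <- sqrt(disc[hit])
    iv[hit, 1] <- (-b[hit] - sq) / (2 * a)
    iv[hit, 2] <- (-b[hit] + sq) / (2 * a)
  }
  iv_clip_nonneg(iv)
}

# Vectorized path lengths through each medium for origins O along unit
# direction d. Returns s_veg (vegetation), s_crown (full crown chord from
# the origin, used for within-crown self-shading), s_gap and s_slab.
scene_path_lengths <- function(O, d, scene) {
  ell <- crown_ellipsoid(scene$tree)
  slab <- iv_slab(O, d, scene$stand$height)
  crn <- iv_ellipsoid(O, d, ell$center, ell$semi)
  gp <- iv_cylinder(O, d, scene$tree$stem_xy, scene$gap$radius)
  crn_s <- iv_intersect(crn, slab)
  gp_s <- iv_intersect(gp, slab)
  both <- iv_intersect(crn_s, gp_s)
  union_len <- iv_len(crn_s) + iv_len(gp_s) - iv_len(both)
  s_veg <- pmax(0, iv_len(slab) - union_len)
  list(s_veg = s_veg, s_crown = iv_len(crn), s_gap = iv_len(gp_s),
       s_slab = iv_len(slab), s_crown_slab = iv_len(crn_s),
       s_overlap = iv_len(both))
}

# ---- public scalar path operations -------------------------------------

#' Ray path length through the vegetation slab
#'
#' Length of the ray segment (from `origin`, upward unit `direction`) with
#' `0 <= z <= z_top`. Zero when the origin lies above the slab.
#'
#' @param origin length-3 numeric point (m).
#' @param direction length-3 upward unit vector.
#' @param z_top slab top (m), > 0.
#' @return path length (m).
#' @export
ray_slab_path <- function(origin, direction, z_top) {
  stopifnot(is.numeric(z_top), z_top > 0)
  direction <- check_ray(origin, direction)
  iv_len(iv_slab(matrix(origin, 1), direction, z_top))[1]
}

#' Ray chord length inside the crown ellipsoid
#'
#' Length of the ray beyond `origin` lying inside the crown of `tree`
#' (0 when the ray misses the crown). The quadratic is solved in
#' ellipsoid-normalized coordinates.
#'
#' @inheritParams ray_slab_path
#' @param tree a [build_tree()] object.
#' @return chord length (m).
#' @export
ray_ellipsoid_chord <- function(origin, direction, tree) {
  stopifnot(inherits(tree, "tree_geometry"))
  ell <- crown_ellipsoid(tree)
  if (any(ell$semi <= 0)) stop("degenerate ellipsoid axes")
  direction <- check_ray(origin, direction)
  iv_len(iv_ellipsoid(matrix(origin, 1), direction, ell$center, ell$semi))[1]
}

#' Ray path length inside the gap cylinder
#'
#' Length of the ray inside the vertical cylinder of the gap, clipped to
#' `0 <= z <= z_top`.
#'
#' @inheritParams ray_slab_path
#' @param gap a [gap_cylinder()] or a numeric radius (m).
#' @param center horizontal axis position (m); default origin of the frame.
#' @return path length (m).
#' @export
ray_cylinder_path <- function(origin, direction, gap, z_top,
                              center = c(0, 0)) {
  r <- if (inherits(gap, "gap_cylinder")) gap$radius else gap
  stopifnot(is.numeric(r), r >= 0, is.numeric(z_top), z_top > 0)
  direction <- check_ray(origin, direction)
  O <- matrix(origin, 1)
  iv <- iv_intersect(iv_cylinder(O, direction, center, r),
                     iv_slab(O, direction, z_top))
  iv_len(iv)[1]
}

#' Ray path length through the vegetation turbid medium of a scene
#'
#' Slab path minus the parts lying inside the gap cylinder or the crown
#' ellipsoid (their union, so overlap of gap and crown is not subtracted
#' twice); never negative.
#'
#' @inheritParams ray_slab_path
#' @param scene a [scene()].
#' @return path length (m).
#' @export
vegetation_path_length <- function(origin, direction, scene) {
  stopifnot(inherits(scene, "scene"))
  direction <- check_ray(origin, direction)
  scene_path_lengths(matrix(origin, 1), direction, scene)$s_veg[1]
}
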