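# Independent oracles and shared fixtures for the test suite.
#
# The oracles deliberately use different formulations from the package:
# a fixed-step marching integrator for path lengths, boundary-sorting
# (segment classification by midpoint membership) for media paths, and
# Monte-Carlo estimators for the projection function and whole-crown
# light capture.

# ---- fixtures -----------------------------------------------------------

fixture_stand3 <- function() vegetation_stand(1.40, 3.73)

# a self-consistent tree (lad * V = leaf_area) for identity checks
fixture_consistent_tree <- function(lad = 5, height = 1.2,
                                    crown_volume = 0.03, lw_ratio = 1.4) {
  build_tree(height = height, crown_volume = crown_volume,
             lw_ratio = lw_ratio, leaf_area = lad * crown_volume,
             lad = lad)
}

random_upward_dir <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-6) {
      v <- v / n
      if (abs(v[3]) > 0.05) {
        v[3] <- abs(v[3])
        return(v)
      }
    }
  }
}

# ---- marching integrator ------------------------------------------------

# Path length along origin + t*dir (t >= 0) through {inside(p) == TRUE},
# fixed step, midpoint sampling. t_max must cover the geometry.
march_length <- function(origin, dir, inside, t_max, step = 1e-3) {
  ts <- seq(step / 2, t_max, by = step)
  pts <- cbind(origin[1] + ts * dir[1],
               origin[2] + ts * dir[2],
               origin[3] + ts * dir[3])
  sum(inside(pts)) * step
}

inside_slab <- function(z_top) function(p) p[, 3] >= 0 & p[, 3] <= z_top

inside_ellipsoid <- function(tree) {
  cz <- tree$crown_base + tree$crown_length / 2
  a <- tree$crown_width / 2
  c_ <- tree$crown_length / 2
  cx <- tree$stem_xy[1]; cy <- tree$stem_xy[2]
  function(p) ((p[, 1] - cx) / a)^2 + ((p[, 2] - cy) / a)^2 +
    ((p[, 3] - cz) / c_)^2 <= 1
}

inside_cylinder <- function(center, r) function(p)
  (p[, 1] - center[1])^2 + (p[, 2] - center[2])^2 <= r^2

inside_vegetation <- function(scene) {
  slab <- inside_slab(scene$stand$height)
  crown <- inside_ellipsoid(scene$tree)
  gapin <- inside_cylinder(scene$tree$stem_xy, scene$gap$radius)
  function(p) slab(p) & !crown(p) & !gapin(p)
}

# t needed to leave the slab upward, with margin
slab_t_max <- function(origin, dir, z_top)
  max(0, (z_top - origin[3]) / dir[3]) + 0.5

# ---- boundary-sorting media paths (scalar, analytic, independent) ------

quad_roots <- function(a, b, cc) {
  if (abs(a) < 1e-300) return(numeric(0))
  z <- polyroot(c(cc, b, a))
  z <- z[abs(Im(z)) < 1e-8]
  sort(Re(z))
}

# returns list(s_veg, s_crown) for one ray; s_crown is the full chord
media_paths_oracle <- function(origin, dir, scene) {
  tree <- scene$tree
  z_top <- scene$stand$height
  cz <- tree$crown_base + tree$crown_length / 2
  a <- tree$crown_width / 2
  c_ <- tree$crown_length / 2

  cuts <- c(0, (0 - origin[3]) / dir[3], (z_top - origin[3]) / dir[3])
  px <- (origin[1] - tree$stem_xy[1]) / a
  py <- (origin[2] - tree$stem_xy[2]) / a
  pz <- (origin[3] - cz) / c_
  dx <- dir[1] / a; dy <- dir[2] / a; dz <- dir[3] / c_
  cuts <- c(cuts, quad_roots(dx^2 + dy^2 + dz^2,
                             2 * (px * dx + py * dy + pz * dz),
                             px^2 + py^2 + pz^2 - 1))
  if (scene$gap$radius > 0) {
    gx <- origin[1] - tree$stem_xy[1]
    gy <- origin[2] - tree$stem_xy[2]
    cuts <- c(cuts, quad_roots(dir[1]^2 + dir[2]^2,
                               2 * (gx * dir[1] + gy * dir[2]),
                               gx^2 + gy^2 - scene$gap$radius^2))
  }
  t_end <- slab_t_max(origin, dir, z_top) +
    tree$crown_length + tree$crown_width
  cuts <- sort(unique(c(pmax(0, cuts), t_end)))
  cuts <- cuts[cuts <= t_end + 1e-12]
  if (length(cuts) < 2) return(list(s_veg = 0, s_crown = 0))

  veg <- inside_vegetation(scene)
  crown <- inside_ellipsoid(tree)
  s_veg <- 0; s_crown <- 0
  for (i in seq_len(length(cuts) - 1)) {
    tm <- (cuts[i] + cuts[i + 1]) / 2
    p <- matrix(origin + tm * dir, 1)
    len <- cuts[i + 1] - cuts[i]
    if (crown(p)) s_crown <- s_crown + len
    if (veg(p)) s_veg <- s_veg + len
  }
  list(s_veg = s_veg, s_crown = s_crown)
}

# ---- Monte-Carlo oracles ------------------------------------------------

# mean |cos(leaf normal, beam)| over uniform leaf azimuth
mc_projection <- function(alpha_deg, beta_deg, n = 1e6, seed = 42) {
  set.seed(seed)
  a <- alpha_deg * pi / 180
  b <- beta_deg * pi / 180
  phi <- stats::runif(n, 0, 2 * pi)
  mean(abs(sin(a) * cos(b) * cos(phi) + cos(a) * sin(b)))
}

# uniform points in the crown ellipsoid (rejection from the unit ball box)
mc_crown_points <- function(tree, n) {
  cz <- tree$crown_base + tree$crown_length / 2
  pts <- matrix(NA_real_, n, 3)
  got <- 0
  while (got < n) {
    m <- 2 * (n - got)
    u <- matrix(stats::runif(3 * m, -1, 1), m, 3)
    keep <- rowSums(u^2) <= 1
    k <- min(sum(keep), n - got)
    if (k > 0) {
      u <- u[keep, , drop = FALSE][seq_len(k), , drop = FALSE]
      pts[got + seq_len(k), ] <- cbind(
        tree$stem_xy[1] + u[, 1] * tree$crown_width / 2,
        tree$stem_xy[2] + u[, 2] * tree$crown_width / 2,
        cz + u[, 3] * tree$crown_length / 2)
      got <- got + k
    }
  }
  pts
}

# Continuous-sky Monte-Carlo whole-crown light capture (uniform overcast:
# radiance I_o / pi). One uniform-hemisphere direction per crown point;
# phi estimate per sample is 2 * I_o * G_tree(beta) * tau.
mc_crown_capture <- function(scene, I_o = 1000, n = 4e4, seed = 7) {
  set.seed(seed)
  tree <- scene$tree
  pts <- mc_crown_points(tree, n)
  z <- stats::runif(n)                      # cos(zenith) uniform => uniform solid angle
  az <- stats::runif(n, 0, 2 * pi)
  st <- sqrt(1 - z^2)
  est <- numeric(n)
  for (i in seq_len(n)) {
    d <- c(st[i] * cos(az[i]), st[i] * sin(az[i]), z[i])
    beta <- asin(z[i]) * 180 / pi
    pth <- media_paths_oracle(pts[i, ], d, scene)
    gt <- g_function(tree$leaf_angles, beta)
    gv <- g_function(scene$stand$leaf_angles, beta)
    tau <- exp(-(gv * scene$stand$lad_veg * pth$s_veg +
                   gt * tree$lad * pth$s_crown))
    est[i] <- 2 * I_o * gt * tau
  }
  list(Phi = tree$leaf_area * mean(est),
       se = tree$leaf_area * stats::sd(est) / sqrt(n))
}
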