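# Geometry of the scene: crown reconstruction from volume and shape,
# and ray path lengths through slab, ellipsoid, cylinder and the
# composite vegetation medium.

test_that("crown dimensions are reconstructed from volume and l:w ratio", {
  # unit ellipsoid identity
  t1 <- build_tree(height = 2, crown_volume = pi / 6, lw_ratio = 1,
                   leaf_area = 1)
  expect_equal(t1$crown_width, 1)
  expect_equal(t1$crown_length, 1)
  expect_equal(t1$crown_base, 1)
  expect_equal((pi / 6) * t1$crown_length * t1$crown_width^2,
               t1$crown_volume, tolerance = 1e-9)

  # M. microcarpus means: w = (6 * 0.04 / (pi * 1.18))^(1/3)
  t2 <- build_tree(height = 1.26, crown_volume = 0.04, lw_ratio = 1.18,
                   leaf_area = 0.29, lad = 6.72)
  w_expect <- (6 * 0.04 / (pi * 1.18))^(1 / 3)
  expect_equal(t2$crown_width, w_expect, tolerance = 1e-12)
  expect_equal(t2$crown_length, 1.18 * w_expect, tolerance = 1e-12)
  expect_equal(round(t2$crown_width, 3), 0.402)
  expect_equal(round(t2$crown_length, 3), 0.474)

  # lad defaults to leaf_area / V
  t3 <- build_tree(height = 1.26, crown_volume = 0.04, lw_ratio = 1.18,
                   leaf_area = 0.29)
  expect_equal(t3$lad, 0.29 / 0.04)

  expect_error(build_tree(height = 0.4, crown_volume = 0.04,
                          lw_ratio = 1.18, leaf_area = 0.29),
               "crown longer than tree height")
  expect_warning(build_tree(height = 2, crown_volume = 0.04, lw_ratio = 1,
                            leaf_area = 0.5, lad = 1),
                 "factor 2")
})

test_that("slab path follows 1/sin(elevation) and vanishes above the slab", {
  expect_equal(ray_slab_path(c(0, 0, 0), c(0, 0, 1), 1.4), 1.4)
  expect_equal(ray_slab_path(c(0, 0, 0), ray_direction(30), 1.4),
               1.4 / sin(pi / 6), tolerance = 1e-12)
  expect_equal(ray_slab_path(c(0, 0, 2), c(0, 0, 1), 1.4), 0)
  expect_equal(ray_slab_path(c(0.3, -0.2, 0.4), c(0, 0, 1), 1.4), 1.0)
  expect_error(ray_slab_path(c(0, 0, 0), c(0, 0, -1), 1.4), "upward")
})

test_that("ellipsoid chords match closed-form and marching oracle", {
  sphere <- build_tree(height = 2, crown_volume = pi / 6 * 8, lw_ratio = 1,
                       leaf_area = 1)   # unit-radius sphere, centre z = 1
  expect_equal(ray_ellipsoid_chord(c(0, 0, 1), c(0, 0, 1), sphere), 1)
  expect_equal(ray_ellipsoid_chord(c(0, 0, 2), c(0, 0, 1), sphere), 0)

  tree <- build_tree(height = 1.26, crown_volume = 0.04, lw_ratio = 1.18,
                     leaf_area = 0.29)
  inside <- inside_ellipsoid(tree)
  set.seed(101)
  for (i in 1:25) {
    o <- c(stats::runif(2, -0.3, 0.3), stats::runif(1, 0.6, 1.3))
    d <- random_upward_dir()
    expect_lt(abs(ray_ellipsoid_chord(o, d, tree) -
                    march_length(o, d, inside, t_max = 2)), 2e-3)
  }
})

test_that("gap cylinder paths match trivial cases and marching oracle", {
  tree <- build_tree(height = 1.26, crown_volume = 0.04, lw_ratio = 1.18,
                     leaf_area = 0.29)
  expect_equal(ray_cylinder_path(c(0, 0, 0), c(0, 0, 1),
                                 gap_cylinder(0), 1.4), 0)
  set.seed(5)
  for (i in 1:5)
    expect_equal(ray_cylinder_path(c(0.1, 0, 0.2), random_upward_dir(),
                                   gap_cylinder(0), 1.4), 0)
  expect_equal(ray_cylinder_path(c(0, 0, 0), c(0, 0, 1),
                                 gap_cylinder(0.5), 1.4), 1.4)
  set.seed(77)
  for (i in 1:25) {
    o <- c(stats::runif(2, -1, 1), stats::runif(1, 0, 1.3))
    d <- random_upward_dir()
    r <- stats::runif(1, 0.1, 1.5)
    both <- function(p) inside_cylinder(c(0, 0), r)(p) &
      inside_slab(1.4)(p)
    expect_lt(abs(ray_cylinder_path(o, d, gap_cylinder(r), 1.4) -
                    march_length(o, d, both,
                                 t_max = slab_t_max(o, d, 1.4) + 3)), 2e-3)
  }
})

test_that("vegetation path composes media correctly", {
  tree <- build_tree(height = 1.26, crown_volume = 0.04, lw_ratio = 1.18,
                     leaf_area = 0.29)
  sc <- scene(tree, fixture_stand3(), gap_cylinder(0.5))

  # at the slab top every upward ray leaves immediately
  expect_equal(vegetation_path_length(c(0.7, 0, 1.4), c(0, 0, 1), sc), 0)
  set.seed(3)
  expect_equal(vegetation_path_length(c(0.7, 0, 1.4), random_upward_dir(),
                                      sc), 0)
  # vertical ray up the stem axis: gap, then crown, never vegetation
  expect_equal(vegetation_path_length(c(0, 0, 0), c(0, 0, 1), sc), 0)

  set.seed(202)
  for (i in 1:25) {
    o <- c(stats::runif(2, -1, 1), stats::runif(1, 0, 1.35))
    d <- random_upward_dir()
    r <- stats::runif(1, 0, 1)
    sc_i <- scene(tree, fixture_stand3(), gap_cylinder(r))
    expect_lt(abs(vegetation_path_length(o, d, sc_i) -
                    march_length(o, d, inside_vegetation(sc_i),
                                 t_max = slab_t_max(o, d, 1.4) + 3)), 5e-3)
  }
})

test_that("media path lengths partition the slab path", {
  tree <- build_tree(height = 1.26, crown_volume = 0.04, lw_ratio = 1.18,
                     leaf_area = 0.29)
  stand <- fixture_stand3()
  set.seed(11)
  for (i in 1:40) {
    o <- c(stats::runif(2, -1, 1), stats::runif(1, 0, 1.35))
    d <- random_upward_dir()
    r <- stats::runif(1, 0, 1.2)
    sc <- scene(tree, stand, gap_cylinder(r))
    p <- pholiage:::scene_path_lengths(matrix(o, 1), d, sc)
    slab <- ray_slab_path(o, d, stand$height)
    # generalized partition: veg + gap + crown-in-slab - overlap = slab
    expect_equal(p$s_veg + p$s_gap + p$s_crown_slab - p$s_overlap,
                 slab, tolerance = 1e-9)
    expect_true(p$s_veg >= 0 && p$s_veg <= slab + 1e-12)
  }
  # literal three-way partition when gap and crown cannot overlap
  sc0 <- scene(tree, stand, gap_cylinder(0))
  o <- c(0.1, -0.2, 0.3); d <- ray_direction(40, 120)
  p0 <- pholiage:::scene_path_lengths(matrix(o, 1), d, sc0)
  expect_equal(p0$s_veg + p0$s_gap + p0$s_crown_slab,
               ray_slab_path(o, d, stand$height), tolerance = 1e-12)
  short <- build_tree(height = 0.4, crown_volume = 0.002, lw_ratio = 1,
                      leaf_area = 0.01, stem_xy = c(3, 0))
  sc_sep <- scene(short, stand, gap_cylinder(0.5))   # crown outside gap
  o2 <- c(2.8, 0, 0.05); d2 <- ray_direction(25, 5)
  p2 <- pholiage:::scene_path_lengths(matrix(o2, 1), d2, sc_sep)
  expect_equal(p2$s_overlap, 0)
  expect_equal(p2$s_veg + p2$s_gap + p2$s_crown_slab,
               ray_slab_path(o2, d2, stand$height), tolerance = 1e-12)
})

test_that("zero-radius gap reproduces the intact canopy bit-exactly", {
  tree <- build_tree(height = 1.26, crown_volume = 0.04, lw_ratio = 1.18,
                     leaf_area = 0.29)
  sc0 <- scene(tree, fixture_stand3(), gap_cylinder(0))
  set.seed(9)
  for (i in 1:20) {
    o <- c(stats::runif(2, -1, 1), stats::runif(1, 0, 1.3))
    d <- random_upward_dir()
    v0 <- vegetation_path_length(o, d, sc0)
    # a gap object of radius 0 must not enter the computation at all
    expect_identical(v0, ray_slab_path(o, d, 1.4) -
                       pholiage:::iv_len(pholiage:::iv_intersect(
                         pholiage:::iv_ellipsoid(
                           matrix(o, 1), d,
                           pholiage:::crown_ellipsoid(tree)$center,
                           pholiage:::crown_ellipsoid(tree)$semi),
                         pholiage:::iv_slab(matrix(o, 1), d, 1.4)))[1])
  }
})

test_that("geometry is invariant under horizontal translation and rotation", {
  stand <- fixture_stand3()
  shift <- c(1.7, -2.3)
  tree0 <- build_tree(height = 1.26, crown_volume = 0.04, lw_ratio = 1.18,
                      leaf_area = 0.29)
  tree1 <- build_tree(height = 1.26, crown_volume = 0.04, lw_ratio = 1.18,
                      leaf_area = 0.29, stem_xy = shift)
  sc0 <- scene(tree0, stand, gap_cylinder(0.4))
  sc1 <- scene(tree1, stand, gap_cylinder(0.4))
  rot <- function(v, ang) c(cos(ang) * v[1] - sin(ang) * v[2],
                            sin(ang) * v[1] + cos(ang) * v[2], v[3])
  set.seed(31)
  for (i in 1:15) {
    o <- c(stats::runif(2, -0.8, 0.8), stats::runif(1, 0, 1.3))
    d <- random_upward_dir()
    expect_equal(vegetation_path_length(c(o[1:2] + shift, o[3]), d, sc1),
                 vegetation_path_length(o, d, sc0), tolerance = 1e-12)
    ang <- stats::runif(1, 0, 2 * pi)
    expect_equal(vegetation_path_length(rot(o, ang), rot(d, ang), sc0),
                 vegetation_path_length(o, d, sc0), tolerance = 1e-9)
  }
})

test_that("leaf angle distributions validate and renormalize", {
  expect_error(leaf_angle_distribution(c(15, 45), c(0.9, 0.3)), "sum to 1")
  expect_error(leaf_angle_distribution(c(-5, 45, 75), c(0.3, 0.3, 0.4)),
               "\\[0, 90\\]")
  expect_error(leaf_angle_distribution("planophile"), "unknown")
  lad <- leaf_angle_distribution(c(15, 45, 75), c(0.37, 0.40, 0.24))
  expect_equal(sum(lad$fractions), 1, tolerance = 1e-12)
  expect_true(leaf_angle_distribution("spherical")$spherical)
})
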