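test_that("centroid is the component-wise mean", {
  expect_equal(centroid(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
  expect_equal(centroid(c(3, -1, 2)), c(3, -1, 2)) # single point: identity
  set.seed(41)
  pts <- matrix(rnorm(15), ncol = 3)
  # direct-summation oracle
  expect_equal(centroid(pts), c(sum(pts[, 1]), sum(pts[, 2]), sum(pts[, 3])) / 5)
  expect_error(centroid(matrix(numeric(0), ncol = 3)), "empty")
})

test_that("build_interface_frame orients the plane toward the partner", {
  f <- build_interface_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), toward = c(0, 0, 5))
  expect_equal(f$normal, c(0, 0, 1))
  expect_equal(f$face_center, c(1, 1, 0) / 3)

  flipped <- build_interface_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), toward = c(0, 0, -5))
  expect_equal(flipped$normal, c(0, 0, -1))
})

test_that("interface-frame normals are unit and orthogonal to the centroid edges", {
  set.seed(11)
  for (i in 1:25) {
    s <- rnorm(3, sd = 4); l <- rnorm(3, sd = 4); cc <- rnorm(3, sd = 4)
    area <- sqrt(sum((l - s)^2) * sum((cc - s)^2) - sum((l - s) * (cc - s))^2) / 2
    if (!is.finite(area) || area < 1e-3) next
    f <- build_interface_frame(s, l, cc, toward = c(0, 0, 50))
    expect_equal(sqrt(sum(f$normal^2)), 1, tolerance = 1e-12)
    expect_lt(abs(sum(f$normal * (l - s))), 1e-10)
    expect_lt(abs(sum(f$normal * (cc - s))), 1e-10)
    expect_equal(f$face_center, (s + l + cc) / 3)
  }
})

test_that("collinear centroids raise a degenerate-geometry error", {
  expect_error(
    build_interface_frame(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), toward = c(0, 0, 1)),
    "collinear"
  )
})

test_that("plane_angle is the unsigned inter-plane angle in [0, 90]", {
  f1 <- build_interface_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), toward = c(0, 0, 1))
  expect_equal(plane_angle(f1, f1), 0)

  f2 <- build_interface_frame(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1), toward = c(1, 0, 0))
  expect_equal(plane_angle(f1, f2), 90)

  # constructed 10-degree rotation about x
  th <- 10 * pi / 180
  f3 <- build_interface_frame(c(0, 0, 0), c(1, 0, 0),
    c(0, cos(th), sin(th)), toward = c(0, -sin(th), cos(th)))
  expect_equal(plane_angle(f1, f3), 10, tolerance = 1e-9)

  # orientation-independence: flipping one normal changes nothing
  f4 <- f3
  f4$normal <- -f4$normal
  expect_equal(plane_angle(f1, f4), plane_angle(f1, f3))
})

test_that("height_over_plane is the signed toward-partner distance", {
  plane <- build_interface_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), toward = c(0, 0, 1))
  expect_equal(height_over_plane(c(0.3, 0.2, 0), plane), 0) # on-plane point
  expect_equal(height_over_plane(c(3, 4, 2), plane), 2)
  expect_equal(height_over_plane(c(3, 4, -2), plane), -2)

  # explicit plane-equation oracle on a random plane
  set.seed(5)
  for (i in 1:10) {
    pr <- random_frame_pair()
    p <- rnorm(3, sd = 6)
    n <- pr$a$normal; d <- -sum(n * pr$a$face_center)
    expect_equal(height_over_plane(p, pr$a), sum(n * p) + d, tolerance = 1e-12)
  }
})

test_that("lateral_shift is the in-plane projection distance", {
  plane <- build_interface_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), toward = c(0, 0, 1))
  expect_equal(lateral_shift(c(0, 0, 7), c(0, 0, 0), plane), 0) # directly above
  expect_equal(lateral_shift(c(3, 4, 7), c(0, 0, 0), plane), 5) # 3-4-5 triangle

  # decomposition oracle: ||(p - h n) - ref||
  set.seed(6)
  for (i in 1:10) {
    pr <- random_frame_pair()
    p <- rnorm(3, sd = 6); ref <- rnorm(3, sd = 6)
    h <- height_over_plane(p, pr$a)
    expect_equal(
      lateral_shift(p, ref, pr$a),
      sqrt(sum((p - h * pr$a$normal - ref)^2)),
      tolerance = 1e-12
    )
  }
})

make_parallel_pair <- function(gap = 10, shear = 0) {
  # B = A translated by gap along +z and shear along +y, parallel faces
  a_pts <- rbind(c(6, 0, 0), c(-3, 5, 0), c(-3, -5, 0))
  b_pts <- sweep(a_pts, 2, c(0, shear, gap), `+`)
  fa <- colMeans(a_pts); fb <- colMeans(b_pts)
  list(
    a = build_interface_frame(a_pts[1, ], a_pts[2, ], a_pts[3, ], toward = fb),
    b = build_interface_frame(b_pts[1, ], b_pts[2, ], b_pts[3, ], toward = fa)
  )
}

test_that("mirror-symmetric parallel faces give the symmetry-forced descriptors", {
  pr <- make_parallel_pair(gap = 10)
  d <- compute_descriptors(pr$a, pr$b)
  expect_equal(d$angleAB, 0)
  expect_equal(d$heightFaceAB, 10)
  expect_equal(d$distFace, 10)
  expect_equal(d$shiftFaceAB, 0)

  # laterally translated by 3 A: Pythagoras oracle
  pr3 <- make_parallel_pair(gap = 10, shear = 3)
  d3 <- compute_descriptors(pr3$a, pr3$b)
  expect_equal(d3$shiftFaceAB, 3)
  expect_equal(d3$heightFaceAB, 10)
  expect_equal(d3$distFace, sqrt(109))
})

test_that("descriptors are exactly A/B symmetric", {
  set.seed(21)
  for (i in 1:20) {
    pr <- random_frame_pair()
    expect_identical(
      compute_descriptors(pr$a, pr$b),
      compute_descriptors(pr$b, pr$a)[, descriptor_names()]
    )
  }
})

test_that("descriptors are invariant under global rigid motions", {
  set.seed(22)
  for (i in 1:20) {
    pr <- random_frame_pair()
    d0 <- compute_descriptors(pr$a, pr$b)
    rot <- random_rotation(); tr <- rnorm(3, sd = 20)
    move <- function(pts) sweep(pts %*% t(rot), 2, tr, `+`)
    am <- move(pr$a_pts); bm <- move(pr$b_pts)
    a2 <- build_interface_frame(am[1, ], am[2, ], am[3, ], toward = colMeans(bm))
    b2 <- build_interface_frame(bm[1, ], bm[2, ], bm[3, ], toward = colMeans(am))
    d1 <- compute_descriptors(a2, b2)
    expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
  }
})

test_that("descriptor ranges hold and parallel faces obey Pythagoras", {
  set.seed(23)
  for (i in 1:20) {
    pr <- random_frame_pair()
    d <- compute_descriptors(pr$a, pr$b)
    expect_gte(d$angleAB, 0); expect_lte(d$angleAB, 90)
    expect_gte(d$distFace, 0)
    expect_gte(d$shiftFaceAB, 0)
    expect_gte(d$shiftSL_AB, 0)
    expect_gte(d$shiftLS_AB, 0)
  }
  for (shear in c(0, 1.5, 4)) {
    d <- compute_descriptors(make_parallel_pair(12, shear)$a,
      make_parallel_pair(12, shear)$b)
    expect_equal(d$heightFaceAB^2 + d$shiftFaceAB^2, d$distFace^2, tolerance = 1e-9)
  }
})
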