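# shared fixture builders for the test suite

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  r <- qr.Q(qr_)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# apply one global rigid motion (rotation + translation) to an atom table
apply_rigid <- function(atoms, rot, trans) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
  atoms$x <- xyz[, 1] + trans[1]
  atoms$y <- xyz[, 2] + trans[2]
  atoms$z <- xyz[, 3] + trans[3]
  atoms
}

# a random non-degenerate pair of interface frames facing each other
random_frame_pair <- function() {
  repeat {
    a_pts <- matrix(rnorm(9, sd = 5), 3)
    b_pts <- matrix(rnorm(9, sd = 5), 3) + matrix(rep(c(0, 0, 15), each = 3), 3)
    fa <- colMeans(a_pts); fb <- colMeans(b_pts)
    a <- try(build_interface_frame(a_pts[1, ], a_pts[2, ], a_pts[3, ], toward = fb),
      silent = TRUE)
    b <- try(build_interface_frame(b_pts[1, ], b_pts[2, ], b_pts[3, ], toward = fa),
      silent = TRUE)
    if (!inherits(a, "try-error") && !inherits(b, "try-error")) {
      return(list(a = a, b = b, a_pts = a_pts, b_pts = b_pts))
    }
  }
}

# random geometry spec with non-collinear random element offsets
random_geometry_spec <- function(seed) {
  set.seed(seed)
  repeat {
    off <- matrix(rnorm(6, sd = 4), ncol = 2)
    sp <- try(
      dimer_geometry(
        angle_deg = runif(1, 0, 90),
        face_gap = runif(1, 4, 20),
        lateral_shear = runif(1, 0, 8),
        element_offsets = off,
        seed = seed
      ),
      silent = TRUE
    )
    if (!inherits(sp, "try-error")) return(sp)
  }
}

descriptor_matrix <- function(series) {
  as.matrix(series[, descriptor_names()])
}
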