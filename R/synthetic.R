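#' Geometry specification for a synthetic LBD dimer
#'
#' Describes a two-subunit fixture whose S/L/C element centroids realise a
#' prescribed interface geometry exactly: the two planes tilted symmetrically
#' by `angle_deg` about an in-plane axis, face centers separated by
#' `face_gap` along the mean normal and sheared laterally by
#' `lateral_shear`, with optional per-frame isotropic Gaussian jitter on the
#' atoms. Serves as the stand-in for MD trajectories, with analytic ground
#' truth.
#'
#' @param angle_deg Inter-plane angle in degrees, in \[0, 90\].
#' @param face_gap Separation of the face centers along the mean normal, Å
#'   (> 0).
#' @param lateral_shear In-plane displacement of the two face centers, Å
#'   (>= 0).
#' @param element_offsets 3 x 2 matrix of in-plane (u, v) positions of the S,
#'   L, C centroids in Å (rows named S, L, C). Offsets are recentred so their
#'   mean is the face center; they must be non-collinear.
#' @param jitter_sd Per-coordinate Gaussian jitter SD in Å (>= 0). The 0.05 Å
#'   scale mimics the residual thermal motion of a well-equilibrated
#'   backbone; 0 gives an exact, static fixture.
#' @param n_frames Number of frames (default 1).
#' @param frame_interval_ps Time between frames in ps (default 200, the
#'   stable-window stride).
#' @param seed Integer seed for the jitter generator.
#' @return Object of class `geometry_spec`.
#' @export
dimer_geometry <- function(angle_deg = 0, face_gap = 10, lateral_shear = 0,
                           element_offsets = default_element_offsets(),
                           jitter_sd = 0, n_frames = 1L,
                           frame_interval_ps = 200, seed = 1L) {
  stopifnot(
    is.finite(angle_deg), angle_deg >= 0, angle_deg <= 90,
    is.finite(face_gap), face_gap > 0,
    is.finite(lateral_shear), lateral_shear >= 0,
    is.finite(jitter_sd), jitter_sd >= 0,
    n_frames >= 1
  )
  off <- as.matrix(element_offsets)
  if (!all(dim(off) == c(3L, 2L))) abort("element_offsets must be a 3 x 2 matrix (S, L, C rows)")
  off <- sweep(off, 2, colMeans(off)) # recentre: face center = prescribed anchor
  # collinear offsets would collapse the plane definition
  area2 <- abs((off[2, 1] - off[1, 1]) * (off[3, 2] - off[1, 2]) -
    (off[3, 1] - off[1, 1]) * (off[2, 2] - off[1, 2]))
  if (area2 <= 2e-6) abort("degenerate element_offsets: S, L, C positions are collinear")
  rownames(off) <- c("S", "L", "C")
  structure(
    list(
      angle_deg = angle_deg, face_gap = face_gap, lateral_shear = lateral_shear,
      element_offsets = off, jitter_sd = jitter_sd,
      n_frames = as.integer(n_frames), frame_interval_ps = frame_interval_ps,
      seed = as.integer(seed)
    ),
    class = "geometry_spec"
  )
}

#' Default in-plane element centroid positions
#' @return 3 x 2 matrix (rows S, L, C) in Å, summing to zero.
#' @export
default_element_offsets <- function() {
  matrix(c(6, -3, -3, 0, 5, -5), ncol = 2,
    dimnames = list(c("S", "L", "C"), c("u", "v")))
}

# residue numbering of the synthetic fixture, matching the default
# selection_spec ranges
.fixture_residues <- list(
  S = 606:610,
  L = 742:756,
  C = c(617:622, 727:732)
)

#' Generate a synthetic dimer trajectory with analytic ground truth
#'
#' Emits C-alpha-only pseudo-atoms for chains A and B (residues 606-610 = S
#' helix, 742-756 = L helix, 617-622 and 727-732 = C sheet), placed on rings
#' around each element's prescribed centroid so the centroids — hence the
#' interface planes — realise the `geometry_spec` exactly. Per-frame
#' isotropic Gaussian jitter (seeded) is added after placement. The returned
#' ground truth is computed from closed-form expressions in the spec's
#' parameters and explicit projection algebra on the analytic centroids; it
#' never calls the descriptor pipeline, so generator and pipeline stay
#' independent cross-checks of each other.
#'
#' @param spec A [dimer_geometry()] object.
#' @return List with `atoms` (tidy atom tibble over `n_frames` frames, time
#'   stamps attached), `truth` (one-row tibble of the eight jitter-free
#'   descriptor values), and `spec`.
#' @examples
#' dim <- make_dimer(dimer_geometry(angle_deg = 15))
#' dim$truth$angleAB # 15
#' @export
make_dimer <- function(spec) {
  stopifnot(inherits(spec, "geometry_spec"))
  g <- dimer_placement(spec)

  ring <- function(center, u, v, n, radius = 2) {
    th <- 2 * pi * (seq_len(n) - 1) / n
    t(center + outer(u, cos(th) * radius) + outer(v, sin(th) * radius))
  }
  chain_atoms <- function(chain, cents, u, v) {
    purrr::imap(.fixture_residues, function(resnos, el) {
      pts <- ring(cents[[el]], u, v, length(resnos))
      tibble::tibble(
        atom_name = "CA", residue_name = "ALA",
        residue_number = as.integer(resnos), chain_id = chain,
        x = pts[, 1], y = pts[, 2], z = pts[, 3]
      )
    }) |> dplyr::bind_rows()
  }
  base <- dplyr::bind_rows(
    chain_atoms("A", g$cent_a, g$u_a, g$v_a),
    chain_atoms("B", g$cent_b, g$u_b, g$v_b)
  )

  set.seed(spec$seed)
  frames <- purrr::map(seq_len(spec$n_frames), function(f) {
    fr <- dplyr::mutate(base,
      frame = f, time_ps = (f - 1) * spec$frame_interval_ps,
      .before = 1
    )
    if (spec$jitter_sd > 0) {
      fr$x <- fr$x + rnorm(nrow(fr), sd = spec$jitter_sd)
      fr$y <- fr$y + rnorm(nrow(fr), sd = spec$jitter_sd)
      fr$z <- fr$z + rnorm(nrow(fr), sd = spec$jitter_sd)
    }
    fr
  })

  list(atoms = dplyr::bind_rows(frames), truth = dimer_truth(spec), spec = spec)
}

# Analytic placement: subunit A's plane tilted by -angle/2 about the x axis,
# subunit B's by +angle/2, so the inter-plane angle is exactly angle_deg and
# the mean normal is +z. Face center A at the origin; face center B at
# (0, shear, gap).
dimer_placement <- function(spec) {
  half <- spec$angle_deg * pi / 360
  s <- sin(half); cc <- cos(half)
  u_a <- c(1, 0, 0); v_a <- c(0, cc, -s) # in-plane basis of A
  u_b <- c(1, 0, 0); v_b <- c(0, cc, s)
  n_a <- c(0, s, cc)   # A's normal, oriented toward B
  n_b <- c(0, s, -cc)  # B's normal, oriented toward A
  fc_a <- c(0, 0, 0)
  fc_b <- c(0, spec$lateral_shear, spec$face_gap)
  off <- spec$element_offsets
  place <- function(fc, u, v) {
    list(
      S = fc + off["S", 1] * u + off["S", 2] * v,
      L = fc + off["L", 1] * u + off["L", 2] * v,
      C = fc + off["C", 1] * u + off["C", 2] * v
    )
  }
  list(
    cent_a = place(fc_a, u_a, v_a), cent_b = place(fc_b, u_b, v_b),
    u_a = u_a, v_a = v_a, u_b = u_b, v_b = v_b,
    n_a = n_a, n_b = n_b, fc_a = fc_a, fc_b = fc_b
  )
}

# Analytic ground truth, from the placement's trigonometric normals and
# centroids plus explicit dot-product/projection algebra. The normals follow
# the same toward-partner orientation rule as the pipeline, but nothing here
# calls the interface_geometry code: angle and distFace come from closed
# forms in the spec parameters, everything else from plane algebra on the
# exact analytic element positions.
dimer_truth <- function(spec) {
  g <- dimer_placement(spec)
  gap <- spec$face_gap; shear <- spec$lateral_shear

  # orient each analytic normal toward the partner's face center (matches the
  # signed-height convention; at high tilt + shear the raw normal can point
  # away)
  orient <- function(n, fc, toward) if (sum(n * (toward - fc)) < 0) -n else n
  n_a <- orient(g$n_a, g$fc_a, g$fc_b)
  n_b <- orient(g$n_b, g$fc_b, g$fc_a)

  hgt <- function(p, fc, n) sum((p - fc) * n)
  proj <- function(p, fc, n) p - hgt(p, fc, n) * n
  dist <- function(p, q) sqrt(sum((p - q)^2))
  mean_height <- function(pa, pb) (hgt(pa, g$fc_b, n_b) + hgt(pb, g$fc_a, n_a)) / 2

  tibble::tibble(
    angleAB = spec$angle_deg,
    heightFaceAB = mean_height(g$fc_a, g$fc_b),
    distFace = sqrt(gap^2 + shear^2),
    shiftFaceAB = (dist(proj(g$fc_b, g$fc_a, n_a), g$fc_a) +
      dist(proj(g$fc_a, g$fc_b, n_b), g$fc_b)) / 2,
    heightS_AB = mean_height(g$cent_a$S, g$cent_b$S),
    shiftSL_AB = (dist(proj(g$cent_b$S, g$fc_a, n_a), g$cent_a$L) +
      dist(proj(g$cent_a$S, g$fc_b, n_b), g$cent_b$L)) / 2,
    heightL_AB = mean_height(g$cent_a$L, g$cent_b$L),
    shiftLS_AB = (dist(proj(g$cent_b$L, g$fc_a, n_a), g$cent_a$S) +
      dist(proj(g$cent_a$L, g$fc_b, n_b), g$cent_b$S)) / 2
  )
}

#' Simulate a compound feature table with planted group structure
#'
#' Draws i.i.d. Gaussian features (SD `noise_sd`) for two groups of
#' compounds and shifts group 2 by `group_shift * noise_sd` along a random
#' seeded unit direction in feature space — the planted-separation ground
#' truth used to validate the PCA clustering readout.
#'
#' @param n_per_group Integer vector of length 2 (default `c(10, 10)`, i.e.
#'   20 compounds).
#' @param n_features Number of features (default 9: the eight descriptors
#'   plus `dG_bind`, so the table is drop-in compatible with
#'   [pca_features()]).
#' @param group_shift Separation in within-group SD units (default 3).
#' @param noise_sd Within-group SD (default 1).
#' @param seed Integer seed.
#' @return List with `features` (tibble `compound_id` + features) and
#'   `labels` (tibble `compound_id`, `group`).
#' @export
make_feature_table <- function(n_per_group = c(10L, 10L), n_features = 9L,
                               group_shift = 3, noise_sd = 1, seed = 1L) {
  stopifnot(length(n_per_group) == 2L, all(n_per_group >= 1L),
    n_features >= 2L, noise_sd > 0)
  set.seed(seed)
  n <- sum(n_per_group)
  x <- matrix(rnorm(n * n_features, sd = noise_sd), nrow = n)
  dir <- rnorm(n_features)
  dir <- dir / sqrt(sum(dir^2))
  grp <- rep(1:2, times = n_per_group)
  x[grp == 2L, ] <- x[grp == 2L, , drop = FALSE] +
    matrix(group_shift * noise_sd * dir, nrow = n_per_group[2],
      ncol = n_features, byrow = TRUE)
  feat_names <- if (n_features == 9L) {
    c(descriptor_names(), "dG_bind")
  } else {
    paste0("f", seq_len(n_features))
  }
  colnames(x) <- feat_names
  ids <- sprintf("cmp%02d", seq_len(n))
  list(
    features = dplyr::bind_cols(tibble::tibble(compound_id = ids),
      tibble::as_tibble(x)),
    labels = tibble::tibble(compound_id = ids, group = grp)
  )
}
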