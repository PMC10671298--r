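#' Centroid of a point set
#'
#' Component-wise arithmetic mean of a set of 3-D points.
#'
#' @param points Numeric matrix with 3 columns (one row per point), or a
#'   single length-3 vector.
#' @return A length-3 numeric vector.
#' @export
centroid <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  if (nrow(points) == 0L) abort("centroid() of an empty point set")
  colMeans(points)
}

#' Build one subunit's interface frame
#'
#' The interface plane of a subunit passes through the centroids of its three
#' interface elements (small helix S, large helix L, central sheet C). The
#' face center is the arithmetic mean of the three centroids, and the unit
#' normal is oriented toward the partner subunit (`toward`), so that signed
#' heights are positive on the partner's side.
#'
#' @param s_pts,l_pts,c_pts C-alpha coordinate matrices (or bare centroids)
#'   of the three elements, as from [select_ca()].
#' @param toward A 3-vector the normal should point at, typically the partner
#'   subunit's face center.
#' @return An object of class `interface_frame`: list with `s_point`,
#'   `l_point`, `c_point`, `face_center` (3-vectors) and unit `normal`.
#' @export
build_interface_frame <- function(s_pts, l_pts, c_pts, toward) {
  s <- centroid(s_pts); l <- centroid(l_pts); cc <- centroid(c_pts)
  e1 <- l - s
  e2 <- cc - s
  n <- cross3(e1, e2)
  # collinearity guard: triangle area below 1e-6 A^2 is degenerate
  area <- sqrt(sum(n^2)) / 2
  if (!is.finite(area) || area <= 1e-6) {
    abort("degenerate geometry: S, L, C centroids are (near-)collinear")
  }
  n <- n / sqrt(sum(n^2))
  fc <- (s + l + cc) / 3
  if (sum(n * (toward - fc)) < 0) n <- -n
  structure(
    list(s_point = s, l_point = l, c_point = cc, face_center = fc, normal = n),
    class = "interface_frame"
  )
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.interface_frame <- function(x, ...) {
  cat("<interface_frame>\n")
  p <- function(v) paste(sprintf("%.3f", v), collapse = ", ")
  cat("  face_center: (", p(x$face_center), ")\n", sep = "")
  cat("  normal:      (", p(x$normal), ")\n", sep = "")
  invisible(x)
}

#' Angle between two interface planes
#'
#' Arc-cosine of the absolute dot product of the two unit normals, in degrees.
#' The result lies in \[0, 90\] and is 0 exactly when the planes are parallel,
#' independent of either normal's orientation.
#'
#' @param a,b `interface_frame` objects.
#' @return Angle in degrees.
#' @export
plane_angle <- function(a, b) {
  d <- abs(sum(a$normal * b$normal))
  acos(min(1, d)) * 180 / pi
}

#' Signed height of a point over an interface plane
#'
#' Signed distance `(point - face_center) . normal`; positive on the side the
#' oriented normal points to, i.e. toward the partner subunit.
#'
#' @param point A 3-vector.
#' @param plane An `interface_frame`.
#' @return Signed height in Å.
#' @export
height_over_plane <- function(point, plane) {
  sum((point - plane$face_center) * plane$normal)
}

#' In-plane lateral shift between a projected point and a reference point
#'
#' Euclidean distance between the orthogonal projection of `point` onto the
#' plane and `ref_point`. Always non-negative.
#'
#' @param point A 3-vector to project.
#' @param ref_point A 3-vector compared against the projection (interpreted
#'   in the plane).
#' @param plane An `interface_frame`.
#' @return Distance in Å.
#' @export
lateral_shift <- function(point, ref_point, plane) {
  h <- height_over_plane(point, plane)
  proj <- point - h * plane$normal
  sqrt(sum((proj - ref_point)^2))
}

#' Descriptor names of the dimer arrangement
#'
#' The eight quantities describing the mutual arrangement of the two subunit
#' interface planes, in canonical order.
#' @return Character vector of length 8.
#' @export
descriptor_names <- function() {
  c("angleAB", "heightFaceAB", "distFace", "shiftFaceAB",
    "heightS_AB", "shiftSL_AB", "heightL_AB", "shiftLS_AB")
}

#' Compute the eight dimer-arrangement descriptors for one frame
#'
#' Given the two subunits' interface frames, computes:
#' \describe{
#'   \item{angleAB}{angle between the A and B planes (degrees; 0 = parallel)}
#'   \item{heightFaceAB}{mean signed height of each face center over the
#'     other subunit's plane (Å)}
#'   \item{distFace}{distance between the two face centers (Å)}
#'   \item{shiftFaceAB}{mean lateral shift between each face center and the
#'     projection of the other face center onto its plane (Å)}
#'   \item{heightS_AB, heightL_AB}{mean signed heights of the S (resp. L)
#'     centroids over the other subunit's plane (Å)}
#'   \item{shiftSL_AB}{mean lateral shift between the projection of one
#'     subunit's S centroid and the other subunit's L centroid (Å)}
#'   \item{shiftLS_AB}{the L-projection-versus-other-S analogue (Å)}
#' }
#' Heights are signed along each plane's toward-partner normal and the two
#' directions (A over B, B over A) are averaged; shifts are unsigned in-plane
#' distances. All eight quantities are symmetric in A and B by construction.
#'
#' @param a,b `interface_frame` objects for the two subunits.
#' @return A one-row tibble with the eight descriptor columns in
#'   [descriptor_names()] order.
#' @examples
#' pa <- build_interface_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), toward = c(0, 0, 10))
#' pb <- build_interface_frame(c(0, 0, 10), c(1, 0, 10), c(0, 1, 10), toward = c(0, 0, 0))
#' compute_descriptors(pa, pb)
#' @export
compute_descriptors <- function(a, b) {
  fa <- a$face_center; fb <- b$face_center
  tibble::tibble(
    angleAB = plane_angle(a, b),
    heightFaceAB = (height_over_plane(fa, b) + height_over_plane(fb, a)) / 2,
    distFace = sqrt(sum((fa - fb)^2)),
    shiftFaceAB = (lateral_shift(fb, fa, a) + lateral_shift(fa, fb, b)) / 2,
    heightS_AB = (height_over_plane(a$s_point, b) + height_over_plane(b$s_point, a)) / 2,
    shiftSL_AB = (lateral_shift(b$s_point, a$l_point, a) + lateral_shift(a$s_point, b$l_point, b)) / 2,
    heightL_AB = (height_over_plane(a$l_point, b) + height_over_plane(b$l_point, a)) / 2,
    shiftLS_AB = (lateral_shift(b$l_point, a$s_point, a) + lateral_shift(a$l_point, b$s_point, b)) / 2
  )
}

# Build both subunits' interface frames from one frame's atom table.
# Face centers are computable before normals, which resolves the mutual
# "toward the partner" orientation dependency.
interface_frames_from_atoms <- function(atoms, sel) {
  pts <- function(chain) {
    list(
      s = select_ca(atoms, chain, sel$s_range),
      l = select_ca(atoms, chain, sel$l_range),
      c = select_ca(atoms, chain, sel$c_ranges)
    )
  }
  pa <- pts(sel$chain_a)
  pb <- pts(sel$chain_b)
  fc <- function(p) (centroid(p$s) + centroid(p$l) + centroid(p$c)) / 3
  fca <- fc(pa); fcb <- fc(pb)
  list(
    a = build_interface_frame(pa$s, pa$l, pa$c, toward = fcb),
    b = build_interface_frame(pb$s, pb$l, pb$c, toward = fca)
  )
}
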