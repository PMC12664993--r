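#' Center of mass of a set of atoms
#'
#' Uniform weighting returns the plain centroid (the convention for C-alpha
#' COM metrics, where all atoms share a mass anyway); mass weighting uses
#' standard atomic masses looked up by element symbol.
#'
#' @param xyz numeric matrix, n x 3, coordinates in Angstrom.
#' @param weighting `"uniform"` or `"mass"`.
#' @param element character vector of element symbols (required for mass
#'   weighting).
#' @return length-3 numeric vector.
#' @examples
#' center_of_mass(rbind(c(0, 0, 0), c(2, 0, 0)))
#' @export
center_of_mass <- function(xyz, weighting = c("uniform", "mass"),
                           element = NULL) {
  weighting <- match.arg(weighting)
  xyz <- coords_matrix(xyz)
  if (nrow(xyz) == 0L) abort("center_of_mass: empty atom set")
  if (weighting == "uniform") {
    return(colMeans(xyz))
  }
  if (is.null(element)) abort("mass weighting requires element symbols")
  w <- atomic_masses()[toupper(trimws(element))]
  if (anyNA(w)) {
    abort(sprintf("unknown element(s): %s",
                  paste(unique(element[is.na(w)]), collapse = ", ")))
  }
  colSums(xyz * w) / sum(w)
}

atomic_masses <- function() {
  setNames(
    c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974, 40.078, 22.990,
      24.305, 65.38, 39.098, 35.45, 55.845, 54.938, 78.971),
    c("H", "C", "N", "O", "S", "P", "CA", "NA",
      "MG", "ZN", "K", "CL", "FE", "MN", "SE")
  )
}

coords_matrix <- function(xyz) {
  if (is.data.frame(xyz)) xyz <- as.matrix(xyz[, c("x", "y", "z")])
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L) abort("coordinates must be n x 3")
  if (!all(is.finite(xyz))) abort("non-finite coordinates")
  xyz
}

#' Dihedral angle through four points
#'
#' Returns the torsion a-b-c-d in degrees in (-180, 180], using the IUPAC
#' sign convention: viewed along b towards c, a clockwise rotation carrying
#' the projection of a onto the projection of d is positive.
#'
#' @param a,b,c,d length-3 numeric vectors (Angstrom).
#' @return angle in degrees.
#' @examples
#' dihedral_angle(c(1, 0, 1), c(0, 0, 1), c(0, 0, 0), c(1, 0, 0)) # cis, 0
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- a - b
  b2 <- c - b
  b3 <- d - c
  n2 <- sqrt(sum(b2^2))
  if (n2 < 1e-12) abort("dihedral_angle: b and c coincide")
  u2 <- b2 / n2
  v1 <- b1 - sum(b1 * u2) * u2  # rejections of the outer bonds
  v3 <- b3 - sum(b3 * u2) * u2
  if (sqrt(sum(v1^2)) < 1e-12 || sqrt(sum(v3^2)) < 1e-12) {
    abort("dihedral_angle: degenerate (colinear) input")
  }
  x <- sum(v1 * v3)
  y <- sum(cross3(u2, v1) * v3)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing
#' sum_i |R x_i + t - y_i|^2 over an ordered correspondence between `mobile`
#' (x) and `reference` (y). Reflections are excluded by the determinant
#' correction, so R is always a rotation.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3, same n.
#' @return list with `rotation` (3 x 3), `translation` (length 3) and
#'   `rmsd` (post-fit, Angstrom); class `rigid_transform`.
#' @export
superpose <- function(mobile, reference) {
  x <- coords_matrix(mobile)
  y <- coords_matrix(reference)
  if (nrow(x) != nrow(y)) {
    abort(sprintf("superpose: %d mobile vs %d reference atoms", nrow(x), nrow(y)))
  }
  if (nrow(x) < 3L) abort("superpose: need at least 3 points")
  cx <- colMeans(x)
  cy <- colMeans(y)
  xc <- sweep(x, 2, cx)
  yc <- sweep(y, 2, cy)
  s <- svd(crossprod(xc, yc))          # H = X'Y; R = V diag(1,1,d) U'
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cy - as.vector(R %*% cx)
  fitted <- sweep(xc %*% t(R), 2, cy, "+")
  rmsd <- sqrt(mean(rowSums((fitted - y)^2)))
  structure(list(rotation = R, translation = t, rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply or invert a rigid transform
#'
#' @param transform a `rigid_transform` from [superpose()].
#' @param xyz n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, xyz) {
  xyz <- coords_matrix(xyz)
  sweep(xyz %*% t(transform$rotation), 2, transform$translation, "+")
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  structure(list(rotation = Rt,
                 translation = as.vector(-Rt %*% transform$translation),
                 rmsd = transform$rmsd),
            class = "rigid_transform")
}

#' Root-mean-square deviation between two coordinate sets
#'
#' Plain (unfitted) RMSD over an ordered correspondence.
#' @param a,b n x 3 matrices.
#' @return Angstrom.
#' @export
rmsd <- function(a, b) {
  a <- coords_matrix(a); b <- coords_matrix(b)
  if (nrow(a) != nrow(b)) abort("rmsd: unequal atom counts")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Estimate the pore (C5 symmetry) axis of a pentamer
#'
#' For a five-fold ring of TMD C-alpha atoms the pore axis is the direction
#' of smallest coordinate spread: the smallest principal component of the
#' selection, through its centroid. The sign is fixed so that the axis
#' points from the TMD towards the periplasmic NTD side, using the centroid
#' of a reference NTD selection.
#'
#' @param tmd_xyz coordinates of the TMD selection (must span all 5 chains).
#' @param tmd_chain chain id per TMD atom (used to enforce the 5-chain
#'   precondition).
#' @param ntd_xyz coordinates whose centroid defines the "up" (periplasmic)
#'   side; if NULL the sign convention is +z-most-aligned.
#' @return list with `origin` (centroid) and `direction` (unit vector);
#'   class `pore_axis`.
#' @export
estimate_axis <- function(tmd_xyz, tmd_chain, ntd_xyz = NULL) {
  xyz <- coords_matrix(tmd_xyz)
  if (length(tmd_chain) != nrow(xyz)) {
    abort("estimate_axis: chain labels must match atom count")
  }
  if (length(unique(tmd_chain)) < 5L) {
    abort("estimate_axis: TMD selection must span all five chains")
  }
  ctr <- colMeans(xyz)
  cov <- crossprod(sweep(xyz, 2, ctr)) / nrow(xyz)
  ev <- eigen(cov, symmetric = TRUE)
  dir <- ev$vectors[, 3]                       # smallest-spread direction
  up <- if (is.null(ntd_xyz)) c(0, 0, 1) else colMeans(coords_matrix(ntd_xyz)) - ctr
  if (sum(dir * up) < 0) dir <- -dir
  dir <- dir / sqrt(sum(dir^2))
  structure(list(origin = ctr, direction = dir), class = "pore_axis")
}

#' Decompose points into axial and radial coordinates about a pore axis
#'
#' @param axis a `pore_axis`.
#' @param xyz n x 3 matrix.
#' @return tibble with columns `z` (signed axial coordinate relative to the
#'   axis origin) and `radial` (perpendicular distance from the axis).
#' @export
axis_decompose <- function(axis, xyz) {
  xyz <- coords_matrix(xyz)
  rel <- sweep(xyz, 2, axis$origin)
  z <- as.vector(rel %*% axis$direction)
  perp <- rel - outer(z, axis$direction)
  tibble(z = z, radial = sqrt(rowSums(perp^2)))
}

rotation_about_axis <- function(axis_dir, angle_deg) {
  u <- axis_dir / sqrt(sum(axis_dir^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
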