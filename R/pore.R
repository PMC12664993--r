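#' Van der Waals radii (Bondi-type)
#'
#' Element-keyed vdW radii in Angstrom used by the pore probe. Elements not
#' in the table fall back to the carbon radius; the table is a plain named
#' vector so callers can supply their own for bit-reproducible profiles.
#'
#' @return named numeric vector.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, CA = 2.31, MG = 1.73,
    ZN = 1.39, `NA` = 2.27, K = 2.75, FE = 1.63)
}

lookup_vdw <- function(element, vdw) {
  r <- vdw[toupper(trimws(element))]
  r[is.na(r)] <- vdw[["C"]]
  unname(r)
}

#' Pore radius profile by largest inscribed sphere probe
#'
#' At each axial sample z, the pore radius is the radius of the largest
#' sphere centered in the plane perpendicular to the pore axis at z that
#' touches no atom: the maximum over in-plane probe centers of
#' `min_i (|center - atom_i| - vdw_i)`. The maximization is seeded by a
#' coarse in-plane grid scan around the axis and refined by Nelder-Mead,
#' the 2-D-per-slice simplification appropriate for an axis-aligned channel.
#'
#' @param model a [pent_structure()] (use [set_coords()] to profile a
#'   trajectory frame).
#' @param axis a `pore_axis`; defaults to [model_axis()].
#' @param scheme a [domain_scheme()] (used for the default axis, lining and
#'   z-window).
#' @param lining integer atom indices lining the pore; defaults to all
#'   protein heavy atoms within `cylinder_radius` of the axis.
#' @param vdw named element-to-radius table, see [vdw_radii()].
#' @param z_window `c(lo, hi)` axial window (Angstrom, axis coordinates);
#'   defaults to the axial extent of the TMD-twist C-alpha selection.
#' @param z_step sample spacing (Angstrom).
#' @param cap_radius radii that grow beyond this cap (no confining atoms)
#'   are capped and flagged.
#' @param cylinder_radius lining pre-filter radius about the axis.
#' @param include_hydrogens keep hydrogens in the lining (default drops
#'   them; MD frames may carry them).
#' @return tibble of class `pore_profile` with columns `z`, `radius`,
#'   `capped`; the axis is attached as attribute `"axis"`.
#' @export
pore_radius_profile <- function(model, axis = NULL, scheme = domain_scheme(),
                                lining = NULL, vdw = vdw_radii(),
                                z_window = NULL, z_step = 0.5,
                                cap_radius = 10, cylinder_radius = 15,
                                include_hydrogens = FALSE) {
  axis <- axis %||% model_axis(model, scheme)
  a <- model$atoms
  if (is.null(lining)) {
    cand <- which(!a$is_hetero &
                    (include_hydrogens | a$element != "H"))
    dec_all <- axis_decompose(axis, model_coords(model, cand))
    lining <- cand[dec_all$radial <= cylinder_radius]
  }
  if (!length(lining)) abort("pore_radius_profile: empty lining selection")
  if (is.null(z_window)) {
    tmd <- unlist(scheme_selection(model, scheme, "tmd_twist"))
    zr <- axis_decompose(axis, model_coords(model, tmd))$z
    z_window <- range(zr)
  }
  # lining coordinates in the axis frame (z along the axis)
  rel <- sweep(model_coords(model, lining), 2, axis$origin)
  az <- as.vector(rel %*% axis$direction)
  perp_basis <- axis_perp_basis(axis$direction)
  ax_ <- as.vector(rel %*% perp_basis[, 1])
  ay <- as.vector(rel %*% perp_basis[, 2])
  rad_i <- lookup_vdw(a$element[lining], vdw)

  zs <- seq(z_window[1], z_window[2], by = z_step)
  prof <- purrr::map_dfr(zs, function(z0) {
    slab <- abs(az - z0) <= cap_radius + max(rad_i)
    if (!any(slab)) {
      return(tibble(z = z0, radius = cap_radius, capped = TRUE))
    }
    r <- max_inscribed_radius(ax_[slab], ay[slab], az[slab], rad_i[slab],
                              z0, cap_radius)
    tibble(z = z0, radius = min(r, cap_radius), capped = r >= cap_radius)
  })
  if (any(prof$capped)) {
    warn(sprintf("pore radius capped at %.1f Angstrom for %d of %d samples",
                 cap_radius, sum(prof$capped), nrow(prof)))
  }
  prof$radius <- pmax(prof$radius, 0)
  attr(prof, "axis") <- axis
  class(prof) <- c("pore_profile", class(prof))
  prof
}

# orthonormal in-plane basis perpendicular to a unit axis direction
axis_perp_basis <- function(dir) {
  seedv <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- seedv - sum(seedv * dir) * dir
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(dir, e1)
  cbind(e1, e2)
}

# maximin clearance in the plane at z0: coarse grid seed + Nelder-Mead
max_inscribed_radius <- function(x, y, z, vdw, z0, cap_radius) {
  clearance <- function(p) {
    min(sqrt((p[1] - x)^2 + (p[2] - y)^2 + (z0 - z)^2) - vdw)
  }
  g <- seq(-3, 3, by = 0.5)
  grid <- expand.grid(gx = g, gy = g)
  vals <- vapply(seq_len(nrow(grid)),
                 function(i) clearance(c(grid$gx[i], grid$gy[i])),
                 numeric(1))
  best <- c(grid$gx[which.max(vals)], grid$gy[which.max(vals)])
  opt <- optim(best, function(p) -clearance(p), method = "Nelder-Mead",
               control = list(reltol = 1e-10, maxit = 500))
  r <- -opt$value
  if (r >= cap_radius) cap_radius else r
}

#' Replace the coordinates of a structural model
#'
#' Utility for profiling trajectory frames: returns the model with its
#' atom coordinates swapped for `xyz`.
#'
#' @param model a [pent_structure()].
#' @param xyz n x 3 matrix matching the atom count.
#' @return a [pent_structure()].
#' @export
set_coords <- function(model, xyz) {
  xyz <- coords_matrix(xyz)
  if (nrow(xyz) != nrow(model$atoms)) abort("set_coords: atom count mismatch")
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

#' Pore profiles across trajectory frames
#'
#' @param traj an (aligned) [pent_trajectory()].
#' @param frames frame indices (default all).
#' @param ... passed to [pore_radius_profile()]; the axis is estimated once
#'   from the topology and reused for every frame.
#' @inheritParams pore_radius_profile
#' @return long tibble: `replicate`, `frame`, `z`, `radius`, `capped`.
#' @export
traj_pore_profiles <- function(traj, frames = NULL, axis = NULL,
                               scheme = domain_scheme(), ...) {
  frames <- frames %||% seq_len(n_frames(traj))
  axis <- axis %||% model_axis(traj$topology, scheme)
  purrr::map_dfr(frames, function(i) {
    m <- set_coords(traj$topology, traj_frame(traj, i))
    p <- pore_radius_profile(m, axis = axis, scheme = scheme, ...)
    tibble(replicate = traj$replicate_id, frame = i,
           z = p$z, radius = p$radius, capped = p$capped)
  })
}

#' Pointwise mean and standard error over pore profiles
#'
#' @param profiles long profile tibble (e.g. from [traj_pore_profiles()])
#'   with columns `z` and `radius`, one profile per `frame` (and
#'   `replicate`).
#' @return tibble with `z`, `radius_mean`, `radius_sem` (sample SD /
#'   sqrt(n)), `n`.
#' @export
profile_stats <- function(profiles) {
  if (!nrow(profiles)) abort("profile_stats: no profiles")
  profiles |>
    group_by(.data$z) |>
    summarise(
      radius_mean = mean(.data$radius),
      radius_sem = if (dplyr::n() > 1) sd(.data$radius) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Annotate a pore profile with prime positions
#'
#' The z of each prime position (2', 9', 16', ...) is the axial coordinate
#' of the COM of the five corresponding C-alpha atoms. Annotations land in
#' attribute `"primes"` as a tibble with the interpolated profile radius at
#' each position; with no `prime_map` in the scheme the profile is returned
#' unchanged with a warning.
#'
#' @param profile a `pore_profile`.
#' @param model the [pent_structure()] the profile was computed from.
#' @param scheme a [domain_scheme()] carrying `prime_map`.
#' @return the profile with attribute `"primes"` set.
#' @export
annotate_primes <- function(profile, model, scheme) {
  pm <- scheme$prime_map
  if (is.null(pm)) {
    warn("no prime_map in scheme; profile returned unannotated")
    return(profile)
  }
  axis <- attr(profile, "axis")
  if (is.null(axis)) axis <- model_axis(model, scheme)
  ann <- purrr::map_dfr(names(pm), function(lbl) {
    res <- pm[[lbl]]
    idx <- which(!model$atoms$is_hetero & model$atoms$res_seq == res &
                   model$atoms$atom_name == "CA")
    if (!length(idx)) {
      warn(sprintf("prime %s: residue %d has no C-alpha atoms", lbl, res))
      return(tibble(label = lbl, res_seq = res, z = NA_real_,
                    radius = NA_real_))
    }
    com <- colMeans(model_coords(model, idx))
    z0 <- axis_decompose(axis, matrix(com, 1))$z
    r0 <- stats::approx(profile$z, profile$radius, xout = z0, rule = 2)$y
    tibble(label = lbl, res_seq = res, z = z0, radius = r0)
  })
  attr(profile, "primes") <- ann
  profile
}
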