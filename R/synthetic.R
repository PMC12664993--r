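#' Specification for a synthetic ideal pentamer
#'
#' The generator builds a five-fold symmetric pseudo-atom pentamer (C-alpha
#' backbone plus coordinating O shells and bound cations) whose gating
#' metrics are known by construction: `ecd_twist()` returns `twist_deg`
#' exactly, `beta_expansion()` returns `beta_sep` exactly, the TMD pore
#' rings realize the probe radii in `pore_radius_by_z`, and each requested
#' ion site archetype carries a coordination shell at exact distances. The
#' model follows the DeCLIC-style numbering the default [domain_scheme()]
#' selects on: NTD1 35-195, NTD2 196-325, ECD 328-513, TMD 514-639, with
#' beta-1 at 340-345 and beta-10 at 511-515.
#'
#' @param twist_deg target per-subunit ECD twist (degrees, IUPAC sign;
#'   negative for the closed-channel convention).
#' @param beta_sep beta1-beta10 COM separation (Angstrom).
#' @param pore_radius_by_z data.frame with columns `z` (Angstrom along the
#'   pore axis, TMD window) and `radius` (target probe radius at that z);
#'   one 20-atom ring is built per row.
#' @param lobe_offsets named list of 3-vectors, names like `"C.ntd1"`,
#'   applied as rigid translations of that chain's lobe.
#' @param ions character subset of `c("site1","site2","site3","site4")`;
#'   each archetype places one Ca ion plus its coordination shell per chain.
#' @param ion_displacement named list (by archetype) of 3-vectors displacing
#'   the ion away from its shell center.
#' @param noise_sigma isotropic Gaussian coordinate noise (Angstrom).
#' @param seed integer seed for the noise stream.
#' @return list of class `pentamer_spec`.
#' @export
pentamer_spec <- function(twist_deg = -26,
                          beta_sep = 12,
                          pore_radius_by_z = default_pore_rings(),
                          lobe_offsets = NULL,
                          ions = c("site1", "site2", "site3", "site4"),
                          ion_displacement = NULL,
                          noise_sigma = 0,
                          seed = 1L) {
  pore_radius_by_z <- as_tibble(pore_radius_by_z)
  if (!all(c("z", "radius") %in% names(pore_radius_by_z))) {
    abort("pore_radius_by_z needs columns z and radius")
  }
  if (any(pore_radius_by_z$radius <= 0)) abort("pore radii must be > 0")
  if (noise_sigma < 0) abort("noise_sigma must be >= 0")
  ions <- if (length(ions)) {
    match.arg(ions, c("site1", "site2", "site3", "site4"), several.ok = TRUE)
  } else {
    character(0)
  }
  structure(list(twist_deg = twist_deg, beta_sep = beta_sep,
                 pore_radius_by_z = pore_radius_by_z,
                 lobe_offsets = lobe_offsets, ions = ions,
                 ion_displacement = ion_displacement,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "pentamer_spec")
}

#' @rdname pentamer_spec
#' @export
default_pore_rings <- function() {
  tibble(z = c(-18, -14, -10, -6, -2),
         radius = c(1.5, 2.0, 3.0, 4.5, 6.0))
}

#' Domain scheme matching the synthetic generator's numbering
#'
#' Identical to the package defaults plus the generator's lobe ranges
#' (NTD1 35-195, NTD2 196-325) and a prime map placing 2', 9' and 16' on
#' the inner, middle and outer default pore rings.
#' @return a [domain_scheme()].
#' @export
generator_scheme <- function() {
  domain_scheme(ntd1 = c(35L, 195L), ntd2 = c(196L, 325L),
                prime_map = c("2'" = 521L, "9'" = 529L, "16'" = 537L))
}

# carbon vdW radius used for ring pseudo-atoms; must agree with vdw_radii()
GEN_RING_VDW <- 1.7

# evenly spaced circle of n points, horizontal plane, centered exactly
circle_points <- function(n, center, radius, phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1L) / n
  cbind(center[1] + radius * cos(th),
        center[2] + radius * sin(th),
        center[3] + rep(0, n))
}

# one chain in its local frame (azimuth 0 = +x); returns tibble of protein
# atoms. Exactness contracts: beta1 COM = P1, beta10 COM = P10 with
# |P1 - P10| = beta_sep; ECD(328-513) C-alpha COM at azimuth twist_deg;
# TMD(515-636) C-alpha COM at azimuth 0.
build_chain_local <- function(spec) {
  tau <- spec$twist_deg * pi / 180
  rings <- spec$pore_radius_by_z
  n_rings <- nrow(rings)
  ring_res <- lapply(seq_len(n_rings), function(j) 520L + 4L * (j - 1L) + 0:3)
  all_ring_res <- unlist(ring_res)
  if (max(all_ring_res) > 636L) abort("too many pore rings for the TMD range")

  P1 <- c(14, 0, 28)
  P10 <- P1 + spec$beta_sep * c(0, 0, -1)
  Qa <- P10 + c(0, 0, 1.0)     # residues 511-513;  (3*Qa + 2*Qb)/5 = P10
  Qb <- P10 + c(0, 0, -1.5)    # residues 514-515

  out <- list()
  add <- function(res, xyz) {
    out[[length(out) + 1L]] <<- tibble(
      res_seq = as.integer(res), atom_name = "CA", res_name = "GLY",
      element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
  }

  # NTD lobes
  add(35:195, circle_points(161, c(23, 0, 58), 6))
  add(196:325, circle_points(130, c(17, 0, 45), 6))

  # beta strands and the 511-515 boundary
  add(340:345, circle_points(6, P1, 0.8))
  add(511:513, circle_points(3, Qa, 0.8))
  add(514L, matrix(Qb + c(0, 0, 0.8), 1))
  add(515L, matrix(Qb + c(0, 0, -0.8), 1))

  # ECD filler placed so the 186-residue ECD C-alpha COM lands exactly on
  # target (twist_deg azimuth, radius 16, z 25)
  ecd_free <- c(328:339, 346:510)
  C_ecd <- c(16 * cos(tau), 16 * sin(tau), 25)
  C_free <- (186 * C_ecd - 6 * P1 - 3 * Qa) / length(ecd_free)
  add(ecd_free, circle_points(length(ecd_free), C_free, 5))

  # TMD pore rings: per-chain arcs of 4 atoms symmetric about azimuth 0,
  # completing 20-atom rings under C5; atom-center radius = probe + vdW
  arc <- c(-27, -9, 9, 27) * pi / 180
  ring_sum <- c(0, 0, 0)
  for (j in seq_len(n_rings)) {
    R <- rings$radius[j] + GEN_RING_VDW
    xyz <- cbind(R * cos(arc), R * sin(arc), rep(rings$z[j], 4))
    ring_sum <- ring_sum + colSums(xyz)
    add(ring_res[[j]], xyz)
  }

  # TMD filler so the 515-636 C-alpha COM lands exactly at (12, 0, -10)
  tmd_free <- setdiff(516:636, all_ring_res)
  C_tmd <- c(12, 0, -10)
  n_block <- 122
  C_tfill <- (n_block * C_tmd - (Qb + c(0, 0, -0.8)) - ring_sum) / length(tmd_free)
  add(tmd_free, circle_points(length(tmd_free), C_tfill, 3))

  # alignment-range tail outside both twist blocks
  add(637:639, circle_points(3, c(12, 0, -19), 1))

  bind_rows(out)
}

# ion archetypes: shell center, and (residue, atom, distance) partners.
# Distances mirror the published per-site coordination bounds.
ion_archetypes <- function() {
  list(
    site1 = list(res_seq = 701L, center = c(20, 0, 50), partners = tibble(
      res_seq = c(76L, 77L, 123L, 123L, 124L, 129L),
      res_name = c("ASP", "PRO", "ASP", "ASP", "ASP", "TYR"),
      atom_name = c("OD1", "O", "OD1", "O", "OD2", "O"),
      dist = c(2.40, 2.45, 2.50, 2.55, 2.58, 2.60))),
    site2 = list(res_seq = 702L, center = c(27, 0, 44), partners = tibble(
      res_seq = c(124L, 126L, 128L),
      res_name = c("ASP", "GLY", "GLY"),
      atom_name = c("O", "O", "O"),
      dist = c(2.60, 2.85, 3.10))),
    site3 = list(res_seq = 703L, center = c(16, 0, 18), partners = tibble(
      res_seq = c(347L, 434L, 436L, 477L),
      res_name = c("GLU", "PRO", "PHE", "LEU"),
      atom_name = c("OE1", "O", "O", "O"),
      dist = c(2.40, 2.55, 2.60, 2.70))),
    site4 = list(res_seq = 704L, center = c(22, 0, 13), partners = tibble(
      res_seq = c(480L, 476L, 478L),
      res_name = c("GLU", "GLN", "GLY"),
      atom_name = c("OE1", "O", "O"),
      dist = c(2.50, 2.80, 3.00)))
  )
}

octahedral_dirs <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
}

build_ions_local <- function(spec) {
  if (!length(spec$ions)) {
    return(tibble(res_seq = integer(), res_name = character(),
                  atom_name = character(), element = character(),
                  x = double(), y = double(), z = double(),
                  is_hetero = logical()))
  }
  arch <- ion_archetypes()[spec$ions]
  out <- list()
  for (nm in names(arch)) {
    a <- arch[[nm]]
    disp <- spec$ion_displacement[[nm]] %||% c(0, 0, 0)
    dirs <- octahedral_dirs()[seq_len(nrow(a$partners)), , drop = FALSE]
    shell <- sweep(dirs * a$partners$dist, 2, a$center, "+")
    out[[length(out) + 1L]] <- tibble(
      res_seq = a$partners$res_seq, res_name = a$partners$res_name,
      atom_name = a$partners$atom_name, element = "O",
      x = shell[, 1], y = shell[, 2], z = shell[, 3], is_hetero = FALSE
    )
    ion <- a$center + disp
    out[[length(out) + 1L]] <- tibble(
      res_seq = a$res_seq, res_name = "CA", atom_name = "CA", element = "CA",
      x = ion[1], y = ion[2], z = ion[3], is_hetero = TRUE
    )
  }
  bind_rows(out)
}

#' Build a synthetic pentamer
#'
#' Constructs the C5-symmetric model described by a [pentamer_spec()]. The
#' returned structure carries the spec as attribute `"generator"`.
#'
#' @param spec a [pentamer_spec()].
#' @return a [pent_structure()] with 5 chains A-E.
#' @export
build_pentamer <- function(spec) {
  stopifnot(inherits(spec, "pentamer_spec"))
  chain_prot <- build_chain_local(spec)
  chain_prot$is_hetero <- FALSE
  chain_ion <- build_ions_local(spec)
  local <- bind_rows(chain_prot, chain_ion)

  chains <- LETTERS[1:5]
  all_atoms <- purrr::map2_dfr(chains, (seq_along(chains) - 1L) * 72, function(ch, phi) {
    R <- rotation_about_axis(c(0, 0, 1), phi)
    xyz <- as.matrix(local[, c("x", "y", "z")]) %*% t(R)
    a <- local
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    a$chain <- ch
    a
  })

  # per-chain rigid lobe offsets ("C.ntd1" = c(dx, dy, dz))
  sch <- generator_scheme()
  if (!is.null(spec$lobe_offsets)) {
    for (key in names(spec$lobe_offsets)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      if (length(parts) != 2L || !parts[2] %in% c("ntd1", "ntd2")) {
        abort(sprintf("lobe_offsets key '%s' must look like 'A.ntd1'", key))
      }
      rng <- sch[[parts[2]]]
      hit <- all_atoms$chain == parts[1] & !all_atoms$is_hetero &
        all_atoms$res_seq >= rng[1] & all_atoms$res_seq <= rng[2]
      if (!any(hit)) abort(sprintf("lobe_offsets: no atoms for '%s'", key))
      off <- spec$lobe_offsets[[key]]
      all_atoms$x[hit] <- all_atoms$x[hit] + off[1]
      all_atoms$y[hit] <- all_atoms$y[hit] + off[2]
      all_atoms$z[hit] <- all_atoms$z[hit] + off[3]
    }
  }

  all_atoms <- all_atoms |>
    arrange(match(.data$chain, chains), .data$is_hetero, .data$res_seq)

  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    n <- nrow(all_atoms)
    all_atoms$x <- all_atoms$x + rnorm(n, 0, spec$noise_sigma)
    all_atoms$y <- all_atoms$y + rnorm(n, 0, spec$noise_sigma)
    all_atoms$z <- all_atoms$z + rnorm(n, 0, spec$noise_sigma)
  }

  model <- pent_structure(all_atoms, title = "synthetic C5 pentamer",
                          assembly_chains = chains)
  attr(model, "generator") <- spec
  model
}

#' Scripted rigid-body events for synthetic trajectories
#'
#' Each event takes effect at `frame` (1-based) and persists to the end of
#' the trajectory; events compose cumulatively.
#'
#' @param frame frame index at which the event switches on.
#' @param chain chain id (A-E).
#' @param target one of `"ntd1"`, `"ntd2"`, `"ecd"`, `"tmd"`, `"beta1"`,
#'   `"beta10"` (residue blocks of the generator scheme) or `"ion:site1"`
#'   ... `"ion:site4"`.
#' @param translate length-3 displacement (Angstrom), or NULL.
#' @param radial scalar displacement along the target's outward radial
#'   direction (from the z axis), or NULL.
#' @param rotate_deg rotation about the pore (z) axis, degrees, or NULL.
#' @return a one-row tibble; rows from several calls can be `rbind`-ed.
#' @export
motion_event <- function(frame, chain, target, translate = NULL,
                         radial = NULL, rotate_deg = NULL) {
  n_set <- (!is.null(translate)) + (!is.null(radial)) + (!is.null(rotate_deg))
  if (n_set != 1L) abort("exactly one of translate/radial/rotate_deg must be set")
  tibble(frame = as.integer(frame), chain = as.character(chain),
         target = target,
         translate = list(translate), radial = list(radial),
         rotate_deg = list(rotate_deg))
}

event_indices <- function(model, chain, target) {
  a <- model$atoms
  if (startsWith(target, "ion:")) {
    site <- sub("^ion:", "", target)
    arch <- ion_archetypes()[[site]]
    if (is.null(arch)) abort(sprintf("unknown ion target '%s'", target))
    idx <- which(a$chain == chain & a$is_hetero & a$res_seq == arch$res_seq)
  } else {
    sch <- generator_scheme()
    rng <- switch(target, ntd1 = sch$ntd1, ntd2 = sch$ntd2,
                  ecd = sch$ecd_twist, tmd = sch$tmd_twist,
                  beta1 = sch$beta1, beta10 = sch$beta10,
                  abort(sprintf("unknown target '%s'", target)))
    idx <- which(a$chain == chain & !a$is_hetero &
                   a$res_seq >= rng[1] & a$res_seq <= rng[2])
  }
  if (!length(idx)) abort(sprintf("no atoms for chain %s target %s", chain, target))
  idx
}

#' Build a synthetic trajectory with scripted motions
#'
#' Frame 1 is the noise-free pentamer; each subsequent frame applies all
#' script events with `frame <= i` cumulatively, then (optionally) a random
#' global rigid sway (removable by TMD alignment) and isotropic Gaussian
#' noise. The same spec, script and seed reproduce the trajectory
#' bit-identically.
#'
#' @param spec a [pentamer_spec()]; its `noise_sigma` is the per-frame noise.
#' @param n_frames number of frames.
#' @param script tibble of [motion_event()] rows, or NULL.
#' @param dt_ns frame spacing in ns.
#' @param global_sway if TRUE, contaminate every frame after the first with
#'   a random rigid rotation (up to ~10 degrees) and translation (up to
#'   ~5 Angstrom) of the whole system.
#' @param replicate_id replicate label.
#' @return a [pent_trajectory()]; attribute `"generator"` holds the spec
#'   and script.
#' @export
build_trajectory <- function(spec, n_frames, script = NULL, dt_ns = 1,
                             global_sway = FALSE, replicate_id = "rep1") {
  base_spec <- spec
  base_spec$noise_sigma <- 0
  model <- build_pentamer(base_spec)
  base <- model_coords(model)
  n_atoms <- nrow(base)

  ev_idx <- NULL
  if (!is.null(script) && nrow(script)) {
    if (any(script$frame < 1L | script$frame > n_frames)) {
      abort("script frame indices must lie within the trajectory")
    }
    ev_idx <- lapply(seq_len(nrow(script)), function(i) {
      event_indices(model, script$chain[i], script$target[i])
    })
  }

  set.seed(spec$seed)
  coords <- array(0, c(n_atoms, 3L, n_frames))
  for (i in seq_len(n_frames)) {
    xyz <- base
    if (!is.null(ev_idx)) {
      for (e in seq_len(nrow(script))) {
        if (script$frame[e] > i) next
        idx <- ev_idx[[e]]
        if (!is.null(script$translate[[e]])) {
          xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2,
                              script$translate[[e]], "+")
        } else if (!is.null(script$radial[[e]])) {
          ctr <- colMeans(xyz[idx, , drop = FALSE])
          u <- c(ctr[1], ctr[2], 0)
          u <- u / sqrt(sum(u^2))
          xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2,
                              script$radial[[e]] * u, "+")
        } else {
          R <- rotation_about_axis(c(0, 0, 1), script$rotate_deg[[e]])
          xyz[idx, ] <- xyz[idx, , drop = FALSE] %*% t(R)
        }
      }
    }
    if (isTRUE(global_sway) && i > 1L) {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      R <- rotation_about_axis(ax, runif(1, -10, 10))
      shift <- runif(3, -5, 5)
      xyz <- sweep(xyz %*% t(R), 2, shift, "+")
    }
    if (spec$noise_sigma > 0) {
      xyz <- xyz + matrix(rnorm(n_atoms * 3L, 0, spec$noise_sigma), n_atoms, 3L)
    }
    coords[, , i] <- xyz
  }

  traj <- pent_trajectory(model, coords,
                          times = dt_ns * (seq_len(n_frames) - 1L),
                          replicate_id = replicate_id)
  attr(traj, "generator") <- list(spec = spec, script = script,
                                  global_sway = global_sway)
  traj
}
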