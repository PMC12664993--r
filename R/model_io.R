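#' Structural model container
#'
#' A `pent_structure` holds one structural model as a tidy atom table plus
#' assembly metadata. Atoms carry author residue numbering (`res_seq`), the
#' numbering used for every published residue identifier this package
#' selects on; label/entity numbering from mmCIF is ignored.
#'
#' @param atoms tibble/data.frame with columns `chain` (character),
#'   `res_seq` (integer, author numbering), `res_name`, `atom_name`,
#'   `element`, `x`, `y`, `z` (Angstrom) and `is_hetero` (logical).
#' @param title optional free-text title.
#' @param assembly_chains ordered chain ids of the assembly subunits;
#'   defaults to the protein chains in file order. Pentamer analyses require
#'   exactly five (enforced at analysis entry, not here).
#' @return object of class `pent_structure`.
#' @export
pent_structure <- function(atoms, title = "", assembly_chains = NULL) {
  need <- c("chain", "res_seq", "res_name", "atom_name", "element",
            "x", "y", "z", "is_hetero")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols)) {
    abort(paste0("atoms is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  atoms <- as_tibble(atoms)[need]
  atoms$chain <- as.character(atoms$chain)
  atoms$res_seq <- as.integer(atoms$res_seq)
  atoms$is_hetero <- as.logical(atoms$is_hetero)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("all atoms must have finite coordinates")
  }
  prot <- atoms[!atoms$is_hetero, ]
  bad <- prot |>
    group_by(.data$chain) |>
    summarise(ok = !is.unsorted(.data$res_seq), .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(bad)) {
    abort(sprintf("protein res_seq not non-decreasing in chain(s): %s",
                  paste(bad$chain, collapse = ", ")))
  }
  if (is.null(assembly_chains)) {
    assembly_chains <- unique(prot$chain)
  }
  structure(list(atoms = atoms, title = title,
                 assembly_chains = as.character(assembly_chains)),
            class = "pent_structure")
}

#' @export
print.pent_structure <- function(x, ...) {
  cat(sprintf("<pent_structure> %d atoms (%d hetero), chains: %s\n",
              nrow(x$atoms), sum(x$atoms$is_hetero),
              paste(x$assembly_chains, collapse = " ")))
  if (nzchar(x$title)) cat("  ", x$title, "\n", sep = "")
  invisible(x)
}

assert_pentamer <- function(model) {
  if (length(model$assembly_chains) != 5L) {
    abort(sprintf("pentamer analysis requires 5 assembly chains, found %d (%s)",
                  length(model$assembly_chains),
                  paste(model$assembly_chains, collapse = " ")))
  }
  invisible(model)
}

model_coords <- function(model, idx = NULL) {
  a <- model$atoms
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  cbind(x = a$x, y = a$y, z = a$z)
}

#' Read a structural model from PDB or mmCIF
#'
#' Parsing is delegated to bio3d; author residue numbering and hetero
#' records (ions, waters, lipids) are preserved. Alternate locations other
#' than blank/"A" are dropped (deposited models are single-conformer in
#' practice).
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return a [pent_structure()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  raw <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) abort(sprintf("failed to parse %s as %s: %s",
                                      path, format, conditionMessage(e)))
  )
  at <- raw$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  elem <- toupper(trimws(at$elesy))
  guess <- toupper(substr(trimws(at$elety), 1, 1))
  elem[is.na(elem) | elem == ""] <- guess[is.na(elem) | elem == ""]
  atoms <- tibble(
    chain = as.character(at$chain),
    res_seq = as.integer(at$resno),
    res_name = trimws(at$resid),
    atom_name = trimws(at$elety),
    element = elem,
    x = at$x, y = at$y, z = at$z,
    is_hetero = at$type == "HETATM"
  )
  atoms$chain[is.na(atoms$chain)] <- " "
  if (!any(!atoms$is_hetero)) {
    abort(sprintf("%s contains no protein (ATOM) records", path))
  }
  pent_structure(atoms, title = basename(path))
}

#' Write a structural model to PDB
#'
#' @param model a `pent_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(model_coords(model))),
    type = ifelse(a$is_hetero, "HETATM", "ATOM"),
    resno = a$res_seq,
    resid = a$res_name,
    eleno = seq_len(nrow(a)),
    elety = a$atom_name,
    chain = a$chain,
    elesy = a$element
  )
  invisible(path)
}

#' Trajectory container
#'
#' Ordered coordinate frames over a fixed topology. Frames are stored as an
#' `n_atoms x 3 x n_frames` array in Angstrom with strictly increasing time
#' stamps in nanoseconds.
#'
#' @param topology a [pent_structure()].
#' @param coords `n_atoms x 3 x n_frames` array (a single `n x 3` matrix is
#'   promoted to one frame).
#' @param times numeric vector of frame times (ns); default `0:(n-1)`.
#' @param replicate_id label carried into all per-frame outputs.
#' @return object of class `pent_trajectory`.
#' @export
pent_trajectory <- function(topology, coords, times = NULL,
                            replicate_id = "rep1") {
  if (!inherits(topology, "pent_structure")) abort("topology must be a pent_structure")
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    abort("coords must be an n_atoms x 3 x n_frames array")
  }
  n_top <- nrow(topology$atoms)
  if (dim(coords)[1] != n_top) {
    abort(sprintf("atom-count mismatch: topology has %d atoms, frames have %d",
                  n_top, dim(coords)[1]))
  }
  n_frames <- dim(coords)[3]
  if (is.null(times)) times <- as.numeric(seq_len(n_frames) - 1L)
  if (length(times) != n_frames) abort("times must have one entry per frame")
  if (n_frames > 1L && any(diff(times) <= 0)) {
    abort("frame times must be strictly increasing")
  }
  if (!all(is.finite(coords))) abort("non-finite frame coordinates")
  structure(list(topology = topology, coords = coords,
                 times = as.numeric(times),
                 replicate_id = as.character(replicate_id)),
            class = "pent_trajectory")
}

#' @export
print.pent_trajectory <- function(x, ...) {
  cat(sprintf("<pent_trajectory> %s: %d frames x %d atoms, %.3g-%.3g ns\n",
              x$replicate_id, n_frames(x), dim(x$coords)[1],
              min(x$times), max(x$times)))
  invisible(x)
}

#' @rdname pent_trajectory
#' @param traj a `pent_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

traj_frame <- function(traj, i) traj$coords[, , i, drop = TRUE]

#' Read a trajectory from topology + coordinate files
#'
#' The coordinate file may be a multi-model PDB (the package's plain-text
#' trajectory format) or a binary DCD; both are read through bio3d. Atom
#' counts must agree between topology and frames.
#'
#' @param topology path to a PDB/mmCIF topology, or a `pent_structure`.
#' @param coords path to a multi-model PDB or `.dcd` file.
#' @param times optional frame times (ns); defaults to 0, 1, 2, ...
#' @param replicate_id replicate label.
#' @return a [pent_trajectory()].
#' @export
read_trajectory <- function(topology, coords, times = NULL,
                            replicate_id = "rep1") {
  top <- if (inherits(topology, "pent_structure")) topology else read_structure(topology)
  n_top <- nrow(top$atoms)
  xyz <- if (grepl("\\.dcd$", coords, ignore.case = TRUE)) {
    bio3d::read.dcd(coords, verbose = FALSE)
  } else {
    bio3d::read.pdb(coords, multi = TRUE, verbose = FALSE)$xyz
  }
  xyz <- unclass(xyz)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_atoms <- ncol(xyz) / 3
  if (n_atoms != n_top) {
    abort(sprintf("atom-count mismatch: topology has %d atoms, frames have %g",
                  n_top, n_atoms))
  }
  arr <- array(0, c(n_top, 3L, nrow(xyz)))
  for (i in seq_len(nrow(xyz))) {
    arr[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  }
  pent_trajectory(top, arr, times = times, replicate_id = replicate_id)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj a `pent_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  a <- traj$topology$atoms
  xyz <- t(vapply(seq_len(n_frames(traj)),
                  function(i) as.vector(t(traj_frame(traj, i))),
                  numeric(nrow(a) * 3L)))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = ifelse(a$is_hetero, "HETATM", "ATOM"),
    resno = a$res_seq, resid = a$res_name,
    eleno = seq_len(nrow(a)), elety = a$atom_name,
    chain = a$chain, elesy = a$element
  )
  invisible(path)
}

#' Select atoms by chain and author residue range
#'
#' Residue-range selection over protein records, with a coverage report:
#' the fraction of residues in the requested range actually present in the
#' model. Deposited models legitimately omit disordered stretches, so
#' partial coverage yields a warning (below the floor) rather than an
#' error, and an empty match returns an empty, flagged selection.
#'
#' @param model a [pent_structure()].
#' @param chain chain id, or NULL for all assembly chains.
#' @param range `c(lo, hi)` author residue range, or NULL for the whole chain.
#' @param atom_filter `"ca_only"` (C-alpha), `"heavy"` (non-hydrogen) or
#'   `"all"`.
#' @param coverage_floor warn when coverage drops below this fraction.
#' @return integer row indices into `model$atoms`, with attributes
#'   `coverage` (fraction) and `flagged` (logical).
#' @export
select_atoms <- function(model, chain = NULL, range = NULL,
                         atom_filter = c("ca_only", "heavy", "all"),
                         coverage_floor = 0.8) {
  atom_filter <- match.arg(atom_filter)
  a <- model$atoms
  keep <- !a$is_hetero
  if (!is.null(chain)) {
    if (!any(a$chain == chain)) abort(sprintf("no such chain: %s", chain))
    keep <- keep & a$chain == chain
  }
  if (!is.null(range)) {
    range <- as.integer(range)
    keep <- keep & a$res_seq >= range[1] & a$res_seq <= range[2]
  }
  keep <- keep & switch(atom_filter,
    ca_only = a$atom_name == "CA",
    heavy = a$element != "H",
    all = TRUE
  )
  idx <- which(keep)
  coverage <- if (is.null(range)) {
    if (length(idx)) 1 else 0
  } else {
    length(unique(a$res_seq[idx])) / (range[2] - range[1] + 1L)
  }
  flagged <- coverage < coverage_floor
  if (flagged) {
    warn(sprintf("selection coverage %.2f below floor %.2f (chain %s, range %s)",
                 coverage, coverage_floor, chain %||% "*",
                 if (is.null(range)) "*" else paste(range, collapse = "-")))
  }
  structure(idx, coverage = coverage, flagged = flagged)
}

# Per-chain C-alpha selections for a scheme role; returns a named list of
# index vectors over model$atoms, one per assembly chain.
scheme_selection <- function(model, scheme, role, chains = NULL,
                             atom_filter = "ca_only") {
  rng <- scheme[[role]]
  if (is.null(rng)) abort(sprintf("scheme range '%s' is unset", role))
  chains <- chains %||% model$assembly_chains
  sel <- lapply(chains, function(ch) {
    select_atoms(model, chain = ch, range = rng, atom_filter = atom_filter,
                 coverage_floor = scheme$coverage_floor)
  })
  setNames(sel, chains)
}
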