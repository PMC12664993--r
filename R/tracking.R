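#' Align a trajectory on the TMD C-alpha atoms of a reference
#'
#' Every frame is rigidly superposed (via [superpose()]) onto the
#' reference's TMD alignment selection, the standard pre-processing step
#' before any domain-displacement measurement: whatever global rigid motion
#' contaminates the raw frames is removed exactly when the TMD is
#' internally rigid.
#'
#' @param traj a [pent_trajectory()].
#' @param reference a [pent_structure()]; defaults to the trajectory
#'   topology.
#' @param scheme a [domain_scheme()]; `tmd_align` defines the fit
#'   selection.
#' @return an aligned [pent_trajectory()]; attribute `"tmd_rmsd"` holds the
#'   per-frame post-fit RMSD (Angstrom).
#' @export
align_trajectory <- function(traj, reference = NULL, scheme = domain_scheme()) {
  reference <- reference %||% traj$topology
  sel_top <- unlist(scheme_selection(traj$topology, scheme, "tmd_align"))
  sel_ref <- unlist(scheme_selection(reference, scheme, "tmd_align"))
  if (length(sel_top) != length(sel_ref)) {
    abort(sprintf(
      "alignment correspondence mismatch: %d topology vs %d reference TMD atoms",
      length(sel_top), length(sel_ref)))
  }
  if (length(sel_top) < 3L) abort("alignment selection too small")
  ref_xyz <- model_coords(reference, sel_ref)
  out <- traj$coords
  fit_rmsd <- numeric(n_frames(traj))
  for (i in seq_len(n_frames(traj))) {
    xyz <- traj$coords[, , i]
    tr <- superpose(xyz[sel_top, , drop = FALSE], ref_xyz)
    out[, , i] <- apply_transform(tr, xyz)
    fit_rmsd[i] <- tr$rmsd
  }
  aligned <- pent_trajectory(traj$topology, out, times = traj$times,
                             replicate_id = traj$replicate_id)
  attr(aligned, "tmd_rmsd") <- fit_rmsd
  attr(aligned, "aligned") <- TRUE
  aligned
}

#' Pore axis of a structural model
#'
#' Convenience wrapper around [estimate_axis()] using the scheme's
#' TMD-twist selection (the membrane-embedded helix bundle, a ring-like
#' atom set whose smallest-spread direction is the channel axis) and the
#' NTD tracking selection for the periplasmic sign convention.
#'
#' @param model a [pent_structure()].
#' @param scheme a [domain_scheme()].
#' @return a `pore_axis`.
#' @export
model_axis <- function(model, scheme = domain_scheme()) {
  assert_pentamer(model)
  sel <- scheme_selection(model, scheme, "tmd_twist")
  idx <- unlist(sel)
  ntd <- tryCatch(unlist(scheme_selection(model, scheme, "ntd_track")),
                  warning = function(w) integer(0))
  estimate_axis(model_coords(model, idx), model$atoms$chain[idx],
                ntd_xyz = if (length(ntd)) model_coords(model, ntd) else NULL)
}

#' Trace the center of mass of an NTD lobe through a trajectory
#'
#' Per-frame C-alpha COM of one lobe of one chain, in the aligned frame of
#' reference: displacement from its first-frame position (the "initial
#' pose"), plus the (radial, z) decomposition about the pore axis used for
#' lobe-position maps.
#'
#' @param aligned an aligned [pent_trajectory()] (see [align_trajectory()]).
#' @param chain chain id.
#' @param lobe `"ntd1"`, `"ntd2"`, `"ntd_track"`, or an explicit residue
#'   range `c(lo, hi)`.
#' @param axis a `pore_axis`; defaults to [model_axis()] of the topology.
#' @param scheme a [domain_scheme()]. Lobe ranges must be set in the scheme
#'   when `lobe` is a name.
#' @return tibble of class `lobe_trace`: `replicate`, `frame`, `time_ns`,
#'   `chain`, `lobe`, `com_x/y/z`, `displacement`, `radial`, `z`.
#' @export
lobe_trace <- function(aligned, chain, lobe = "ntd1", axis = NULL,
                       scheme = domain_scheme()) {
  model <- aligned$topology
  rng <- if (is.numeric(lobe)) {
    lab <- paste(lobe, collapse = "-")
    as.integer(lobe)
  } else {
    lab <- lobe
    r <- scheme[[lobe]]
    if (is.null(r)) abort(sprintf(
      "lobe range '%s' is unset in the scheme; supply ntd1/ntd2 ranges", lobe))
    r
  }
  idx <- select_atoms(model, chain = chain, range = rng,
                      atom_filter = "ca_only",
                      coverage_floor = scheme$coverage_floor)
  if (!length(idx)) abort(sprintf("no lobe atoms for chain %s", chain))
  axis <- axis %||% model_axis(model, scheme)
  nf <- n_frames(aligned)
  com <- t(vapply(seq_len(nf), function(i) {
    colMeans(aligned$coords[idx, , i, drop = FALSE])
  }, numeric(3)))
  disp <- sqrt(rowSums(sweep(com, 2, com[1, ])^2))
  dec <- axis_decompose(axis, com)
  out <- tibble(replicate = aligned$replicate_id, frame = seq_len(nf),
                time_ns = aligned$times, chain = chain, lobe = lab,
                com_x = com[, 1], com_y = com[, 2], com_z = com[, 3],
                displacement = disp, radial = dec$radial, z = dec$z)
  attr(out, "flagged") <- isTRUE(attr(idx, "flagged"))
  class(out) <- c("lobe_trace", class(out))
  out
}

#' Trace every lobe of every chain
#'
#' @param aligned an aligned [pent_trajectory()].
#' @param lobes lobe names to trace (must be set in the scheme).
#' @inheritParams lobe_trace
#' @return row-bound [lobe_trace()] tibble.
#' @export
lobe_traces <- function(aligned, lobes = c("ntd1", "ntd2"), axis = NULL,
                        scheme = domain_scheme()) {
  axis <- axis %||% model_axis(aligned$topology, scheme)
  out <- purrr::map_dfr(lobes, function(lb) {
    purrr::map_dfr(aligned$topology$assembly_chains, function(ch) {
      lobe_trace(aligned, ch, lobe = lb, axis = axis, scheme = scheme)
    })
  })
  class(out) <- c("lobe_trace", class(out))
  out
}

#' Pooled displacement summary per lobe
#'
#' Median and extrema of the per-frame COM displacement, pooled over
#' chains, frames and replicates (the pooled maximum is the headline
#' "deviated up to X Angstrom" number for a condition).
#'
#' @param traces a [lobe_trace()] tibble (one or many traces row-bound).
#' @param pool_by extra grouping columns (e.g. `"replicate"`, `"chain"`).
#' @return tibble with `lobe`, `median`, `min`, `max`, `range`, `n`.
#' @export
displacement_summary <- function(traces, pool_by = NULL) {
  if (!nrow(traces)) abort("displacement_summary: empty input")
  traces |>
    group_by(across(all_of(c("lobe", pool_by)))) |>
    summarise(
      median = stats::median(.data$displacement),
      min = min(.data$displacement),
      max = max(.data$displacement),
      range = max(.data$displacement) - min(.data$displacement),
      n = dplyr::n(),
      .groups = "drop"
    )
}
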