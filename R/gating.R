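#' Per-subunit ECD twist
#'
#' The global gating coordinate of the pLGIC extracellular domain: for each
#' subunit, the dihedral angle through four C-alpha centers of mass —
#' (a) the subunit's ECD block, (b) the ECD block of all five subunits,
#' (c) the TMD block of all five subunits, (d) the subunit's TMD block.
#' "All subunits" includes the subunit under evaluation. The dihedral is
#' invariant under rigid motion, so no alignment is required; a static
#' model is treated as its own single frame.
#'
#' @param model a [pent_structure()] with five assembly chains.
#' @param scheme a [domain_scheme()]; the `ecd_twist` and `tmd_twist`
#'   ranges define the COM blocks.
#' @return tibble with columns `chain` and `value` (degrees). A chain whose
#'   block coverage fails entirely gets `NA` with a warning rather than an
#'   error.
#' @examples
#' m <- build_pentamer(pentamer_spec(twist_deg = -26))
#' ecd_twist(m)
#' @export
ecd_twist <- function(model, scheme = domain_scheme()) {
  assert_pentamer(model)
  sel_e <- scheme_selection(model, scheme, "ecd_twist")
  sel_t <- scheme_selection(model, scheme, "tmd_twist")
  xyz <- model_coords(model)
  twist_from_selections(xyz, sel_e, sel_t, model$assembly_chains)
}

twist_from_selections <- function(xyz, sel_e, sel_t, chains) {
  com_all_e <- colMeans(xyz[unlist(sel_e), , drop = FALSE])
  com_all_t <- colMeans(xyz[unlist(sel_t), , drop = FALSE])
  vals <- vapply(chains, function(ch) {
    ie <- sel_e[[ch]]; it <- sel_t[[ch]]
    if (!length(ie) || !length(it)) return(NA_real_)
    dihedral_angle(colMeans(xyz[ie, , drop = FALSE]), com_all_e,
                   com_all_t, colMeans(xyz[it, , drop = FALSE]))
  }, numeric(1))
  if (anyNA(vals)) {
    warn(sprintf("ECD twist undefined for chain(s): %s",
                 paste(chains[is.na(vals)], collapse = ", ")))
  }
  tibble(chain = chains, value = unname(vals))
}

#' Per-subunit beta-expansion
#'
#' The second global gating coordinate: for each subunit, the Euclidean
#' distance between the C-alpha centers of mass of the beta-1 and beta-10
#' strand regions, which straddle the ECD-TMD interface.
#'
#' @inheritParams ecd_twist
#' @return tibble with columns `chain` and `value` (Angstrom).
#' @export
beta_expansion <- function(model, scheme = domain_scheme()) {
  assert_pentamer(model)
  sel1 <- scheme_selection(model, scheme, "beta1")
  sel10 <- scheme_selection(model, scheme, "beta10")
  xyz <- model_coords(model)
  expansion_from_selections(xyz, sel1, sel10, model$assembly_chains)
}

expansion_from_selections <- function(xyz, sel1, sel10, chains) {
  vals <- vapply(chains, function(ch) {
    i1 <- sel1[[ch]]; i10 <- sel10[[ch]]
    if (!length(i1) || !length(i10)) return(NA_real_)
    d <- colMeans(xyz[i1, , drop = FALSE]) - colMeans(xyz[i10, , drop = FALSE])
    sqrt(sum(d^2))
  }, numeric(1))
  if (anyNA(vals)) {
    warn(sprintf("beta-expansion undefined for chain(s): %s",
                 paste(chains[is.na(vals)], collapse = ", ")))
  }
  tibble(chain = chains, value = unname(vals))
}

#' Gating metrics over a trajectory
#'
#' Evaluates ECD twist and/or beta-expansion on every frame of a
#' trajectory, returning a long metric series suitable for pooling across
#' replicates.
#'
#' @param traj a [pent_trajectory()].
#' @param scheme a [domain_scheme()].
#' @param metrics subset of `c("ecd_twist", "beta_expansion")`.
#' @return tibble of class `metric_series` with columns `replicate`,
#'   `frame`, `time_ns`, `chain`, `metric`, `value`, `units`.
#' @export
gating_series <- function(traj, scheme = domain_scheme(),
                          metrics = c("ecd_twist", "beta_expansion")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  model <- traj$topology
  assert_pentamer(model)
  chains <- model$assembly_chains
  sels <- list()
  if ("ecd_twist" %in% metrics) {
    sels$e <- scheme_selection(model, scheme, "ecd_twist")
    sels$t <- scheme_selection(model, scheme, "tmd_twist")
  }
  if ("beta_expansion" %in% metrics) {
    sels$b1 <- scheme_selection(model, scheme, "beta1")
    sels$b10 <- scheme_selection(model, scheme, "beta10")
  }
  rows <- purrr::map_dfr(seq_len(n_frames(traj)), function(i) {
    xyz <- traj_frame(traj, i)
    out <- list()
    if ("ecd_twist" %in% metrics) {
      tw <- twist_from_selections(xyz, sels$e, sels$t, chains)
      out$tw <- tibble(frame = i, time_ns = traj$times[i], chain = tw$chain,
                       metric = "ecd_twist", value = tw$value,
                       units = "degrees")
    }
    if ("beta_expansion" %in% metrics) {
      be <- expansion_from_selections(xyz, sels$b1, sels$b10, chains)
      out$be <- tibble(frame = i, time_ns = traj$times[i], chain = be$chain,
                       metric = "beta_expansion", value = be$value,
                       units = "angstrom")
    }
    bind_rows(out)
  })
  out <- bind_cols(tibble(replicate = traj$replicate_id), rows)
  class(out) <- c("metric_series", class(out))
  out
}

#' Pooled summary of a metric series
#'
#' Median, extrema and range (max - min) over the pooled values. By default
#' everything is pooled per metric — all chains, frames and replicates —
#' matching the single-number-per-condition convention for reporting metric
#' ranges; pass grouping columns for per-replicate or per-chain summaries.
#'
#' @param series a metric series (long tibble with `metric` and `value`),
#'   e.g. from [gating_series()].
#' @param pool_by extra grouping columns kept separate (e.g. `"replicate"`).
#' @return tibble with `median`, `min`, `max`, `range`, `n` per group.
#' @export
summarize_metrics <- function(series, pool_by = NULL) {
  if (!all(c("metric", "value") %in% names(series))) {
    abort("series must have 'metric' and 'value' columns")
  }
  vals <- series$value[is.finite(series$value)]
  if (!length(vals)) abort("summarize_metrics: empty pool")
  series |>
    filter(is.finite(.data$value)) |>
    group_by(across(all_of(c("metric", pool_by)))) |>
    summarise(
      median = stats::median(.data$value),
      min = min(.data$value),
      max = max(.data$value),
      range = max(.data$value) - min(.data$value),
      n = dplyr::n(),
      .groups = "drop"
    )
}
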