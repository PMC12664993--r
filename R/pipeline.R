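#' Full conformational analysis of a single structural model
#'
#' Bundles the per-subunit gating metrics (ECD twist, beta-expansion), the
#' sphere-probe pore profile (annotated at prime positions when the scheme
#' provides a prime map) and per-ion coordination tables with site
#' classification into one report object.
#'
#' @param model a [pent_structure()] with five assembly chains.
#' @param scheme a [domain_scheme()].
#' @param site_definitions cation-site definitions,
#'   default [default_site_definitions()].
#' @param condition free-text condition label (e.g. `"with_calcium"`)
#'   carried verbatim into all outputs.
#' @param pore compute the pore profile (TRUE/FALSE).
#' @param shell_cutoff coordination-shell cutoff (Angstrom).
#' @param ... passed to [pore_radius_profile()].
#' @return object of class `pent_report`.
#' @export
run_structure_analysis <- function(model, scheme = domain_scheme(),
                                   site_definitions = default_site_definitions(),
                                   condition = "custom", pore = TRUE,
                                   shell_cutoff = 3.5, ...) {
  assert_pentamer(model)
  twist <- ecd_twist(model, scheme) |>
    mutate(condition = condition, metric = "ecd_twist", units = "degrees")
  expansion <- beta_expansion(model, scheme) |>
    mutate(condition = condition, metric = "beta_expansion", units = "angstrom")

  profile <- NULL
  if (isTRUE(pore)) {
    profile <- pore_radius_profile(model, scheme = scheme, ...)
    if (!is.null(scheme$prime_map)) {
      profile <- annotate_primes(profile, model, scheme)
    }
  }

  ions <- ion_table(model)
  contacts <- NULL
  assignments <- NULL
  site_distances <- NULL
  if (nrow(ions)) {
    contacts <- purrr::map_dfr(ions$ion_id, function(id) {
      coordination_shell(model, id, cutoff = shell_cutoff)
    })
    if (nrow(contacts)) {
      assignments <- classify_sites(contacts, site_definitions)
      assigned <- assignments |> filter(.data$site != "unassigned")
      if (nrow(assigned)) {
        site_distances <- purrr::pmap_dfr(
          assigned[c("ion_id", "site")],
          function(ion_id, site) {
            cc <- contacts[contacts$ion_id == ion_id, ]
            partners <- site_definitions[[site]]$partners
            present <- purrr::map2_lgl(
              partners$res_seq, partners$partner_class,
              function(rs, pc) any(cc$res_seq == rs & cc$partner_class == pc))
            tibble(ion_id = ion_id, site = site,
                   n_partners_present = sum(present),
                   n_partners_required = nrow(partners),
                   max_distance = max_coordination_distance(
                     cc, partners[present, , drop = FALSE]))
          })
      }
    }
  } else {
    inform("no bound cations in model; ion section empty")
  }

  structure(list(
    kind = "structure", condition = condition,
    twist = twist, expansion = expansion, pore_profile = profile,
    ions = ions, contacts = contacts, site_assignments = assignments,
    site_distances = site_distances,
    config = list(condition = condition, shell_cutoff = shell_cutoff,
                  scheme = unclass(scheme))
  ), class = "pent_report")
}

#' Full conformational analysis of replicate trajectories
#'
#' Aligns each replicate on the reference TMD, evaluates the gating metric
#' series over all frames, pools summaries (all chains, frames and
#' replicates together, plus per-replicate for transparency), traces NTD
#' lobe COMs when the scheme defines lobe ranges, summarizes ion residence
#' for every cation in the topology, and averages pore profiles over a
#' frame subsample.
#'
#' @param trajs a [pent_trajectory()] or list of them (replicates).
#' @param reference alignment reference model; defaults to each
#'   trajectory's topology.
#' @param scheme a [domain_scheme()].
#' @param condition condition label.
#' @param residence_threshold bound/unbound threshold (Angstrom).
#' @param profile_frames number of evenly spaced frames per replicate for
#'   pore profiling (0 disables).
#' @param profile_args list of extra arguments for [pore_radius_profile()]
#'   (e.g. `z_window`, `z_step`, `cap_radius`).
#' @return object of class `pent_report`.
#' @export
run_trajectory_analysis <- function(trajs, reference = NULL,
                                    scheme = domain_scheme(),
                                    condition = "custom",
                                    residence_threshold = 5,
                                    profile_frames = 5,
                                    profile_args = list()) {
  if (inherits(trajs, "pent_trajectory")) trajs <- list(trajs)
  aligned <- lapply(trajs, align_trajectory, reference = reference,
                    scheme = scheme)

  series <- purrr::map_dfr(aligned, gating_series, scheme = scheme)
  summary_pooled <- summarize_metrics(series)
  summary_by_rep <- summarize_metrics(series, pool_by = "replicate")

  traces <- NULL
  trace_summary <- NULL
  if (!is.null(scheme$ntd1) || !is.null(scheme$ntd2)) {
    lobes <- c(if (!is.null(scheme$ntd1)) "ntd1",
               if (!is.null(scheme$ntd2)) "ntd2")
    traces <- purrr::map_dfr(aligned, lobe_traces, lobes = lobes,
                             scheme = scheme)
    trace_summary <- displacement_summary(traces)
  } else {
    inform("scheme has no ntd1/ntd2 ranges; lobe tracking skipped")
  }

  ions <- ion_table(aligned[[1]]$topology)
  residence <- NULL
  res_summary <- NULL
  if (nrow(ions)) {
    residence <- purrr::map_dfr(aligned, function(tr) {
      purrr::map_dfr(ions$ion_id, function(id) {
        ion_residence(tr, id, threshold = residence_threshold)
      })
    })
    res_summary <- residence_summary(residence)
  }

  pore <- NULL
  if (profile_frames > 0) {
    long <- purrr::map_dfr(aligned, function(tr) {
      fr <- unique(round(seq(1, n_frames(tr),
                             length.out = min(profile_frames, n_frames(tr)))))
      do.call(traj_pore_profiles,
              c(list(tr, frames = fr, scheme = scheme), profile_args))
    })
    pore <- profile_stats(long)
  }

  structure(list(
    kind = "trajectory", condition = condition,
    series = series, summary_pooled = summary_pooled,
    summary_by_replicate = summary_by_rep,
    lobe_traces = traces, lobe_summary = trace_summary,
    residence = residence, residence_summary = res_summary,
    pore_profile = pore,
    config = list(condition = condition,
                  residence_threshold = residence_threshold,
                  profile_frames = profile_frames,
                  n_replicates = length(aligned),
                  scheme = unclass(scheme))
  ), class = "pent_report")
}

#' @export
print.pent_report <- function(x, ...) {
  cat(sprintf("<pent_report> %s analysis, condition '%s'\n",
              x$kind, x$condition))
  nm <- setdiff(names(x), c("kind", "condition", "config"))
  for (n in nm) {
    v <- x[[n]]
    if (is.null(v)) next
    cat(sprintf("  $%s: %s\n", n,
                if (is.data.frame(v)) sprintf("%d rows", nrow(v)) else class(v)[1]))
  }
  invisible(x)
}

#' Tidy a report into one long metric table
#'
#' @param x a `pent_report`.
#' @param ... unused.
#' @return tibble with `condition`, `metric`, grouping columns and `value`.
#' @export
tidy.pent_report <- function(x, ...) {
  if (x$kind == "structure") {
    out <- bind_rows(x$twist, x$expansion) |>
      select("condition", "metric", "chain", "value", "units")
  } else {
    out <- x$series |>
      mutate(condition = x$condition) |>
      select("condition", "metric", "replicate", "frame", "time_ns",
             "chain", "value", "units")
  }
  as_tibble(out)
}

#' One-row overview of a report
#'
#' @param x a `pent_report`.
#' @param ... unused.
#' @return one-row tibble.
#' @export
glance.pent_report <- function(x, ...) {
  if (x$kind == "structure") {
    tibble(
      condition = x$condition, kind = x$kind,
      twist_mean = mean(x$twist$value, na.rm = TRUE),
      expansion_mean = mean(x$expansion$value, na.rm = TRUE),
      pore_min_radius = if (!is.null(x$pore_profile)) min(x$pore_profile$radius) else NA_real_,
      n_ions = nrow(x$ions)
    )
  } else {
    sp <- x$summary_pooled
    rng <- function(m) {
      v <- sp$range[sp$metric == m]
      if (length(v)) v else NA_real_
    }
    tibble(
      condition = x$condition, kind = x$kind,
      n_replicates = x$config$n_replicates,
      twist_range = rng("ecd_twist"),
      expansion_range = rng("beta_expansion"),
      ntd1_max_displacement = max_or_na(x$lobe_summary, "ntd1"),
      ntd2_max_displacement = max_or_na(x$lobe_summary, "ntd2")
    )
  }
}

max_or_na <- function(lobe_summary, lobe) {
  if (is.null(lobe_summary)) return(NA_real_)
  v <- lobe_summary$max[lobe_summary$lobe == lobe]
  if (length(v)) v else NA_real_
}

#' Write a report bundle to disk
#'
#' Plain tabular files (TSV) plus a machine-readable JSON summary and the
#' resolved configuration (with the package version and a config hash) so
#' a run is fully auditable and re-runnable.
#'
#' @param report a `pent_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (is.null(df) || !is.data.frame(df)) return(invisible(NULL))
    utils::write.table(df, file.path(dir, paste0(name, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  for (n in setdiff(names(report), c("kind", "condition", "config"))) {
    wr(report[[n]], n)
  }
  if (!is.null(report$pore_profile)) {
    primes <- attr(report$pore_profile, "primes")
    wr(primes, "pore_primes")
  }
  meta <- list(
    kind = report$kind, condition = report$condition,
    package_version = as.character(utils::packageVersion("pentagate")),
    config_hash = rlang::hash(report$config),
    glance = glance(report)
  )
  jsonlite::write_json(meta, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(report$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
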