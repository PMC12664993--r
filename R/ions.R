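CATION_ELEMENTS <- c("CA", "MG", "NA", "K", "ZN", "MN", "FE", "BA", "SR")

#' List bound cations in a model
#'
#' Hetero records whose element is a common cation. Ions are identified
#' throughout the package by `"chain:res_seq"` ids.
#'
#' @param model a [pent_structure()].
#' @return tibble with `ion_id`, `chain`, `res_seq`, `res_name`, `element`
#'   and the atom row index.
#' @export
ion_table <- function(model) {
  a <- model$atoms
  idx <- which(a$is_hetero & toupper(a$element) %in% CATION_ELEMENTS)
  tibble(ion_id = paste(a$chain[idx], a$res_seq[idx], sep = ":"),
         chain = a$chain[idx], res_seq = a$res_seq[idx],
         res_name = a$res_name[idx], element = a$element[idx],
         atom_index = idx)
}

ion_index <- function(model, ion_id) {
  tab <- ion_table(model)
  hit <- tab$atom_index[tab$ion_id == ion_id]
  if (!length(hit)) {
    abort(sprintf("unknown ion id '%s' (known: %s)", ion_id,
                  paste(head(tab$ion_id, 20), collapse = ", ")))
  }
  hit[1]
}

classify_partner <- function(is_hetero, res_name, atom_name, element) {
  dplyr::case_when(
    is_hetero & res_name %in% c("HOH", "WAT", "TIP", "SOL") ~ "water_O",
    !is_hetero & element == "O" & atom_name == "O" ~ "backbone_carbonyl_O",
    !is_hetero & element == "O" ~ "sidechain_O",
    TRUE ~ "other"
  )
}

#' Coordination shell of a bound cation
#'
#' All oxygen (optionally also nitrogen) heavy atoms within `cutoff` of the
#' ion, classified as side-chain O, backbone carbonyl O (protein atom named
#' "O"), water O, or other, and sorted deterministically by
#' (distance, chain, res_seq, atom_name). Hydrogens are never counted:
#' coordination distances are heavy-atom distances.
#'
#' @param model a [pent_structure()].
#' @param ion_id ion id from [ion_table()].
#' @param cutoff shell cutoff in Angstrom (default 3.5, a generous upper
#'   bound over typical printed Ca-O coordination distances).
#' @param include_nitrogen also admit protein N atoms.
#' @return tibble of contacts: `ion_id`, `chain`, `res_seq`, `res_name`,
#'   `atom_name`, `element`, `distance`, `partner_class`.
#' @export
coordination_shell <- function(model, ion_id, cutoff = 3.5,
                               include_nitrogen = FALSE) {
  if (cutoff <= 0) abort("cutoff must be > 0")
  i <- ion_index(model, ion_id)
  a <- model$atoms
  ion_xyz <- c(a$x[i], a$y[i], a$z[i])
  elems <- c("O", if (include_nitrogen) "N")
  cand <- which(a$element %in% elems)
  cand <- setdiff(cand, i)
  if (!length(cand)) {
    return(empty_contacts())
  }
  d <- sqrt((a$x[cand] - ion_xyz[1])^2 + (a$y[cand] - ion_xyz[2])^2 +
              (a$z[cand] - ion_xyz[3])^2)
  keep <- d <= cutoff
  cand <- cand[keep]; d <- d[keep]
  if (!length(cand)) return(empty_contacts())
  out <- tibble(
    ion_id = ion_id,
    chain = a$chain[cand], res_seq = a$res_seq[cand],
    res_name = a$res_name[cand], atom_name = a$atom_name[cand],
    element = a$element[cand], distance = d,
    partner_class = classify_partner(a$is_hetero[cand], a$res_name[cand],
                                     a$atom_name[cand], a$element[cand])
  )
  arrange(out, .data$distance, .data$chain, .data$res_seq, .data$atom_name)
}

empty_contacts <- function() {
  tibble(ion_id = character(), chain = character(), res_seq = integer(),
         res_name = character(), atom_name = character(),
         element = character(), distance = double(),
         partner_class = character())
}

#' Shipped cation-site definitions
#'
#' The four site archetypes of the DeCLIC periplasmic domains, as required
#' partner lists (residue + partner class): Site 1 — NTD1 Asp76/Asp123/
#' Asp124 side-chain O plus Pro77/Asp123/Tyr129 backbone carbonyls; Site 2
#' — backbone carbonyls of Asp124/Gly126/Gly128; Site 3 — ECD-interface
#' Glu347 side chain plus Pro434/Phe436/Leu477 carbonyls; Site 4 — Glu480
#' side chain plus Gln476/Gly478 carbonyls. The default match threshold of
#' 0.5 lets the loosely coordinated Sites 2 and 4 still classify.
#'
#' @return named list of definitions, each with `label`, `partners`
#'   (tibble of `res_seq`, `partner_class`) and `threshold`.
#' @export
default_site_definitions <- function() {
  def <- function(label, res_seq, partner_class, threshold = 0.5) {
    list(label = label,
         partners = tibble(res_seq = as.integer(res_seq),
                           partner_class = partner_class),
         threshold = threshold)
  }
  list(
    Site1 = def("Site1", c(76, 123, 124, 77, 123, 129),
                c(rep("sidechain_O", 3), rep("backbone_carbonyl_O", 3))),
    Site2 = def("Site2", c(124, 126, 128), rep("backbone_carbonyl_O", 3)),
    Site3 = def("Site3", c(347, 434, 436, 477),
                c("sidechain_O", rep("backbone_carbonyl_O", 3))),
    Site4 = def("Site4", c(480, 476, 478),
                c("sidechain_O", rep("backbone_carbonyl_O", 2)))
  )
}

#' Read site definitions from YAML
#'
#' Format: a mapping from site label to `threshold` plus a `partners` list
#' of `{res_seq, partner_class}` entries.
#'
#' @param path YAML file path.
#' @return list of definitions as in [default_site_definitions()].
#' @export
read_site_definitions <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(setNames(names(cfg), names(cfg)), function(lbl) {
    d <- cfg[[lbl]]
    partners <- bind_rows(lapply(d$partners, as_tibble))
    if (!nrow(partners)) abort(sprintf("site '%s' has no partners", lbl))
    list(label = lbl, partners = partners,
         threshold = d$threshold %||% 0.5)
  })
}

#' Classify ions into cation sites by coordination shell
#'
#' Each ion is matched against every site definition: the matched fraction
#' is the share of required (residue, partner-class) pairs present among
#' the ion's contacts. The ion takes the best-matching label above its
#' threshold; exact ties report all tied labels with a tie flag; no match
#' above threshold leaves the ion `"unassigned"`.
#'
#' @param contacts contact table from [coordination_shell()] (one or many
#'   ions row-bound).
#' @param definitions list of site definitions,
#'   default [default_site_definitions()].
#' @return tibble: `ion_id`, `site`, `matched_fraction`, `tie`.
#' @export
classify_sites <- function(contacts, definitions = default_site_definitions()) {
  if (!length(definitions)) abort("no site definitions supplied")
  ids <- unique(contacts$ion_id)
  purrr::map_dfr(ids, function(id) {
    cc <- contacts[contacts$ion_id == id, ]
    frac <- vapply(definitions, function(d) {
      hit <- purrr::map2_lgl(d$partners$res_seq, d$partners$partner_class,
                             function(rs, pc) {
                               any(cc$res_seq == rs & cc$partner_class == pc)
                             })
      mean(hit)
    }, numeric(1))
    thr <- vapply(definitions, `[[`, numeric(1), "threshold")
    ok <- frac >= thr & frac > 0
    if (!any(ok)) {
      return(tibble(ion_id = id, site = "unassigned",
                    matched_fraction = max(frac), tie = FALSE))
    }
    best <- max(frac[ok])
    winners <- names(definitions)[ok & frac == best]
    tibble(ion_id = id, site = winners, matched_fraction = best,
           tie = length(winners) > 1)
  })
}

#' Maximum coordination distance over named partners
#'
#' @param contacts contact table for one ion.
#' @param partners tibble with `res_seq` and `partner_class` (e.g. a site
#'   definition's `partners`), or an integer vector of residue numbers.
#' @return maximum heavy-atom distance (Angstrom) over the named partners.
#' @export
max_coordination_distance <- function(contacts, partners) {
  if (is.numeric(partners)) {
    partners <- tibble(res_seq = as.integer(partners),
                       partner_class = NA_character_)
  }
  d <- purrr::map2_dbl(partners$res_seq, partners$partner_class,
                       function(rs, pc) {
    hit <- contacts$res_seq == rs &
      (is.na(pc) | contacts$partner_class == pc)
    if (!any(hit)) NA_real_ else min(contacts$distance[hit])
  })
  if (anyNA(d)) {
    miss <- partners[is.na(d), ]
    pc <- ifelse(is.na(miss$partner_class), "*", miss$partner_class)
    abort(sprintf("partners absent from contacts: %s",
                  paste(sprintf("%d/%s", miss$res_seq, pc), collapse = ", ")))
  }
  max(d)
}

#' Ion residence through an aligned trajectory
#'
#' Tracks the displacement of one ion from its initial (first-frame) pose
#' in the TMD-aligned frame of reference, so whole-channel drift does not
#' register as unbinding. The ion counts as bound while its displacement
#' stays below the threshold.
#'
#' @param aligned an aligned [pent_trajectory()].
#' @param ion_id ion id from [ion_table()] of the topology.
#' @param threshold bound/unbound displacement threshold (Angstrom,
#'   default 5).
#' @return tibble of class `residence_series`: `replicate`, `frame`,
#'   `time_ns`, `ion_id`, `displacement`, `bound`.
#' @export
ion_residence <- function(aligned, ion_id, threshold = 5) {
  i <- ion_index(aligned$topology, ion_id)
  nf <- n_frames(aligned)
  pos <- t(vapply(seq_len(nf), function(k) aligned$coords[i, , k], numeric(3)))
  disp <- sqrt(rowSums(sweep(pos, 2, pos[1, ])^2))
  out <- tibble(replicate = aligned$replicate_id, frame = seq_len(nf),
                time_ns = aligned$times, ion_id = ion_id,
                displacement = disp, bound = disp < threshold)
  class(out) <- c("residence_series", class(out))
  out
}

#' Residence summary per ion
#'
#' @param series one or many row-bound [ion_residence()] series.
#' @return tibble per (`replicate`, `ion_id`): `bound_fraction`,
#'   `bound_at_end`, `max_displacement`.
#' @export
residence_summary <- function(series) {
  series |>
    group_by(.data$replicate, .data$ion_id) |>
    summarise(
      bound_fraction = mean(.data$bound),
      bound_at_end = .data$bound[which.max(.data$frame)],
      max_displacement = max(.data$displacement),
      n_frames = dplyr::n(),
      .groups = "drop"
    )
}
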