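#' Domain scheme: named residue-range selections per structural role
#'
#' A pLGIC subunit decomposes into stacked blocks: the periplasmic N-terminal
#' domain lobes (NTD1, NTD2), the canonical extracellular beta-sandwich (ECD)
#' and the four-helix transmembrane domain (TMD). All analyses in this package
#' select atoms through a `domain_scheme`, a named set of author-numbered
#' residue ranges plus an optional map from M2 prime positions (2', 9', 16')
#' to residue numbers.
#'
#' Defaults follow the DeCLIC numbering convention used throughout the
#' package: trajectory alignment on TMD residues 328-639, ECD-twist blocks
#' 328-513 (ECD) and 515-636 (TMD), beta-expansion strands 340-345 (beta-1)
#' and 511-515 (beta-10), and NTD tracking over residues 35-195. Residue 514
#' and 637-639 deliberately belong to the alignment range but to neither
#' twist block; the scheme reproduces the published residue arithmetic
#' verbatim rather than "fixing" it. NTD1/NTD2 lobe ranges have no universal
#' default and must be supplied for two-lobe tracking (the synthetic
#' generator supplies its own: 35-195 and 196-325).
#'
#' @param ntd_track integer range (c(lo, hi)) for whole-NTD COM tracking.
#' @param ecd_twist,tmd_twist ranges for the twist dihedral COM blocks.
#' @param tmd_align range for trajectory superposition.
#' @param beta1,beta10 ranges for the beta-expansion COM blocks.
#' @param ntd1,ntd2 lobe ranges, or NULL if unknown (lobe tracking then
#'   requires explicit ranges).
#' @param prime_map named numeric vector mapping prime labels (e.g. `"2'"`)
#'   to residue numbers, or NULL. Values must fall inside the TMD ranges.
#' @param coverage_floor minimum fraction of residues in a range that must
#'   resolve to atoms before a selection is flagged (default 0.8).
#'
#' @return An object of class `domain_scheme` (a named list of ranges).
#' @examples
#' sch <- domain_scheme()
#' sch$beta1
#' @export
domain_scheme <- function(ntd_track = c(35L, 195L),
                          ecd_twist = c(328L, 513L),
                          tmd_twist = c(515L, 636L),
                          tmd_align = c(328L, 639L),
                          beta1 = c(340L, 345L),
                          beta10 = c(511L, 515L),
                          ntd1 = NULL,
                          ntd2 = NULL,
                          prime_map = NULL,
                          coverage_floor = 0.8) {
  rng <- function(x, nm) {
    if (is.null(x)) return(NULL)
    x <- as.integer(x)
    if (length(x) != 2L || any(is.na(x)) || x[2] < x[1]) {
      abort(sprintf("range '%s' must be c(lo, hi) with lo <= hi", nm))
    }
    x
  }
  sch <- structure(list(
    ntd_track = rng(ntd_track, "ntd_track"),
    ecd_twist = rng(ecd_twist, "ecd_twist"),
    tmd_twist = rng(tmd_twist, "tmd_twist"),
    tmd_align = rng(tmd_align, "tmd_align"),
    beta1 = rng(beta1, "beta1"),
    beta10 = rng(beta10, "beta10"),
    ntd1 = rng(ntd1, "ntd1"),
    ntd2 = rng(ntd2, "ntd2"),
    prime_map = prime_map,
    coverage_floor = coverage_floor
  ), class = "domain_scheme")
  validate_scheme(sch)
  sch
}

validate_scheme <- function(sch) {
  b1 <- seq(sch$beta1[1], sch$beta1[2])
  b10 <- seq(sch$beta10[1], sch$beta10[2])
  if (length(intersect(b1, b10)) > 0L) {
    abort("beta1 and beta10 ranges must be disjoint")
  }
  if (!is.null(sch$prime_map)) {
    if (is.null(names(sch$prime_map)) || any(!nzchar(names(sch$prime_map)))) {
      abort("prime_map must be a named numeric vector (names are prime labels)")
    }
    tmd_res <- union(
      seq(sch$tmd_twist[1], sch$tmd_twist[2]),
      seq(sch$tmd_align[1], sch$tmd_align[2])
    )
    bad <- !(sch$prime_map %in% tmd_res)
    if (any(bad)) {
      abort(sprintf(
        "prime_map positions outside TMD ranges: %s",
        paste(names(sch$prime_map)[bad], collapse = ", ")
      ))
    }
  }
  invisible(sch)
}

#' Read a domain scheme from a YAML config file
#'
#' Keys mirror the arguments of [domain_scheme()]; ranges are given as
#' two-element lists and `prime_map` as a mapping from label to residue.
#' Missing keys fall back to the package defaults.
#'
#' @param path path to a YAML file.
#' @return A `domain_scheme`.
#' @export
read_domain_scheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("ntd_track", "ecd_twist", "tmd_twist", "tmd_align", "beta1",
             "beta10", "ntd1", "ntd2", "prime_map", "coverage_floor")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) warn(paste0("ignoring unknown scheme keys: ",
                                 paste(extra, collapse = ", ")))
  cfg <- cfg[intersect(names(cfg), known)]
  if (!is.null(cfg$prime_map)) cfg$prime_map <- unlist(cfg$prime_map)
  do.call(domain_scheme, cfg)
}

#' @export
print.domain_scheme <- function(x, ...) {
  cat("<domain_scheme>\n")
  for (nm in c("ntd_track", "ecd_twist", "tmd_twist", "tmd_align",
               "beta1", "beta10", "ntd1", "ntd2")) {
    r <- x[[nm]]
    cat(sprintf("  %-9s %s\n", nm,
                if (is.null(r)) "<unset>" else sprintf("%d-%d", r[1], r[2])))
  }
  if (!is.null(x$prime_map)) {
    cat("  prime_map",
        paste(sprintf("%s=%d", names(x$prime_map), x$prime_map),
              collapse = " "), "\n")
  }
  invisible(x)
}
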