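sch <- generator_scheme()

# hand-built single-ion model: one calcium with an octahedral O shell at a
# single distance, plus a remote protein atom
octahedral_model <- function(dist = 2.40, n_shell = 6) {
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))[seq_len(n_shell), , drop = FALSE]
  shell <- dirs * dist
  atoms <- tibble::tibble(
    chain = "A",
    res_seq = c(seq_len(n_shell) + 9L, 5L, 800L),
    res_name = c(rep("ASP", n_shell), "GLY", "CA"),
    atom_name = c(rep("OD1", n_shell), "CA", "CA"),
    element = c(rep("O", n_shell), "C", "CA"),
    x = c(shell[, 1], 30, 0), y = c(shell[, 2], 0, 0),
    z = c(shell[, 3], 0, 0),
    is_hetero = c(rep(FALSE, n_shell), FALSE, TRUE)
  )
  atoms <- atoms |> dplyr::arrange(is_hetero, res_seq)
  pent_structure(atoms)
}

test_that("coordination shells report exact constructed distances", {
  m <- octahedral_model(2.40)
  cc <- coordination_shell(m, "A:800")
  expect_equal(nrow(cc), 6)
  expect_equal(cc$distance, rep(2.40, 6), tolerance = 1e-12)
  expect_true(all(cc$partner_class == "sidechain_O"))

  # ion with nothing nearby
  far <- coordination_shell(m, "A:800", cutoff = 1.0)
  expect_equal(nrow(far), 0)
  expect_error(coordination_shell(m, "B:999"), "unknown ion")
  expect_error(coordination_shell(m, "A:800", cutoff = -1), "cutoff")
})

test_that("contact ordering is deterministic under exact distance ties", {
  m <- octahedral_model(2.40)
  cc <- coordination_shell(m, "A:800")
  # all six distances tie; order must follow (chain, res_seq, atom_name)
  expect_equal(cc$res_seq, sort(cc$res_seq))
  cc2 <- coordination_shell(m, "A:800")
  expect_identical(cc, cc2)
})

test_that("enlarging the cutoff never removes a contact", {
  m <- build_pentamer(pentamer_spec())
  key <- function(cc) paste(cc$chain, cc$res_seq, cc$atom_name)
  for (cut in c(2.5, 2.8, 3.1, 3.5, 4.5)) {
    cc_small <- coordination_shell(m, "A:701", cutoff = cut)
    cc_big <- coordination_shell(m, "A:701", cutoff = cut + 0.5)
    expect_true(all(key(cc_small) %in% key(cc_big)))
  }
})

test_that("generated site shells match their published-style bounds", {
  m <- build_pentamer(pentamer_spec())
  defs <- default_site_definitions()
  # Site 1: acidic side chains + backbone carbonyls, all within 2.6 A
  cc1 <- coordination_shell(m, "A:701")
  expect_lte(max_coordination_distance(cc1, defs$Site1$partners), 2.6 + 1e-9)
  expect_true(all(c(76, 123, 124) %in%
                    cc1$res_seq[cc1$partner_class == "sidechain_O"]))
  expect_true(all(c(77, 123, 129) %in%
                    cc1$res_seq[cc1$partner_class == "backbone_carbonyl_O"]))
  # Site 2: backbone carbonyls at 2.6-3.1 A
  cc2 <- coordination_shell(m, "A:702")
  d2 <- max_coordination_distance(cc2, defs$Site2$partners)
  expect_gte(d2, 2.6 - 1e-9); expect_lte(d2, 3.1 + 1e-9)
  # Site 3 within 2.7, Site 4 within 2.5-3.0
  cc3 <- coordination_shell(m, "A:703")
  expect_lte(max_coordination_distance(cc3, defs$Site3$partners), 2.7 + 1e-9)
  cc4 <- coordination_shell(m, "A:704")
  d4 <- max_coordination_distance(cc4, defs$Site4$partners)
  expect_gte(d4, 2.5 - 1e-9); expect_lte(d4, 3.0 + 1e-9)
})

test_that("max coordination distance handles subsets and missing partners", {
  cc <- tibble::tibble(ion_id = "x", chain = "A", res_seq = c(1L, 2L, 3L),
                       res_name = "ASP", atom_name = "OD1", element = "O",
                       distance = c(2.1, 2.4, 2.6),
                       partner_class = "sidechain_O")
  expect_equal(max_coordination_distance(cc, c(1, 2, 3)), 2.6)
  expect_equal(max_coordination_distance(cc, c(1, 2)), 2.4)
  expect_error(max_coordination_distance(cc, c(1, 9)), "absent")
})

test_that("site classification assigns, rejects and flags ties", {
  m <- build_pentamer(pentamer_spec())
  ids <- ion_table(m)$ion_id
  cc <- purrr::map_dfr(ids, ~coordination_shell(m, .x))
  out <- classify_sites(cc)
  expect_equal(nrow(out), 20)
  got <- out$site[match(paste0(LETTERS[1:5], ":703"), out$ion_id)]
  expect_equal(got, rep("Site3", 5))
  expect_true(all(out$matched_fraction == 1))
  expect_false(any(out$tie))

  # empty contacts -> unassigned
  none <- tibble::tibble(ion_id = "q:1", chain = "A", res_seq = 999L,
                         res_name = "GLY", atom_name = "O", element = "O",
                         distance = 2.5, partner_class = "other")
  expect_equal(classify_sites(none)$site, "unassigned")

  # 2 of 3 Site-2 partners at threshold 0.6: 2/3 = 0.667 passes
  partial <- tibble::tibble(
    ion_id = "p:1", chain = "A", res_seq = c(124L, 126L),
    res_name = c("ASP", "GLY"), atom_name = "O", element = "O",
    distance = c(2.6, 2.8), partner_class = "backbone_carbonyl_O")
  defs <- default_site_definitions()
  defs$Site2$threshold <- 0.6
  out2 <- classify_sites(partial, defs)
  expect_equal(out2$site, "Site2")
  expect_equal(out2$matched_fraction, 2 / 3, tolerance = 1e-12)

  # duplicated definition -> tie flagged
  defs$SiteX <- defs$Site2
  defs$SiteX$label <- "SiteX"
  out3 <- classify_sites(partial, defs)
  expect_true(all(out3$tie))
  expect_setequal(out3$site, c("Site2", "SiteX"))
})

test_that("residence tracks scripted unbinding with exact fractions", {
  # static control: permanently bound
  tr0 <- align_trajectory(build_trajectory(pentamer_spec(seed = 2), 10),
                          scheme = sch)
  rs0 <- ion_residence(tr0, "A:701")
  expect_equal(mean(rs0$bound), 1)
  expect_equal(rs0$displacement[1], 0)

  # scripted escape at frame 7 of 10: bound frames 1-6
  script <- motion_event(7, "B", "ion:site1", translate = c(9, 0, 0))
  tr <- align_trajectory(build_trajectory(pentamer_spec(seed = 3), 10, script),
                         scheme = sch)
  rs <- ion_residence(tr, "B:701")
  expect_equal(mean(rs$bound), 6 / 10)
  summ <- residence_summary(rs)
  expect_false(summ$bound_at_end)
  expect_equal(summ$max_displacement, 9, tolerance = 1e-9)

  # across all chains: four of five remain bound at the end
  all_rs <- purrr::map_dfr(paste0(LETTERS[1:5], ":701"),
                           ~ion_residence(tr, .x))
  summ_all <- residence_summary(all_rs)
  expect_equal(sum(summ_all$bound_at_end), 4)
})

test_that("residence is measured in the aligned frame, not raw coordinates", {
  tr <- build_trajectory(pentamer_spec(seed = 6), 6, global_sway = TRUE)
  al <- align_trajectory(tr, scheme = sch)
  rs_aligned <- ion_residence(al, "C:703")
  expect_equal(mean(rs_aligned$bound), 1)  # drift removed, ion never "leaves"
  rs_raw <- ion_residence(tr, "C:703")
  expect_gt(max(rs_raw$displacement), max(rs_aligned$displacement))
})

test_that("bound fraction is non-increasing as the threshold tightens", {
  script <- dplyr::bind_rows(
    motion_event(3, "A", "ion:site1", translate = c(2, 0, 0)),
    motion_event(6, "A", "ion:site1", translate = c(2.5, 0, 0)),
    motion_event(9, "A", "ion:site1", translate = c(3, 0, 0))
  )
  tr <- align_trajectory(build_trajectory(pentamer_spec(seed = 4), 12, script),
                         scheme = sch)
  fracs <- vapply(c(8, 6, 5, 3, 2, 1), function(th) {
    mean(ion_residence(tr, "A:701", threshold = th)$bound)
  }, numeric(1))
  expect_true(all(diff(fracs) <= 1e-12))
})

test_that("site definitions round-trip through YAML", {
  defs <- default_site_definitions()
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(lapply(defs, function(d) {
    list(threshold = d$threshold,
         partners = purrr::pmap(d$partners, function(res_seq, partner_class) {
           list(res_seq = res_seq, partner_class = partner_class)
         }))
  }), f)
  defs2 <- read_site_definitions(f)
  expect_setequal(names(defs2), names(defs))
  expect_equal(defs2$Site1$partners$res_seq, defs$Site1$partners$res_seq)
  expect_equal(defs2$Site3$threshold, 0.5)
})
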