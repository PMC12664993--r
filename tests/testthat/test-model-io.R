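test_that("a minimal hand-written PDB parses to the expected atoms", {
  f <- write_fixture(mini_pdb_text(), ".pdb")
  m <- read_structure(f)
  expect_s3_class(m, "pent_structure")
  expect_equal(nrow(m$atoms), 3)
  expect_equal(m$atoms$chain, c("A", "A", "A"))
  expect_equal(m$atoms$res_seq, c(35L, 36L, 701L))
  expect_equal(m$atoms$x, c(1, 2.5, 0))
  expect_equal(m$atoms$is_hetero, c(FALSE, FALSE, TRUE))
  expect_equal(m$atoms$element, c("C", "C", "CA"))
})

test_that("the same content read as PDB and as mmCIF gives one model", {
  mp <- read_structure(write_fixture(mini_pdb_text(), ".pdb"))
  mc <- read_structure(write_fixture(mini_cif_text(), ".cif"))
  for (col in c("chain", "res_seq", "res_name", "atom_name", "element",
                "x", "y", "z", "is_hetero")) {
    expect_equal(mp$atoms[[col]], mc$atoms[[col]], info = col)
  }
})

test_that("unreadable or protein-free files raise informative errors", {
  f <- write_fixture("this is not a structure file", ".pdb")
  expect_error(read_structure(f))
  expect_error(read_structure(tempfile(fileext = ".pdb")), "no such file")
  het_only <- "HETATM    1 CA    CA A 701       0.000   0.000   0.000  1.00  0.00          CA"
  expect_error(read_structure(write_fixture(het_only, ".pdb")),
               "no protein")
})

test_that("write -> read round-trips a generated model at format precision", {
  m <- build_pentamer(pentamer_spec())
  f <- tempfile(fileext = ".pdb")
  write_structure(m, f)
  m2 <- read_structure(f)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_equal(m2$atoms$atom_name, m$atoms$atom_name)
  expect_equal(m2$atoms$res_seq, m$atoms$res_seq)
  expect_equal(max(abs(pentagate:::model_coords(m2) -
                         pentagate:::model_coords(m))), 0,
               tolerance = 1e-3)
  # metric drift stays at format precision
  tw <- ecd_twist(m2, generator_scheme())
  expect_equal(tw$value, rep(-26, 5), tolerance = 1e-2)
})

test_that("selection resolves ranges with coverage reporting", {
  m <- build_pentamer(pentamer_spec())
  idx <- select_atoms(m, chain = "A", range = c(340, 345))
  expect_length(idx, 6)
  expect_equal(attr(idx, "coverage"), 1)
  expect_false(attr(idx, "flagged"))

  # a model missing a disordered loop: empty selection, not an error
  a <- m$atoms
  gone <- a$chain == "A" & !a$is_hetero & a$res_seq %in% 291:296
  m_gap <- pent_structure(a[!gone, ], assembly_chains = m$assembly_chains)
  expect_warning(
    idx0 <- select_atoms(m_gap, chain = "A", range = c(291, 296)),
    "coverage"
  )
  expect_length(idx0, 0)
  expect_equal(attr(idx0, "coverage"), 0)
  expect_true(attr(idx0, "flagged"))
  # partial gap: coverage is the matched fraction
  expect_warning(
    idx_part <- select_atoms(m_gap, chain = "A", range = c(289, 296)),
    "coverage"
  )
  expect_equal(attr(idx_part, "coverage"), 2 / 8)

  expect_error(select_atoms(m, chain = "Z", range = c(1, 10)), "no such chain")
})

test_that("atom filters exclude ions and hydrogens as appropriate", {
  atoms <- tibble::tibble(
    chain = "A", res_seq = c(10L, 10L, 10L, 900L),
    res_name = c("SER", "SER", "SER", "CA"),
    atom_name = c("CA", "HB1", "OG", "CA"),
    element = c("C", "H", "O", "CA"),
    x = 1:4 + 0, y = 0, z = 0,
    is_hetero = c(FALSE, FALSE, FALSE, TRUE)
  )
  m <- pent_structure(atoms)
  ca <- select_atoms(m, chain = "A", range = c(10, 10), atom_filter = "ca_only")
  expect_length(ca, 1)  # the calcium ion is hetero, never a C-alpha match
  heavy <- select_atoms(m, chain = "A", range = c(10, 10), atom_filter = "heavy")
  expect_equal(m$atoms$atom_name[heavy], c("CA", "OG"))
})

test_that("selections are invariant to atom record order within a chain", {
  m <- build_pentamer(pentamer_spec())
  key <- function(model, idx) {
    sort(paste(model$atoms$chain[idx], model$atoms$res_seq[idx],
               model$atoms$atom_name[idx]))
  }
  ref_key <- key(m, select_atoms(m, chain = "B", range = c(328, 513)))
  # reorder atoms within each residue (O shells before CA) and rebuild
  shuffled <- m$atoms |>
    dplyr::arrange(match(chain, m$assembly_chains), is_hetero, res_seq,
                   dplyr::desc(atom_name))
  m2 <- pent_structure(shuffled, assembly_chains = m$assembly_chains)
  expect_equal(key(m2, select_atoms(m2, chain = "B", range = c(328, 513))),
               ref_key)
})

test_that("trajectory construction enforces its contracts", {
  m <- read_structure(write_fixture(mini_pdb_text(), ".pdb"))
  xyz <- pentagate:::model_coords(m)

  tr <- pent_trajectory(m, xyz)
  expect_equal(n_frames(tr), 1)
  expect_equal(tr$coords[, , 1], xyz, ignore_attr = TRUE)

  arr <- array(rep(xyz, 3), c(3, 3, 3))
  expect_error(pent_trajectory(m, arr, times = c(0, 2, 1)),
               "strictly increasing")
  expect_error(pent_trajectory(m, array(0, c(5, 3, 2))), "mismatch")
})

test_that("a generated trajectory round-trips through multi-model PDB", {
  tr <- build_trajectory(pentamer_spec(seed = 4), 10)
  top <- tempfile(fileext = ".pdb")
  crd <- tempfile(fileext = ".pdb")
  write_structure(tr$topology, top)
  write_trajectory(tr, crd)
  tr2 <- read_trajectory(top, crd, times = tr$times)
  expect_equal(n_frames(tr2), 10)
  expect_equal(max(abs(tr2$coords - tr$coords)), 0, tolerance = 1e-3)
  expect_error(read_trajectory(write_fixture(mini_pdb_text(), ".pdb"), crd),
               "mismatch")
})

test_that("domain scheme validates ranges and loads from YAML", {
  sch <- domain_scheme()
  expect_equal(sch$tmd_align, c(328L, 639L))
  expect_equal(sch$beta1, c(340L, 345L))
  expect_error(domain_scheme(beta1 = c(340, 512), beta10 = c(511, 515)),
               "disjoint")
  expect_error(domain_scheme(prime_map = c("2'" = 100)), "outside TMD")

  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(ntd1 = c(35, 195), ntd2 = c(196, 325),
                        prime_map = list(`2'` = 521L)), f)
  sch2 <- read_domain_scheme(f)
  expect_equal(sch2$ntd1, c(35L, 195L))
  expect_equal(unname(sch2$prime_map["2'"]), 521L)
  expect_equal(sch2$ecd_twist, c(328L, 513L))  # default preserved
})
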