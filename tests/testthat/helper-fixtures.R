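# Shared fixtures: everything is generated in code, nothing is read from disk
# except files the tests themselves write to tempdir().

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# minimal hand-written 3-atom PDB (two glycine CA + one calcium ion)
mini_pdb_text <- function() {
  paste(
    "ATOM      1  CA  GLY A  35       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A  36       2.500   2.000   3.000  1.00  0.00           C",
    "HETATM    3 CA    CA A 701       0.000   0.000   0.000  1.00  0.00          CA",
    "END",
    sep = "\n"
  )
}

# identical content as mmCIF
mini_cif_text <- function() {
  paste(
    "data_mini",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . GLY A 1 1 ? 1.000 2.000 3.000 1.00 0.00 ? 35 GLY A CA 1",
    "ATOM 2 C CA . GLY A 1 2 ? 2.500 2.000 3.000 1.00 0.00 ? 36 GLY A CA 1",
    "HETATM 3 CA CA . CA B 2 . ? 0.000 0.000 0.000 1.00 0.00 ? 701 CA A CA 1",
    sep = "\n"
  )
}

write_fixture <- function(text, ext) {
  f <- tempfile(fileext = ext)
  writeLines(text, f)
  f
}

# random rigid motion for invariance properties
random_rigid <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, -180, 180)
  R <- pentagate:::rotation_about_axis(ax, ang)
  list(R = R, t = runif(3, -30, 30))
}

move_rigid <- function(xyz, rig) {
  sweep(xyz %*% t(rig$R), 2, rig$t, "+")
}

# apply a rigid motion to every atom of a pent_structure
move_model <- function(model, rig) {
  set_coords(model, move_rigid(pentagate:::model_coords(model), rig))
}

# hand-built pentamer-shaped micro model: 5 chains, a couple of residues
# each, fully controlled coordinates (for oracle tests independent of the
# generator)
micro_pentamer <- function(coords_fun) {
  rows <- list()
  for (k in 0:4) {
    ch <- LETTERS[k + 1]
    df <- coords_fun(ch, k)
    rows[[length(rows) + 1L]] <- df
  }
  atoms <- dplyr::bind_rows(rows)
  atoms$element <- atoms$element %||% "C"
  pent_structure(atoms, assembly_chains = LETTERS[1:5])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
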