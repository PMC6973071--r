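# Coordinate I/O and nomenclature normalization.

test_that("PDB write/read round trip preserves structure to file precision", {
  ens <- perturb_ensemble(build_quadruplex(g4_preset("vloop-ODN1415")),
                          2, 0.1, seed = 11)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ens, path)
  back <- read_structure(path)
  expect_identical(n_models(back), 2L)
  expect_identical(residue_table(back)$seq_index,
                   residue_table(ens)$seq_index)
  expect_lt(max(abs(ens$atoms$x - back$atoms$x),
                abs(ens$atoms$y - back$atoms$y),
                abs(ens$atoms$z - back$atoms$z)), 1e-3 + 1e-9)
  # variants survive the round trip via residue names
  rt <- residue_table(back)
  expect_identical(rt$variant[rt$seq_index == 14], "2F-ribo")
  expect_identical(rt$variant[rt$seq_index == 2], "deoxy")
})

test_that("models with mismatched residue lists raise a consistency error", {
  ens <- perturb_ensemble(build_quadruplex(g4_preset("parallel")), 2, 0.01,
                          seed = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ens, path)
  lines <- readLines(path)
  # drop all atoms of the last residue from model 2 only
  m2 <- which(cumsum(grepl("^MODEL", lines)) == 2 & grepl("^ATOM", lines))
  drop <- m2[grepl(" 15 ", substr(lines[m2], 18, 30))]
  writeLines(lines[-drop], path)
  expect_error(read_structure(path), "mismatched residue lists")
})

test_that("nomenclature normalization resolves aliases and warns on unknowns", {
  ens <- build_quadruplex(g4_preset("parallel"))
  a <- ens$atoms
  a$res_name[a$seq_index == 1] <- "GF2"
  a$res_name[a$seq_index == 4] <- "XYZ"
  a$atom[a$atom == "O4'"] <- "O1'"
  ens2 <- structure_ensemble(a, "aliased")
  expect_warning(norm <- normalize_nomenclature(ens2), "XYZ")
  rt <- residue_table(norm)
  expect_identical(rt$base_type[rt$seq_index == 1], "G")
  expect_identical(rt$variant[rt$seq_index == 1], "2F-ribo")
  expect_identical(rt$base_type[rt$seq_index == 4], "other")
  expect_identical(rt$variant[rt$seq_index == 4], "unknown")
  expect_identical(rt$variant[rt$seq_index == 2], "deoxy")
  expect_false(any(norm$atoms$atom == "O1'"))
  expect_true(any(norm$atoms$atom == "O4'"))
  # model count and residue identity invariant under normalization
  expect_identical(n_models(norm), n_models(ens))
  expect_identical(rt$seq_index, residue_table(ens)$seq_index)
})

test_that("star atom names are normalized to primes on read", {
  ens <- build_quadruplex(g4_preset("parallel"))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ens, path)
  lines <- gsub(" C1' ", " C1* ", readLines(path), fixed = TRUE)
  writeLines(lines, path)
  back <- read_structure(path)
  expect_true(any(back$atoms$atom == "C1'"))
  expect_false(any(grepl("\\*", back$atoms$atom)))
})

test_that("mmCIF atom_site loops parse to the same ensemble as PDB", {
  ens <- build_quadruplex(g4_preset("parallel"))
  path <- withr::local_tempfile(fileext = ".cif")
  a <- ens$atoms
  con <- file(path, "w")
  writeLines(c("data_synthetic", "loop_",
               "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.type_symbol", "_atom_site.label_atom_id",
               "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
               "_atom_site.auth_seq_id", "_atom_site.Cartn_x",
               "_atom_site.Cartn_y", "_atom_site.Cartn_z",
               "_atom_site.occupancy", "_atom_site.pdbx_PDB_model_num"), con)
  writeLines(sprintf("ATOM %d %s %s %s %s %d %.3f %.3f %.3f 1.00 1",
                     seq_len(nrow(a)), a$element, a$atom, a$res_name,
                     a$chain, a$seq_index, a$x, a$y, a$z), con)
  close(con)
  back <- read_structure(path, format = "mmcif")
  expect_identical(n_models(back), 1L)
  expect_identical(nrow(back$atoms), nrow(a))
  expect_lt(max(abs(back$atoms$x - a$x)), 1e-3 + 1e-9)
  # auto-detection by content works too
  back2 <- read_structure(path, format = "auto")
  expect_identical(nrow(back2$atoms), nrow(a))
})

test_that("report serialization is schema-stable and deterministic", {
  ens <- perturb_ensemble(build_quadruplex(g4_preset("parallel")), 2, 0.01,
                          seed = 5)
  tab <- pucker_table(ens)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_report(tab, f1, "tsv")
  write_report(tab, f2, "tsv")
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(length(readLines(f1)) - 1L, nrow(tab))

  # empty V-loop list serializes as an empty array, not a missing key
  topo <- analyze_topology(ens, 1)
  rep <- quadfold:::.topology_report(topo)
  j1 <- withr::local_tempfile(fileext = ".json")
  write_report(rep, j1, "json")
  parsed <- jsonlite::fromJSON(readLines(j1))
  expect_true("vloops" %in% names(parsed))
  expect_identical(length(parsed$vloops), 0L)
  j2 <- withr::local_tempfile(fileext = ".json")
  write_report(rep, j2, "json")
  expect_identical(readLines(j1), readLines(j2))
})
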