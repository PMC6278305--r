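test_that("read_structure preserves atom counts and model indices", {
  f1 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(raw_pdb_lines(n_models = 1, atoms_per_model = 10), f1)
  atoms <- read_structure(f1)
  expect_equal(nrow(atoms), 10)
  expect_true(all(atoms$model == 1))

  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(raw_pdb_lines(n_models = 3, atoms_per_model = 4), f3)
  all_models <- read_structure(f3, model_policy = "all")
  expect_setequal(unique(all_models$model), 1:3)
  expect_equal(nrow(all_models), 12)
  first <- read_structure(f3, model_policy = "first")
  expect_equal(unique(first$model), 1)
  expect_equal(nrow(first), 4)
})

test_that("read_structure fails loudly on missing or empty input", {
  expect_error(read_structure(tempfile()), "not found")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER junk", "END"), f)
  expect_error(read_structure(f))
})

test_that("altloc resolution keeps highest occupancy, then lowest B-factor", {
  two <- dplyr::bind_rows(
    atom_row(altloc = "A", occupancy = 0.6, x = 1),
    atom_row(altloc = "B", occupancy = 0.4, x = 2)
  )
  kept <- clean_altlocs(two)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$altloc, "A")

  tie <- dplyr::bind_rows(
    atom_row(altloc = "A", occupancy = 0.5, b_factor = 12, x = 1),
    atom_row(altloc = "B", occupancy = 0.5, b_factor = 15, x = 2)
  )
  kept <- clean_altlocs(tie)
  expect_equal(kept$altloc, "A")
  expect_equal(kept$b_factor, 12)

  # full tie falls back to altloc character order
  full_tie <- dplyr::bind_rows(
    atom_row(altloc = "B", occupancy = 0.5, b_factor = 12, x = 2),
    atom_row(altloc = "A", occupancy = 0.5, b_factor = 12, x = 1)
  )
  expect_equal(clean_altlocs(full_tie)$altloc, "A")
})

test_that("clean_altlocs is the identity without altlocs and is idempotent", {
  plain <- dplyr::bind_rows(
    atom_row(resno = 1, atom = "CA"),
    atom_row(resno = 1, atom = "CB"),
    atom_row(resno = 2, atom = "CA")
  )
  expect_equal(clean_altlocs(plain), plain)
  mixed <- dplyr::bind_rows(
    plain,
    atom_row(resno = 3, atom = "CG", altloc = "A", occupancy = 0.7),
    atom_row(resno = 3, atom = "CG", altloc = "B", occupancy = 0.3)
  )
  once <- clean_altlocs(mixed)
  expect_equal(clean_altlocs(once), once)
  expect_equal(clean_altlocs(mixed[0, ]), mixed[0, ])
})

test_that("partial waters are removed only when requested", {
  atoms <- dplyr::bind_rows(
    atom_row(resname = "HOH", resno = 900, atom = "O", element = "O",
             occupancy = 0.5, record = "HETATM"),
    atom_row(resname = "HOH", resno = 901, atom = "O", element = "O",
             occupancy = 1.0, record = "HETATM")
  )
  expect_equal(nrow(clean_altlocs(atoms)), 2)
  kept <- clean_altlocs(atoms, remove_partial_waters = TRUE)
  expect_equal(kept$resno, 901)
})

test_that("extract_active_site picks the His sidechain N nearer to Cu", {
  atoms <- dplyr::bind_rows(
    atom_row(resname = "CU", resno = 500, atom = "CU", element = "CU",
             record = "HETATM", x = 0),
    atom_row(resname = "HIS", resno = 99, atom = "NE2", element = "N",
             x = 2.0),
    atom_row(resname = "HIS", resno = 99, atom = "ND1", element = "N",
             x = 4.1),
    atom_row(resname = "HIS", resno = 134, atom = "ND1", element = "N",
             y = 2.0),
    atom_row(resname = "HIS", resno = 134, atom = "NE2", element = "N",
             y = 4.2),
    atom_row(resname = "HIS", resno = 289, atom = "NE2", element = "N",
             z = 2.0),
    atom_row(resname = "NO2", resno = 600, atom = "N", element = "N",
             record = "HETATM", x = -2.0),
    atom_row(resname = "NO2", resno = 600, atom = "O1", element = "O",
             record = "HETATM", x = -2.8, y = 1.0),
    atom_row(resname = "NO2", resno = 600, atom = "O2", element = "O",
             record = "HETATM", x = -2.8, y = -1.0)
  )
  site <- extract_active_site(atoms, "A")
  expect_equal(unname(site$his_n$His99), c(2, 0, 0))
  expect_equal(unname(site$his_n$His134), c(0, 2, 0))
  # absent aux roles are recorded as missing, not an error
  expect_length(site$aux, 0)
})

test_that("extract_active_site names its deficits", {
  base <- dplyr::bind_rows(
    atom_row(resname = "HIS", resno = 99, atom = "NE2", element = "N",
             x = 2),
    atom_row(resname = "HIS", resno = 134, atom = "NE2", element = "N",
             y = 2),
    atom_row(resname = "HIS", resno = 289, atom = "NE2", element = "N",
             z = 2),
    atom_row(resname = "NO2", resno = 600, atom = "N", element = "N",
             x = -2),
    atom_row(resname = "NO2", resno = 600, atom = "O1", element = "O",
             x = -2.8, y = 1),
    atom_row(resname = "NO2", resno = 600, atom = "O2", element = "O",
             x = -2.8, y = -1)
  )
  expect_error(extract_active_site(base, "A"), "no Cu")
  with_cu <- dplyr::bind_rows(
    base, atom_row(resname = "CU", resno = 500, atom = "CU", element = "CU")
  )
  expect_error(extract_active_site(dplyr::filter(with_cu, resno != 134), "A"),
               "His 134")
  bad_nitrite <- dplyr::filter(with_cu, atom != "O2")
  expect_error(extract_active_site(bad_nitrite, "A"), "nitrite")
})

test_that("sidechain COM is the mass-weighted mean of sidechain heavy atoms", {
  res <- dplyr::bind_rows(
    atom_row(resname = "XXX", resno = 7, atom = "CB", element = "C",
             x = 0),
    atom_row(resname = "XXX", resno = 7, atom = "CG", element = "C",
             x = 2)
  )
  com <- sidechain_com(res, "A", 7)
  expect_equal(c(com$x, com$y, com$z), c(1, 0, 0))
  expect_equal(com$atom_count, 2)

  single <- atom_row(resname = "XXX", resno = 8, atom = "CB", element = "C",
                     x = 3, y = -1, z = 2)
  com1 <- sidechain_com(single, "A", 8)
  expect_equal(c(com1$x, com1$y, com1$z), c(3, -1, 2))

  # backbone and hydrogens are excluded; unequal masses weight the mean
  mixed <- dplyr::bind_rows(
    atom_row(resno = 9, atom = "CA", element = "C", x = 100),
    atom_row(resno = 9, atom = "HB1", element = "H", x = 50),
    atom_row(resno = 9, atom = "CB", element = "C", x = 0),
    atom_row(resno = 9, atom = "OG", element = "O", x = 1)
  )
  com2 <- sidechain_com(mixed, "A", 9)
  m_c <- 12.011; m_o <- 15.999
  expect_equal(com2$x, m_o / (m_c + m_o))
  com2h <- sidechain_com(mixed, "A", 9, include_hydrogens = TRUE)
  expect_equal(com2h$x, (m_o + 50 * 1.008) / (m_c + m_o + 1.008))

  glycine <- atom_row(resno = 10, atom = "CA", element = "C")
  expect_error(sidechain_com(glycine, "A", 10), "sidechain")
})

test_that("extraction and COM are equivariant under rigid motion", {
  set.seed(11)
  site <- random_site(scramble = FALSE)
  atoms <- cunirgeom:::site_atoms(site)
  rot <- random_rotation_test()
  tr <- rnorm(3, 0, 5)
  moved <- dplyr::mutate(
    atoms,
    new_x = rot[1, 1] * x + rot[1, 2] * y + rot[1, 3] * z + tr[1],
    new_y = rot[2, 1] * x + rot[2, 2] * y + rot[2, 3] * z + tr[2],
    new_z = rot[3, 1] * x + rot[3, 2] * y + rot[3, 3] * z + tr[3]
  ) |>
    dplyr::mutate(x = new_x, y = new_y, z = new_z) |>
    dplyr::select(-new_x, -new_y, -new_z)

  s0 <- extract_active_site(atoms, "A")
  s1 <- extract_active_site(moved, "A")
  expect_equal(names(s1$his_n), names(s0$his_n))
  expect_equal(unname(s1$cu), as.numeric(rot %*% s0$cu + tr),
               tolerance = 1e-9)

  res <- dplyr::bind_rows(
    atom_row(resno = 40, atom = "CB", element = "C", x = 1, y = 2, z = 3),
    atom_row(resno = 40, atom = "OG", element = "O", x = -1, y = 0, z = 1)
  )
  moved_res <- dplyr::mutate(
    res,
    x0 = x, y0 = y, z0 = z,
    x = rot[1, 1] * x0 + rot[1, 2] * y0 + rot[1, 3] * z0 + tr[1],
    y = rot[2, 1] * x0 + rot[2, 2] * y0 + rot[2, 3] * z0 + tr[2],
    z = rot[3, 1] * x0 + rot[3, 2] * y0 + rot[3, 3] * z0 + tr[3]
  )
  c0 <- sidechain_com(res, "A", 40)
  c1 <- sidechain_com(moved_res, "A", 40)
  expect_equal(c(c1$x, c1$y, c1$z),
               as.numeric(rot %*% c(c0$x, c0$y, c0$z) + tr),
               tolerance = 1e-9)
})

test_that("active sites round-trip through PDB files", {
  set.seed(21)
  site <- random_site()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(site, f)
  back <- extract_active_site(read_structure(f), site$chain)
  expect_equal(unname(back$cu), unname(site$cu), tolerance = 1e-3)
  expect_equal(unname(back$nitrite_n), unname(site$nitrite_n),
               tolerance = 1e-3)
  expect_equal(names(back$his_n), names(site$his_n))
})
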