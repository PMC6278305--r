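test_that("the ligand frame satisfies its defining conventions", {
  set.seed(31)
  for (i in 1:25) {
    site <- random_site()
    fr <- build_ligand_frame(site)
    axes <- cbind(fr$x_axis, fr$y_axis, fr$z_axis)
    expect_equal(t(axes) %*% axes, diag(3), tolerance = 1e-9,
                 ignore_attr = TRUE)
    to_local <- function(p) as.numeric(t(axes) %*% (p - fr$origin))
    n_loc <- to_local(site$nitrite_n)
    expect_gt(n_loc[1], 0)
    expect_lt(abs(n_loc[2]), 1e-9)
    expect_lt(abs(n_loc[3]), 1e-9)
    expect_lt(abs(to_local(site$nitrite_o1)[3]), 1e-9)
    expect_lt(abs(to_local(site$nitrite_o2)[3]), 1e-9)
    expect_gte(fr$cu_local[3], 0)
  }
})

test_that("theta and psi behave correctly at the poles", {
  th <- function(cu) compute_theta(build_ligand_frame(canonical_site(cu)))
  ps <- function(cu) compute_psi(build_ligand_frame(canonical_site(cu)))
  expect_equal(th(c(2, 0, 0)), 0)
  expect_equal(th(c(0, 0.3, 2)), 90)
  expect_equal(th(c(-2, 0.1, 0)), 180)
  expect_equal(ps(c(2, 0, 0.1)), 0)
  expect_equal(ps(c(-2, 0, 0.1)), 180)
  expect_equal(ps(c(0, 2, 0.1)), 90)
})

test_that("degenerate configurations raise informative errors", {
  expect_error(
    compute_theta(build_ligand_frame(canonical_site(c(0, 2, 0)))),
    "altitude undefined"
  )
  expect_error(
    compute_psi(build_ligand_frame(canonical_site(c(0, 0, 2)))),
    "azimuth undefined"
  )
  collinear <- active_site(
    cu = c(0, 2, 0),
    his_n = list(His99 = c(3, 0, 0), His134 = c(0, 3, 0),
                 His289 = c(0, 0, 3)),
    nitrite_n = c(0, 0, 0), nitrite_o1 = c(1, 0, 0), nitrite_o2 = c(2, 0, 0)
  )
  expect_error(build_ligand_frame(collinear), "degenerate ligand plane")
})

test_that("binding modes follow the angular thresholds, boundaries included", {
  cases <- tibble::tribble(
    ~theta, ~psi, ~alt, ~azi,
    5, 5, "N-bound", "symmetrical",
    5, 10, "N-bound", "symmetrical",  # shared boundary -> symmetrical
    5, 10.1, "N-bound", "l-shaped",
    5, 30, "N-bound", "l-shaped",
    5, 31, "N-bound", "unclassified",
    20, 5, "N-bound", "symmetrical",  # theta boundary closed
    20.5, 5, "borderline", "n/a",
    175, 175, "top-hat", "bidentate",
    175, 170, "top-hat", "bidentate", # shared boundary -> bidentate
    175, 169.9, "top-hat", "monodentate",
    175, 140, "top-hat", "monodentate",
    175, 139.9, "top-hat", "unclassified",
    160, 160, "top-hat", "monodentate",
    159.9, 160, "borderline", "n/a",
    88, 88, "side-on", "n/a",
    70, 75, "side-on", "n/a",
    110, 100, "side-on", "n/a",
    153.2, 160, "borderline", "n/a",
    145.0, 160, "borderline", "n/a",
    45, 45, "borderline", "n/a"
  )
  res <- classify_mode(cases$theta, cases$psi)
  expect_equal(res$altitudinal_class, cases$alt)
  expect_equal(res$azimuthal_class, cases$azi)
  expect_error(classify_mode(190, 5), "0, 180")
})

test_that("coplanar and trigonal limits give the expected twist angle", {
  # near-square-planar: all four ligating atoms coplanar with Cu (exact
  # trans pairs would make the defining planes collinear, hence the slight
  # in-plane offsets)
  sq <- active_site(
    cu = c(0, 0, 0),
    his_n = list(His99 = c(0.3, 2, 0), His134 = c(0, -2, 0),
                 His289 = c(-2, 0.4, 0)),
    nitrite_n = c(2, 0, 0), nitrite_o1 = c(3, 0.9, 0.4),
    nitrite_o2 = c(3, -0.9, -0.4)
  )
  geom <- compute_phi(sq)
  expect_equal(geom$axial_his, "His289")  # near-180-degree angle is largest
  expect_true(min(geom$phi, 180 - geom$phi) < 1e-6)
  expect_equal(geom$shape_label, "tetragonal")

  # C3v: three His trigonally arranged below Cu, nitrite N apical
  ang <- 2 * pi / 3
  c3v <- active_site(
    cu = c(0, 0, 0),
    his_n = list(His99 = c(2 * cos(0), 2 * sin(0), -1),
                 His134 = c(2 * cos(ang), 2 * sin(ang), -1),
                 His289 = c(2 * cos(2 * ang), 2 * sin(2 * ang), -1)),
    nitrite_n = c(0, 0, 2), nitrite_o1 = c(0.9, 0.5, 3),
    nitrite_o2 = c(-0.9, 0.5, 3)
  )
  expect_warning(geom3 <- compute_phi(c3v), "ambiguous axial")
  expect_equal(geom3$phi, 90, tolerance = 1e-6)
  expect_equal(geom3$shape_label, "trigonal")
  expect_equal(geom3$axial_his, "His99")  # tie broken by residue number
})

test_that("compute_phi reports six angles, Cu-O distances and asymmetry", {
  set.seed(41)
  site <- random_site()
  geom <- compute_phi(site)
  expect_equal(nrow(geom$angles), 6)
  expect_true(all(geom$angles$angle >= 0 & geom$angles$angle <= 180))
  expect_equal(geom$cu_o_distances,
               c(vnorm_test(site$cu - site$nitrite_o1),
                 vnorm_test(site$cu - site$nitrite_o2)))
  expect_equal(geom$o_asymmetric,
               abs(diff(geom$cu_o_distances)) > 0.3)

  # asymmetry rule at the cutoff
  near <- active_site(
    cu = c(0, 0, 0),
    his_n = list(His99 = c(0.3, 2, 0.1), His134 = c(0, -2, 0.2),
                 His289 = c(-2, 0.4, 0)),
    nitrite_n = c(2, 0, 0), nitrite_o1 = c(2.6, 1.0, 0),
    nitrite_o2 = c(2.6, -1.0, 0.8)
  )
  g <- compute_phi(near)
  expect_equal(g$o_asymmetric, abs(diff(g$cu_o_distances)) > 0.3)
})

test_that("frame, theta, psi and phi match the brute-force oracles", {
  set.seed(51)
  for (i in 1:200) {
    site <- random_site()
    fr <- build_ligand_frame(site)
    expect_equal(fr$cu_local, oracle_cu_local(site), tolerance = 1e-9)
    expect_equal(compute_theta(fr), oracle_theta(site), tolerance = 1e-6)
    expect_equal(compute_psi(fr), oracle_psi(site), tolerance = 1e-6)
    expect_equal(compute_phi(site)$phi, oracle_phi(site), tolerance = 1e-6)
  }
})

test_that("angles are invariant under rigid motion and O relabelling", {
  set.seed(61)
  site <- random_site(scramble = FALSE)
  ref <- analyze_site(site)
  for (i in 1:20) {
    moved <- transform_site(site, random_rotation_test(), rnorm(3, 0, 20))
    got <- analyze_site(moved)
    expect_equal(got$theta, ref$theta, tolerance = 1e-6)
    expect_equal(got$psi, ref$psi, tolerance = 1e-6)
    expect_equal(got$phi, ref$phi, tolerance = 1e-6)
    expect_equal(got$mode_label, ref$mode_label)
    expect_equal(got$shape_label, ref$shape_label)
  }
  swapped <- active_site(
    cu = site$cu, his_n = site$his_n, nitrite_n = site$nitrite_n,
    nitrite_o1 = site$nitrite_o2, nitrite_o2 = site$nitrite_o1,
    chain = site$chain, frame = site$frame
  )
  got <- analyze_site(swapped)
  expect_equal(got$theta, ref$theta, tolerance = 1e-9)
  expect_equal(got$psi, ref$psi, tolerance = 1e-9)
  expect_equal(got$phi, ref$phi, tolerance = 1e-9)
  expect_equal(got$o_asymmetric, ref$o_asymmetric)
})

test_that("analyze_structure produces one row per chain and model", {
  sites <- list(
    make_site(site_spec(theta = 175, psi = 174), chain = "A", frame = 1),
    make_site(site_spec(theta = 5, psi = 15), chain = "A", frame = 2)
  )
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sites, f)
  res <- analyze_structure(read_structure(f))
  expect_equal(nrow(res), 2)
  expect_equal(res$mode_label,
               c("bidentate top-hat", "l-shaped N-bound"))
})

test_that("tidy and glance methods expose the coordination report", {
  site <- make_site(site_spec(theta = 5, psi = 5, phi = 85))
  geom <- compute_phi(site)
  expect_s3_class(tidy(geom), "tbl_df")
  expect_equal(nrow(tidy(geom)), 6)
  g <- glance(geom)
  expect_equal(g$phi, geom$phi)
  expect_equal(g$shape_label, "trigonal")
  fr <- build_ligand_frame(site)
  expect_equal(nrow(tidy(fr)), 5)
})
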