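#' Build the nitrite-local coordinate frame
#'
#' Constructs the orthonormal frame anchored on the nitrite ion: the origin is
#' the mass-weighted centre of mass of the three nitrite atoms, the X axis
#' points from the origin towards the nitrogen atom, the Z axis is the unit
#' normal of the nitrite plane signed so the copper has a non-negative Z
#' component (with ties on |Z| < 1e-9 broken so the Y component is
#' non-negative), and Y completes the right-handed system. The copper position
#' expressed in this frame (`cu_local`) carries all the information needed for
#' the altitudinal and azimuthal binding angles.
#'
#' @param site An `active_site`.
#' @return A `ligand_frame` object: `origin`, `x_axis`, `y_axis`, `z_axis`,
#'   `cu_local`.
#' @export
build_ligand_frame <- function(site) {
  coords <- rbind(site$nitrite_n, site$nitrite_o1, site$nitrite_o2)
  origin <- mass_com(coords, c("N", "O", "O"))

  xv <- site$nitrite_n - origin
  if (vnorm(xv) < 1e-9) abort("degenerate ligand plane: N at the nitrite COM")
  x_axis <- unit(xv)
  normal <- cross3(site$nitrite_o1 - site$nitrite_n,
                   site$nitrite_o2 - site$nitrite_n)
  if (vnorm(normal) < 1e-9) {
    abort("degenerate ligand plane: nitrite atoms are collinear")
  }
  z_axis <- unit(normal)

  rel <- site$cu - origin
  cz <- sum(rel * z_axis)
  if (abs(cz) < 1e-9) {
    # Cu exactly in the nitrite plane: pick the Z sign that makes Y >= 0
    y_try <- cross3(z_axis, x_axis)
    if (sum(rel * y_try) < 0) z_axis <- -z_axis
  } else if (cz < 0) {
    z_axis <- -z_axis
  }
  y_axis <- cross3(z_axis, x_axis)
  cu_local <- c(sum(rel * x_axis), sum(rel * y_axis), sum(rel * z_axis))

  structure(
    list(origin = origin, x_axis = x_axis, y_axis = y_axis, z_axis = z_axis,
         cu_local = cu_local),
    class = "ligand_frame"
  )
}

#' @export
print.ligand_frame <- function(x, ...) {
  cat("<ligand_frame> Cu at [",
      paste(sprintf("%.4f", x$cu_local), collapse = ", "), "] (local)\n")
  invisible(x)
}

#' Altitudinal binding angle theta
#'
#' The angle between the projection of the copper position onto the local XZ
#' plane and the X axis, mapped to \[0, 180\] degrees. Theta describes the
#' "pitch" of the nitrite ion: 0 for N-bound, 90 for side-on, 180 for
#' top-hat.
#'
#' @param frame A `ligand_frame`.
#' @return Theta in degrees.
#' @export
compute_theta <- function(frame) {
  p <- frame$cu_local
  if (sqrt(p[1]^2 + p[3]^2) < 1e-9) {
    abort("altitude undefined: Cu lies on the local Y axis")
  }
  deg(atan2(abs(p[3]), p[1]))
}

#' Azimuthal binding angle psi
#'
#' The angle between the projection of the copper position onto the local XY
#' plane and the X axis, mapped to \[0, 180\] degrees. Because the two nitrite
#' oxygens are interchangeable the sign of the Y component is non-physical and
#' the absolute value is used. Psi describes the "yaw": 0 symmetrical
#' N-bound, ~10-30 l-shaped, ~140-170 monodentate, 180 bidentate top-hat.
#'
#' @param frame A `ligand_frame`.
#' @return Psi in degrees.
#' @export
compute_psi <- function(frame) {
  p <- frame$cu_local
  if (sqrt(p[1]^2 + p[2]^2) < 1e-9) {
    abort("azimuth undefined: Cu lies on the local Z axis")
  }
  deg(atan2(abs(p[2]), p[1]))
}

#' Angular thresholds for binding-mode classification
#'
#' Default altitudinal and azimuthal class boundaries (degrees). Boundary
#' values belong to the class whose printed range includes them; the shared
#' boundaries psi = 10 (symmetrical vs l-shaped) and psi = 170 (monodentate vs
#' bidentate) go to the symmetrical and bidentate classes respectively.
#'
#' @return A list of named numeric ranges.
#' @export
mode_thresholds <- function() {
  list(
    n_bound = c(0, 20), top_hat = c(160, 180), side_on = c(70, 110),
    symmetrical = c(0, 10), l_shaped = c(10, 30),
    bidentate = c(170, 180), monodentate = c(140, 170)
  )
}

#' Classify a nitrite binding mode from (theta, psi)
#'
#' Assigns the altitudinal class (N-bound, top-hat, side-on, or borderline
#' when theta falls outside every range) and, where applicable, the azimuthal
#' subclass (symmetrical/l-shaped for N-bound; bidentate/monodentate for
#' top-hat; n/a for side-on; unclassified when psi falls outside the ranges).
#' Vectorised over `theta` and `psi`.
#'
#' @param theta,psi Angles in degrees, each in \[0, 180\].
#' @param thresholds Class boundaries, see [mode_thresholds()].
#' @return A tibble: `theta`, `psi`, `altitudinal_class`, `azimuthal_class`,
#'   `mode_label`.
#' @examples
#' classify_mode(c(175.8, 5.8, 88), c(174.2, 1.0, 88))
#' @export
classify_mode <- function(theta, psi, thresholds = mode_thresholds()) {
  stopifnot(length(theta) == length(psi))
  if (any(theta < 0 | theta > 180 | psi < 0 | psi > 180)) {
    abort("theta and psi must lie in [0, 180] degrees")
  }
  th <- thresholds
  alt <- dplyr::case_when(
    theta >= th$n_bound[1] & theta <= th$n_bound[2] ~ "N-bound",
    theta >= th$top_hat[1] & theta <= th$top_hat[2] ~ "top-hat",
    theta >= th$side_on[1] & theta <= th$side_on[2] ~ "side-on",
    TRUE ~ "borderline"
  )
  azi <- dplyr::case_when(
    alt == "borderline" ~ "n/a",
    alt == "side-on" ~ "n/a",
    alt == "N-bound" & psi >= th$symmetrical[1] & psi <= th$symmetrical[2] ~
      "symmetrical",
    alt == "N-bound" & psi > th$l_shaped[1] & psi <= th$l_shaped[2] ~
      "l-shaped",
    alt == "top-hat" & psi >= th$bidentate[1] & psi <= th$bidentate[2] ~
      "bidentate",
    alt == "top-hat" & psi >= th$monodentate[1] & psi < th$monodentate[2] ~
      "monodentate",
    TRUE ~ "unclassified"
  )
  label <- dplyr::case_when(
    alt == "borderline" ~ "borderline",
    alt == "side-on" ~ "side-on",
    azi == "unclassified" ~ paste("unclassified", alt),
    TRUE ~ paste(azi, alt)
  )
  tibble::tibble(
    theta = theta, psi = psi,
    altitudinal_class = alt, azimuthal_class = azi, mode_label = label
  )
}

#' Coordination twist angle phi and copper-centred geometry
#'
#' Identifies the axial histidine (the one with the largest
#' N(nitrite)-Cu-N(His) angle), computes the twist angle phi between the
#' plane through N(nitrite)-Cu-N(His_axial) and the plane through the two
#' equatorial histidine nitrogens and Cu, reports all six Cu-centred pairwise
#' angles among the four nitrogen ligands, the two Cu-O distances and their
#' asymmetry, and labels the coordination shape: phi near 0/180 tetragonal,
#' near 90 trigonal.
#'
#' @param site An `active_site`.
#' @param tetragonal_band,trigonal_band Phi intervals (degrees) labelled
#'   tetragonal (applied symmetrically also as \[180 - band\]) and trigonal.
#' @param asymmetry_cutoff Cu-O distance difference (Angstrom) above which
#'   the oxygens are flagged asymmetric.
#' @return A `coordination_geometry` object: `phi`, `axial_his`, `angles`
#'   (tibble of the six pairwise angles), `shape_label`, `cu_o_distances`,
#'   `o_asymmetric`.
#' @export
compute_phi <- function(site, tetragonal_band = c(0, 30),
                        trigonal_band = c(60, 120),
                        asymmetry_cutoff = 0.3) {
  cu <- site$cu
  nn <- site$nitrite_n
  his <- site$his_n
  for (p in c(list(nn), his)) {
    if (vnorm(p - cu) < 1e-9) abort("ligand atom coincident with Cu")
  }

  his_angles <- vapply(his, function(h) vertex_angle(nn, cu, h), 1.0)
  his_num <- suppressWarnings(as.numeric(gsub("[^0-9]", "", names(his))))
  his_num[is.na(his_num)] <- seq_along(his)[is.na(his_num)]
  ord <- order(his_angles, decreasing = TRUE)
  if (abs(his_angles[ord[1]] - his_angles[ord[2]]) < 1e-6) {
    warn("ambiguous axial histidine: equal largest angles; choosing lower residue number")
    tied <- ord[1:2]
    tied <- tied[order(his_num[tied])]
    ord[1:2] <- tied
  }
  axial <- names(his)[ord[1]]
  eq <- names(his)[ord[2:3]][order(his_num[ord[2:3]])]  # residue-number order

  n1 <- cross3(nn - cu, his[[axial]] - cu)
  n2 <- cross3(his[[eq[1]]] - cu, his[[eq[2]]] - cu)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) {
    abort("degenerate coordination plane")
  }
  phi <- deg(atan2(vnorm(cross3(n1, n2)), sum(n1 * n2)))

  ligs <- c(list(`N(NO2)` = nn), his)
  pairs <- utils::combn(names(ligs), 2)
  angles <- tibble::tibble(
    atom_a = pairs[1, ], atom_b = pairs[2, ],
    angle = apply(pairs, 2, function(p) {
      vertex_angle(ligs[[p[1]]], cu, ligs[[p[2]]])
    })
  )

  in_band <- function(x, band) x >= band[1] & x <= band[2]
  shape <- if (in_band(phi, tetragonal_band) ||
               in_band(phi, 180 - rev(tetragonal_band))) {
    "tetragonal"
  } else if (in_band(phi, trigonal_band)) {
    "trigonal"
  } else {
    "intermediate"
  }

  d_o <- c(vnorm(cu - site$nitrite_o1), vnorm(cu - site$nitrite_o2))
  structure(
    list(
      phi = phi, axial_his = axial, angles = angles, shape_label = shape,
      cu_o_distances = d_o,
      o_asymmetric = abs(d_o[1] - d_o[2]) > asymmetry_cutoff
    ),
    class = "coordination_geometry"
  )
}

#' @export
print.coordination_geometry <- function(x, ...) {
  cat(sprintf("<coordination_geometry> phi = %.1f deg (%s), axial %s\n",
              x$phi, x$shape_label, x$axial_his))
  cat(sprintf("  Cu-O: %.2f / %.2f A%s\n", x$cu_o_distances[1],
              x$cu_o_distances[2],
              if (x$o_asymmetric) " (asymmetric)" else ""))
  invisible(x)
}

#' Full geometric analysis of one active site
#'
#' Composes the ligand frame, the (theta, psi) binding-mode classification
#' and the coordination twist report into a single tidy row.
#'
#' @param site An `active_site`.
#' @param thresholds Binding-mode thresholds, see [mode_thresholds()].
#' @param ... Passed to [compute_phi()].
#' @return One-row tibble: `chain`, `frame`, `theta`, `psi`,
#'   `altitudinal_class`, `azimuthal_class`, `mode_label`, `phi`,
#'   `axial_his`, `shape_label`, `cu_o1`, `cu_o2`, `o_asymmetric`.
#' @examples
#' analyze_site(make_site(site_spec(theta = 175, psi = 174)))
#' @export
analyze_site <- function(site, thresholds = mode_thresholds(), ...) {
  res <- tryCatch(
    {
      frame <- build_ligand_frame(site)
      mode <- classify_mode(compute_theta(frame), compute_psi(frame),
                            thresholds)
      geom <- compute_phi(site, ...)
      dplyr::bind_cols(
        tibble::tibble(chain = site$chain, frame = site$frame),
        mode,
        tibble::tibble(
          phi = geom$phi, axial_his = geom$axial_his,
          shape_label = geom$shape_label,
          cu_o1 = geom$cu_o_distances[1], cu_o2 = geom$cu_o_distances[2],
          o_asymmetric = geom$o_asymmetric
        )
      )
    },
    error = function(e) {
      abort(paste0("analysis failed for chain ", site$chain, ", frame ",
                   site$frame, ": ", conditionMessage(e)))
    }
  )
  res
}

#' Analyse every chain/model of a structure
#'
#' Runs [extract_active_site()] and [analyze_site()] over the requested
#' chains and models of an atom table.
#'
#' @param atoms Atom tibble ([read_structure()]).
#' @param chains Chains to analyse (default: all chains containing a Cu).
#' @param config Residue map ([site_config()]).
#' @param models Models to analyse (default: all).
#' @param ... Passed to [analyze_site()].
#' @return A tibble with one analysis row per chain/model.
#' @export
analyze_structure <- function(atoms, chains = NULL, config = site_config(),
                              models = NULL, ...) {
  if (is.null(chains)) {
    chains <- sort(unique(atoms$chain[atoms$element == "CU"]))
  }
  if (is.null(models)) models <- sort(unique(atoms$model))
  grid <- tidyr::expand_grid(chain = chains, model = models)
  purrr::pmap_dfr(grid, function(chain, model) {
    site <- extract_active_site(atoms, chain, config, model)
    analyze_site(site, ...)
  })
}
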