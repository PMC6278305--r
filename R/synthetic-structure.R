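# Synthetic reconstruction of a crystal-like structure: a full active site
# with realistic residue atom sets placed at prescribed geometry. These are
# stand-ins with known ground truth, not deposited coordinates.

#' Build a synthetic crystal-like structure
#'
#' Assembles a single-model atom table emulating the T2Cu neighbourhood of a
#' crystal structure: the copper-nitrite-histidine core from [make_site()]
#' at prescribed binding angles, plus full heavy-atom sidechains for the
#' Asp/Asn 97 and Tyr323 residues translated so their mass-weighted
#' sidechain centres of mass sit at prescribed distances from the catalytic
#' copper, and (optionally) a heme iron and a T1 copper placed at a
#' prescribed separation. Every prescribed quantity is recovered exactly by
#' the analysis pipeline, which is what makes the structure useful as an
#' offline stand-in with ground truth.
#'
#' The defaults emulate the native resting-state enzyme neighbourhood
#' (deprotonated Asp97, Tyr323 seated in the substrate channel); see the
#' examples for a nitrite-bound mutant-like configuration.
#'
#' @param theta,psi,phi Binding/twist angles for the core, degrees.
#' @param cu_distance Cu to nitrite-COM distance, Angstrom.
#' @param variant `"ASP"` (native) or `"ASN"` (D97N-mutant-like) residue 97.
#' @param asp_com_distance,tyr_com_distance Distance from the catalytic Cu
#'   to the sidechain COM of residue 97 and Tyr323, Angstrom.
#' @param fe_t1cu_distance If non-`NULL`, adds a heme iron (residue `HEC`)
#'   and a T1 copper this far apart (Angstrom), away from the active site.
#' @param chain Chain label.
#' @return A single-model atom tibble ([read_structure()] layout). The
#'   catalytic copper is residue 500; the T1 copper, when present, residue
#'   501.
#' @examples
#' atoms <- make_crystal_structure(theta = 4.9, psi = 45.2,
#'                                 variant = "ASN",
#'                                 asp_com_distance = 4.30,
#'                                 tyr_com_distance = 9.83)
#' analyze_structure(atoms, config = site_config(cu_resno = 500))
#' @export
make_crystal_structure <- function(theta = 5, psi = 12, phi = 85,
                                   cu_distance = 2.0,
                                   variant = c("ASP", "ASN"),
                                   asp_com_distance = 4.48,
                                   tyr_com_distance = 7.16,
                                   fe_t1cu_distance = NULL,
                                   chain = "A") {
  variant <- match.arg(variant)
  core <- make_site(site_spec(theta = theta, psi = psi, phi = phi,
                              cu_distance = cu_distance), chain = chain)
  atoms <- site_atoms(core)
  cu <- core$cu

  place_residue <- function(local, elements, target_com) {
    shift <- target_com - mass_com(local, elements)
    sweep(local, 2, -shift)
  }

  # Tyr323: idealised phenol ring + CB, translated so the sidechain COM
  # lands at the prescribed distance (direction chosen away from the core)
  ring <- t(vapply(0:5, function(k) {
    1.39 * c(cos(pi / 3 * k), sin(pi / 3 * k), 0)
  }, numeric(3)))
  tyr_local <- rbind(
    CB = c(-2.9, 0, 0.4), CG = ring[4, ], CD1 = ring[3, ], CD2 = ring[5, ],
    CE1 = ring[2, ], CE2 = ring[6, ], CZ = ring[1, ],
    OH = ring[1, ] + c(1.36, 0, 0)
  )
  tyr_el <- c("C", "C", "C", "C", "C", "C", "C", "O")
  u_tyr <- unit(c(0.2, -0.5, 0.9))
  tyr <- place_residue(tyr_local, tyr_el, cu + tyr_com_distance * u_tyr)

  # Asp/Asn 97 sidechain
  asp_local <- rbind(
    CB = c(0, 0, 0), CG = c(1.52, 0, 0),
    OD1 = c(2.2, 1.05, 0), OD2 = c(2.2, -1.05, 0)
  )
  asp_el <- c("C", "C", "O", if (variant == "ASP") "O" else "N")
  if (variant == "ASN") rownames(asp_local)[4] <- "ND2"
  u_asp <- unit(c(-0.4, -0.8, 0.5))
  asp <- place_residue(asp_local, asp_el, cu + asp_com_distance * u_asp)

  res_tbl <- function(coords, elements, resname, resno) {
    tibble::tibble(
      model = 1L, record = "ATOM", chain = chain, resname = resname,
      resno = resno, atom = rownames(coords), element = elements,
      altloc = "", x = coords[, 1], y = coords[, 2], z = coords[, 3],
      occupancy = 1, b_factor = 0
    )
  }
  resname97 <- if (variant == "ASP") "ASP" else "ASN"
  out <- dplyr::bind_rows(
    dplyr::mutate(atoms, record = ifelse(.data$resname %in% c("CU", "NO2"),
                                         "HETATM", "ATOM")),
    res_tbl(tyr, tyr_el, "TYR", 323L),
    res_tbl(asp, asp_el, resname97, 97L)
  )
  if (!is.null(fe_t1cu_distance)) {
    fe <- cu + c(20, 0, 0)
    t1 <- fe + fe_t1cu_distance * unit(c(0.3, 0.8, -0.5))
    out <- dplyr::bind_rows(out, tibble::tibble(
      model = 1L, record = "HETATM", chain = chain,
      resname = c("HEC", "CU"), resno = c(700L, 501L),
      atom = c("FE", "CU"), element = c("FE", "CU"), altloc = "",
      x = c(fe[1], t1[1]), y = c(fe[2], t1[2]), z = c(fe[3], t1[3]),
      occupancy = 1, b_factor = 0
    ))
  }
  out
}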