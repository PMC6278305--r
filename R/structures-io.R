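#' Read a PDB structure into a tidy atom table
#'
#' Parses a (possibly multi-model) PDB file and returns one row per atom with
#' the coordinate, occupancy, B-factor and alternate-location fields needed by
#' the downstream geometry. Waters and other hetero groups are retained.
#'
#' @param path Path to a PDB-format file.
#' @param model_policy Either `"all"` (one record set per `MODEL`, tagged by
#'   `model`) or `"first"` (only the first model).
#' @return A tibble with columns `model`, `record`, `chain`, `resname`,
#'   `resno`, `atom`, `element`, `altloc`, `x`, `y`, `z` (Angstrom),
#'   `occupancy` and `b_factor`.
#' @examples
#' pdb <- write_pdb(make_site(site_spec(theta = 170, psi = 175)),
#'                  tempfile(fileext = ".pdb"))
#' read_structure(pdb)
#' @export
read_structure <- function(path, model_policy = c("all", "first")) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) {
    abort(paste0("PDB file not found: ", path))
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = model_policy == "all",
                                     verbose = FALSE)),
    error = function(e) {
      abort(paste0("unparseable PDB file '", path, "': ", conditionMessage(e)))
    }
  )
  atom <- pdb$atom
  if (is.null(atom) || nrow(atom) == 0) {
    abort(paste0("empty structure: no ATOM/HETATM records in ", path))
  }
  n_models <- if (model_policy == "all") max(1L, nrow(pdb$xyz)) else 1L

  v <- list(
    record = atom$type,
    chain = dplyr::coalesce(atom$chain, ""),
    resname = atom$resid,
    resno = atom$resno,
    atom = atom$elety,
    element = guess_element(atom$elesy, atom$elety),
    altloc = dplyr::coalesce(atom$alt, ""),
    occupancy = dplyr::coalesce(atom$o, 1),
    b_factor = dplyr::coalesce(atom$b, 0)
  )
  base_cols <- tibble::as_tibble(v)
  one_model <- function(i) {
    xyz <- if (model_policy == "all") pdb$xyz[i, ] else pdb$xyz[1, ]
    m <- matrix(xyz, ncol = 3, byrow = TRUE)
    dplyr::mutate(base_cols, model = i, x = m[, 1], y = m[, 2], z = m[, 3],
                  .before = 1) |>
      dplyr::relocate("model")
  }
  out <- purrr::map_dfr(seq_len(n_models), one_model)
  bad <- !is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z)
  if (any(bad)) {
    abort(paste0("non-finite coordinates at atom row(s): ",
                 paste(head(which(bad), 5), collapse = ", ")))
  }
  out
}

# Element from the PDB element column, falling back to the first letter of the
# atom name (needed for minimal files written without element fields).
guess_element <- function(elesy, elety) {
  el <- toupper(trimws(dplyr::coalesce(elesy, "")))
  fallback <- sub("^[0-9]*([A-Za-z]).*$", "\\1", toupper(trimws(elety)))
  two_letter <- c("FE", "CU", "ZN", "MG", "MN", "NA", "CL", "BR")
  fb2 <- substr(gsub("[^A-Z]", "", toupper(trimws(elety))), 1, 2)
  fallback[fb2 %in% two_letter] <- fb2[fb2 %in% two_letter]
  ifelse(el == "", fallback, el)
}

#' Resolve alternate-location atoms
#'
#' For every (model, chain, residue, atom name) group with more than one
#' alternate location, keeps a single survivor: the highest fractional
#' occupancy, ties broken by the lowest B-factor, remaining ties by altloc
#' character order. Optionally removes partially occupied water molecules
#' afterwards.
#'
#' @param atoms Atom tibble as returned by [read_structure()].
#' @param remove_partial_waters If `TRUE`, water (`HOH`/`WAT`) atoms whose
#'   occupancy is still below 1 after altloc resolution are dropped.
#' @return The filtered atom tibble, in the original atom order.
#' @export
clean_altlocs <- function(atoms, remove_partial_waters = FALSE) {
  if (nrow(atoms) == 0) return(atoms)
  out <- atoms |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$model, .data$chain, .data$resno, .data$resname,
                    .data$atom) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$b_factor,
                   .data$altloc, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row")
  if (remove_partial_waters) {
    out <- dplyr::filter(
      out,
      !(.data$resname %in% c("HOH", "WAT") & .data$occupancy < 1)
    )
  }
  out
}

#' Default active-site residue map
#'
#' Residue numbers of the catalytic T2Cu site of the three-domain copper
#' nitrite reductase studied here: the three coordinating histidines
#' (His99, His134, His289) and the auxiliary residues Asp97 (Asn97 in the
#' D97N mutant), His240, Ile242 and Tyr323.
#'
#' @param cu_resname Residue name of the catalytic copper ion.
#' @param cu_resno Optional residue number of the catalytic copper, needed
#'   when a chain carries more than one copper (T1 and T2 sites).
#' @param his_resnos Residue numbers of the three coordinating histidines.
#' @param nitrite_resname Residue name of the nitrite ligand.
#' @param aux Named integer vector mapping auxiliary role labels to residue
#'   numbers; roles absent from a structure are recorded as missing, never an
#'   error.
#' @return A list understood by [extract_active_site()].
#' @export
site_config <- function(cu_resname = "CU", cu_resno = NULL,
                        his_resnos = c(99, 134, 289),
                        nitrite_resname = "NO2",
                        aux = c(Asp97 = 97, His240 = 240,
                                Ile242 = 242, Tyr323 = 323)) {
  stopifnot(length(his_resnos) == 3)
  list(
    cu_resname = cu_resname,
    cu_resno = cu_resno,
    his_resnos = as.integer(his_resnos),
    nitrite_resname = nitrite_resname,
    aux = aux
  )
}

#' Extract a T2Cu active site from an atom table
#'
#' Selects the copper ion, the coordinating sidechain nitrogen of each of the
#' three histidines (the ND1/NE2 atom nearer to Cu, robust to tautomer
#' naming), and the nitrite N/O atoms (mapped by element) from one chain and
#' model, along with any auxiliary atoms named in the configuration.
#'
#' @param atoms Atom tibble ([read_structure()] output).
#' @param chain Chain identifier to extract from.
#' @param config Residue map from [site_config()].
#' @param model Model (frame) index to extract.
#' @return An `active_site` object; see [active_site()].
#' @export
extract_active_site <- function(atoms, chain, config = site_config(),
                                model = 1) {
  sel <- dplyr::filter(atoms, .data$model == !!model, .data$chain == !!chain)
  if (nrow(sel) == 0) {
    abort(paste0("no atoms in chain '", chain, "', model ", model))
  }

  cu_rows <- dplyr::filter(sel, .data$resname == config$cu_resname,
                           .data$element == "CU")
  if (!is.null(config$cu_resno)) {
    cu_rows <- dplyr::filter(cu_rows, .data$resno == config$cu_resno)
  }
  if (nrow(cu_rows) == 0) {
    abort(paste0("no Cu atom (residue ", config$cu_resname, ") in chain ",
                 chain))
  }
  cu <- as_coord(cu_rows[1, ])

  his_n <- purrr::map(config$his_resnos, function(rn) {
    ns <- dplyr::filter(sel, .data$resno == rn,
                        .data$atom %in% c("ND1", "NE2"))
    if (nrow(ns) == 0) {
      abort(paste0("His ", rn, ": no sidechain nitrogen (ND1/NE2) found"))
    }
    d <- apply(as.matrix(ns[, c("x", "y", "z")]), 1,
               function(p) vnorm(p - cu))
    as_coord(ns[which.min(d), ])
  })
  names(his_n) <- paste0("His", config$his_resnos)

  nit <- dplyr::filter(sel, .data$resname == config$nitrite_resname)
  n_at <- dplyr::filter(nit, .data$element == "N")
  o_at <- dplyr::filter(nit, .data$element == "O")
  if (nrow(n_at) != 1 || nrow(o_at) != 2) {
    abort(paste0(
      "nitrite residue ", config$nitrite_resname, " in chain ", chain,
      " must contain exactly 1 N and 2 O atoms (found ", nrow(n_at),
      " N, ", nrow(o_at), " O)"
    ))
  }

  aux <- list()
  for (role in names(config$aux)) {
    rows <- dplyr::filter(sel, .data$resno == config$aux[[role]],
                          !(.data$resname %in% c("HOH", "WAT")))
    if (nrow(rows) > 0) {
      coords <- as.matrix(rows[, c("x", "y", "z")])
      rownames(coords) <- rows$atom
      aux[[role]] <- list(resname = rows$resname[1], coords = coords,
                          elements = rows$element)
    }
  }

  active_site(
    cu = cu,
    his_n = his_n,
    nitrite_n = as_coord(n_at[1, ]),
    nitrite_o1 = as_coord(o_at[1, ]),
    nitrite_o2 = as_coord(o_at[2, ]),
    aux = aux,
    chain = chain,
    frame = model
  )
}

as_coord <- function(row) c(x = row$x, y = row$y, z = row$z)

#' Mass-weighted sidechain centre of mass
#'
#' Computes the mass-weighted centre of mass of a residue sidechain, by
#' default over heavy atoms from C-beta onward (backbone N, CA, C, O and all
#' hydrogens excluded) so that crystal structures without hydrogens and MD
#' snapshots give comparable values.
#'
#' @param atoms Atom tibble.
#' @param chain,resno Residue address.
#' @param model Model index.
#' @param include_hydrogens Include hydrogen atoms in the mass weighting.
#' @return A one-row tibble: `chain`, `resno`, `resname`, `x`, `y`, `z`,
#'   `atom_count`.
#' @export
sidechain_com <- function(atoms, chain, resno, model = 1,
                          include_hydrogens = FALSE) {
  backbone <- c("N", "CA", "C", "O", "OXT")
  sel <- dplyr::filter(
    atoms, .data$model == !!model, .data$chain == !!chain,
    .data$resno == !!resno, !(.data$atom %in% backbone)
  )
  if (!include_hydrogens) sel <- dplyr::filter(sel, .data$element != "H")
  if (nrow(sel) == 0) {
    abort(paste0("residue ", chain, ":", resno,
                 " has no sidechain atoms (absent or glycine)"))
  }
  com <- unname(mass_com(as.matrix(sel[, c("x", "y", "z")]), sel$element))
  tibble::tibble(
    chain = chain, resno = resno, resname = sel$resname[1],
    x = com[1], y = com[2], z = com[3], atom_count = nrow(sel)
  )
}
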