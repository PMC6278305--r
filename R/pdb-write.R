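#' Write atoms or an active site to a PDB file
#'
#' Writes fixed-width PDB text. An atom tibble (the [read_structure()] layout)
#' is written model by model; an `active_site` (or list of them, one per
#' frame) is first expanded to atom records with conventional residue names
#' (`CU` for the copper ion, `NO2` for nitrite, histidine/auxiliary residues
#' under their own numbers) so that the file round-trips through
#' [read_structure()] and [extract_active_site()].
#'
#' @param x Atom tibble, `active_site`, or list of `active_site` frames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  atoms <- if (inherits(x, "active_site")) {
    site_atoms(x)
  } else if (is.list(x) && !is.data.frame(x) &&
             all(vapply(x, inherits, TRUE, "active_site"))) {
    purrr::map_dfr(seq_along(x), function(i) {
      dplyr::mutate(site_atoms(x[[i]]), model = i)
    })
  } else {
    x
  }
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)

  models <- sort(unique(atoms$model))
  multi <- length(models) > 1
  con <- file(path, "w")
  on.exit(close(con))
  for (m in models) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    sub <- atoms[atoms$model == m, ]
    writeLines(format_pdb_lines(sub), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

format_pdb_lines <- function(atoms) {
  record <- if ("record" %in% names(atoms)) atoms$record else
    ifelse(atoms$resname %in% c("CU", "NO2", "HOH", "WAT", "HEC"),
           "HETATM", "ATOM")
  altloc <- if ("altloc" %in% names(atoms)) atoms$altloc else ""
  occ <- if ("occupancy" %in% names(atoms)) atoms$occupancy else 1
  b <- if ("b_factor" %in% names(atoms)) atoms$b_factor else 0
  name4 <- ifelse(
    nchar(atoms$atom) >= 4, substr(atoms$atom, 1, 4),
    sprintf("%-4s", paste0(" ", atoms$atom))
  )
  sprintf(
    "%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    record, seq_len(nrow(atoms)), name4,
    substr(paste0(altloc, " "), 1, 1), atoms$resname,
    substr(paste0(atoms$chain, " "), 1, 1), atoms$resno,
    atoms$x, atoms$y, atoms$z, occ, b,
    sprintf("%2s", substr(atoms$element, 1, 2))
  )
}

# Expand an active_site to atom records. Residue numbers: Cu 500, nitrite
# 600; His/aux numbers parsed from their labels (e.g. "His99" -> 99).
site_atoms <- function(site) {
  label_resno <- function(lbl, default) {
    n <- suppressWarnings(as.integer(gsub("[^0-9]", "", lbl)))
    if (is.na(n)) default else n
  }
  rows <- list(tibble::tibble(
    resname = "CU", resno = 500L, atom = "CU", element = "CU",
    x = site$cu[1], y = site$cu[2], z = site$cu[3]
  ))
  for (h in names(site$his_n)) {
    v <- site$his_n[[h]]
    rows <- c(rows, list(tibble::tibble(
      resname = "HIS", resno = label_resno(h, 0L), atom = "NE2",
      element = "N", x = v[1], y = v[2], z = v[3]
    )))
  }
  nit <- rbind(site$nitrite_n, site$nitrite_o1, site$nitrite_o2)
  rows <- c(rows, list(tibble::tibble(
    resname = "NO2", resno = 600L, atom = c("N", "O1", "O2"),
    element = c("N", "O", "O"),
    x = nit[, 1], y = nit[, 2], z = nit[, 3]
  )))
  for (a in names(site$aux)) {
    e <- site$aux[[a]]
    rows <- c(rows, list(tibble::tibble(
      resname = e$resname, resno = label_resno(a, 900L),
      atom = rownames(e$coords), element = e$elements,
      x = e$coords[, 1], y = e$coords[, 2], z = e$coords[, 3]
    )))
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(model = site$frame, chain = site$chain,
                  altloc = "", occupancy = 1, b_factor = 0)
}
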