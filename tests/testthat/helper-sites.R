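# Fixture builders used across test files.

vnorm_test <- function(v) sqrt(sum(v^2))

# An active site with nitrite in canonical position (COM at origin, N on
# +X, O atoms in the XY plane) and Cu at the requested *local* coordinates;
# His positions are incidental (valid but unused by frame/angle tests).
canonical_site <- function(cu_local) {
  b <- 1.25
  beta <- 115 / 2 * pi / 180
  n_pos <- c(0, 0, 0)
  o1 <- c(-b * cos(beta), b * sin(beta), 0)
  o2 <- c(-b * cos(beta), -b * sin(beta), 0)
  m <- c(14.007, 15.999, 15.999)
  com <- colSums(rbind(n_pos, o1, o2) * m) / sum(m)
  active_site(
    cu = cu_local,
    his_n = list(His99 = c(4, 1, 0), His134 = c(4, -1, 1),
                 His289 = c(4, 0, -1)),
    nitrite_n = n_pos - com, nitrite_o1 = o1 - com, nitrite_o2 = o2 - com
  )
}

# Minimal multi-model PDB text written directly (independent of write_pdb).
raw_pdb_lines <- function(n_models = 1, atoms_per_model = 3) {
  lines <- character(0)
  for (m in seq_len(n_models)) {
    if (n_models > 1) lines <- c(lines, sprintf("MODEL     %4d", m))
    for (i in seq_len(atoms_per_model)) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00 10.00           C",
        i, i, i * 1.5, m * 1.0, 0
      ))
    }
    if (n_models > 1) lines <- c(lines, "ENDMDL")
  }
  c(lines, "END")
}

# Atom tibble row constructor for hand-built fixtures.
atom_row <- function(chain = "A", resname = "ALA", resno = 1L, atom = "CA",
                     element = "C", x = 0, y = 0, z = 0, occupancy = 1,
                     b_factor = 10, altloc = "", model = 1L,
                     record = "ATOM") {
  tibble::tibble(
    model = model, record = record, chain = chain, resname = resname,
    resno = as.integer(resno), atom = atom, element = element,
    altloc = altloc, x = x, y = y, z = z, occupancy = occupancy,
    b_factor = b_factor
  )
}
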