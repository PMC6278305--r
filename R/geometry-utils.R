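# Small vector helpers shared by the geometry code. All coordinates are in
# Angstrom; all angles returned in degrees.

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

# Angle at the vertex between rays vertex->a and vertex->b, in [0, 180] deg.
vertex_angle <- function(a, vertex, b) {
  u <- a - vertex
  v <- b - vertex
  deg(atan2(vnorm(cross3(u, v)), sum(u * v)))
}

# Standard atomic masses (u) for the elements that occur around the active
# site. Mass-weighted centres of mass use these.
ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, FE = 55.845, CU = 63.546, NA. = 22.990, CL = 35.45
)

element_mass <- function(element) {
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NA."
  m <- ATOMIC_MASSES[key]
  if (anyNA(m)) {
    abort(paste0(
      "unknown element(s): ",
      paste(unique(element[is.na(m)]), collapse = ", ")
    ))
  }
  unname(m)
}

# Mass-weighted centre of mass of an n x 3 coordinate matrix.
mass_com <- function(coords, elements) {
  m <- element_mass(elements)
  colSums(coords * m) / sum(m)
}
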