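# Synthetic active-site generation: the deterministic inverse of the
# ligand-frame / theta / psi / phi construction, with known ground truth.

#' Specification for a synthetic active site
#'
#' Describes a T2Cu-nitrite site to be realised by [make_site()]: the target
#' binding angles, Cu distance, coordination twist, and the internal nitrite
#' geometry (ideal bond length 1.25 Angstrom and O-N-O angle 115 degrees by
#' default).
#'
#' Feasibility: because theta and psi share the sign of the local X component
#' of Cu, a site can only realise pairs with theta and psi on the same side
#' of 90 degrees (or both exactly 90).
#'
#' @param theta,psi Target binding angles, degrees in \[0, 180\].
#' @param cu_distance Cu to nitrite-COM distance, Angstrom.
#' @param phi Target coordination twist angle, degrees in \[0, 180\].
#' @param his_cu_distance His N to Cu distance, Angstrom.
#' @param axial_angle N(nitrite)-Cu-N(His_axial) angle, degrees; must exceed
#'   `equatorial_angle` so the axial-His rule is unambiguous.
#' @param equatorial_angle N(nitrite)-Cu-N(His_eq) angle, degrees in
#'   (90, 180) exclusive of the axial value.
#' @param no_bond Nitrite N-O bond length, Angstrom.
#' @param ono_angle Nitrite O-N-O angle, degrees.
#' @param noise_sigma Isotropic Gaussian coordinate noise, Angstrom.
#' @param seed Optional integer seed (used only when `noise_sigma > 0`).
#' @return A `site_spec` list.
#' @export
site_spec <- function(theta, psi, cu_distance = 2.0, phi = 90,
                      his_cu_distance = 2.0, axial_angle = 160,
                      equatorial_angle = 100, no_bond = 1.25,
                      ono_angle = 115, noise_sigma = 0, seed = NULL) {
  stopifnot(
    theta >= 0, theta <= 180, psi >= 0, psi <= 180,
    phi >= 0, phi <= 180, cu_distance > 0, his_cu_distance > 0,
    no_bond > 0, ono_angle > 0, ono_angle < 180, noise_sigma >= 0,
    axial_angle > equatorial_angle, equatorial_angle > 90,
    axial_angle < 180
  )
  mixed <- (theta < 90) != (psi < 90) ||
    (theta == 90) != (psi == 90)
  if (mixed) {
    abort(paste0(
      "infeasible spec: theta = ", theta, " and psi = ", psi,
      " lie on opposite sides of 90 degrees (they share the sign of the ",
      "local X component of Cu)"
    ))
  }
  structure(
    list(theta = theta, psi = psi, cu_distance = cu_distance, phi = phi,
         his_cu_distance = his_cu_distance, axial_angle = axial_angle,
         equatorial_angle = equatorial_angle, no_bond = no_bond,
         ono_angle = ono_angle, noise_sigma = noise_sigma, seed = seed),
    class = "site_spec"
  )
}

# Unit vector whose altitudinal/azimuthal angles are (theta, psi).
cu_direction <- function(theta, psi) {
  if (theta == 90 && psi == 90) return(c(0, 1, 1) / sqrt(2))
  x0 <- if (theta < 90) 1 else -1
  unit(c(x0, x0 * tan(rad(psi)), x0 * tan(rad(theta))))
}

#' Build a synthetic active site at prescribed angles
#'
#' Realises a [site_spec()]: nitrite is laid out in its canonical frame (COM
#' at the origin, N on +X, O atoms in the XY plane), copper is placed on the
#' direction that reproduces the target (theta, psi) at the requested
#' distance, and the three histidine nitrogens are arranged around Cu so that
#' the axial-His rule and the twist angle phi recover their targets exactly.
#' With `noise_sigma = 0`, [analyze_site()] on the result returns the targets
#' to numerical precision.
#'
#' @param spec A `site_spec`.
#' @param chain,frame Labels attached to the site.
#' @return An `active_site` whose `His99` and `His134` are the equatorial
#'   ligands and `His289` the axial one.
#' @examples
#' analyze_site(make_site(site_spec(theta = 5, psi = 15)))
#' @export
make_site <- function(spec, chain = "A", frame = 1L) {
  stopifnot(inherits(spec, "site_spec"))

  # nitrite in canonical position
  b <- spec$no_bond
  beta <- rad(spec$ono_angle / 2)
  n_pos <- c(0, 0, 0)
  o1 <- c(-b * cos(beta), b * sin(beta), 0)
  o2 <- c(-b * cos(beta), -b * sin(beta), 0)
  com <- mass_com(rbind(n_pos, o1, o2), c("N", "O", "O"))
  n_pos <- n_pos - com; o1 <- o1 - com; o2 <- o2 - com

  cu <- spec$cu_distance * cu_direction(spec$theta, spec$psi)

  # Local orthonormal basis at Cu with e1 towards the nitrite N
  e1 <- unit(n_pos - cu)
  ref <- if (abs(e1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e3 <- unit(cross3(e1, ref))
  e2 <- cross3(e3, e1)

  r <- spec$his_cu_distance
  a1 <- rad(spec$axial_angle)
  his_ax <- cu + r * (cos(a1) * e1 + sin(a1) * e2)

  # Plane normal of the equatorial pair at angle phi from the axial-plane
  # normal e3. The equatorial cone angle > 90 makes the computed normal
  # orientation (residue-number atom order) match this construction.
  phi_star <- rad(spec$phi)
  n2 <- cos(phi_star) * e3 + sin(phi_star) * e2
  w2 <- cross3(n2, e1)
  bb <- rad(spec$equatorial_angle)
  his_eq1 <- cu + r * (cos(bb) * e1 + sin(bb) * w2)
  his_eq2 <- cu + r * (cos(bb) * e1 - sin(bb) * w2)

  site <- active_site(
    cu = cu,
    his_n = list(His99 = his_eq1, His134 = his_eq2, His289 = his_ax),
    nitrite_n = n_pos, nitrite_o1 = o1, nitrite_o2 = o2,
    chain = chain, frame = frame
  )

  if (spec$noise_sigma > 0) {
    with_seed(spec$seed, {
      jitter <- function(v) v + rnorm(3, 0, spec$noise_sigma)
      site <- active_site(
        cu = jitter(site$cu),
        his_n = lapply(site$his_n, jitter),
        nitrite_n = jitter(site$nitrite_n),
        nitrite_o1 = jitter(site$nitrite_o1),
        nitrite_o2 = jitter(site$nitrite_o2),
        chain = chain, frame = frame
      )
    })
  }
  site
}

# Run code under a temporary RNG state seeded with `seed` (NULL = use the
# current stream).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(eval.parent(substitute(code)))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  eval.parent(substitute(code))
}
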