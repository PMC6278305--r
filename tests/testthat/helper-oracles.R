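# Independent brute-force implementations used as oracles for the frame and
# angle computations, deliberately built along different code paths
# (Gram-Schmidt rotation matrix; QR null-space plane normals; acos-based
# angles) than the package internals.

xprod <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

nitrite_com <- function(site) {
  m <- c(14.007, 15.999, 15.999)
  p <- rbind(site$nitrite_n, site$nitrite_o1, site$nitrite_o2)
  colSums(p * m) / sum(m)
}

# Frame oracle: Gram-Schmidt over (N - COM, O1 - COM) gives an in-plane
# orthonormal pair; the plane normal completes the rotation matrix, whose
# transpose maps Cu to local coordinates. Sign conventions (Z towards Cu;
# Y >= 0 in the exact in-plane case) applied afterwards.
oracle_cu_local <- function(site) {
  com <- nitrite_com(site)
  u1 <- site$nitrite_n - com
  x <- u1 / sqrt(sum(u1^2))
  u2 <- site$nitrite_o1 - com
  v2 <- u2 - sum(u2 * x) * x
  y_in_plane <- v2 / sqrt(sum(v2^2))
  z <- xprod(x, y_in_plane)
  rel <- site$cu - com
  if (abs(sum(rel * z)) < 1e-9) {
    y_conv <- xprod(z, x)
    if (sum(rel * y_conv) < 0) z <- -z
  } else if (sum(rel * z) < 0) {
    z <- -z
  }
  y <- xprod(z, x)
  rot <- cbind(x, y, z)
  as.numeric(t(rot) %*% rel)
}

oracle_theta <- function(site) {
  p <- oracle_cu_local(site)
  r <- sqrt(p[1]^2 + p[3]^2)
  acos(max(-1, min(1, p[1] / r))) * 180 / pi
}

oracle_psi <- function(site) {
  p <- oracle_cu_local(site)
  r <- sqrt(p[1]^2 + p[2]^2)
  acos(max(-1, min(1, p[1] / r))) * 180 / pi
}

# Normal of the plane through (a, vertex, b) via the QR null space of the
# two spanning vectors, oriented by the determinant rule so it matches the
# right-handed orientation of (a - vertex, b - vertex).
qr_plane_normal <- function(a, vertex, b) {
  m <- cbind(a - vertex, b - vertex)
  n <- qr.Q(qr(m), complete = TRUE)[, 3]
  if (det(cbind(m, n)) < 0) n <- -n
  n / sqrt(sum(n^2))
}

# Twist-angle oracle: axial His by largest acos-angle, plane normals by QR.
oracle_phi <- function(site) {
  cu <- site$cu
  nn <- site$nitrite_n
  ang <- vapply(site$his_n, function(h) {
    u <- nn - cu; v <- h - cu
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  }, 1.0)
  axial <- names(site$his_n)[which.max(ang)]
  eq <- setdiff(names(site$his_n), axial)
  eq_num <- as.numeric(gsub("[^0-9]", "", eq))
  eq <- eq[order(eq_num)]
  n1 <- qr_plane_normal(nn, cu, site$his_n[[axial]])
  n2 <- qr_plane_normal(site$his_n[[eq[1]]], cu, site$his_n[[eq[2]]])
  acos(max(-1, min(1, sum(n1 * n2)))) * 180 / pi
}

# A random geometrically valid active site (uniform angles on the feasible
# side of 90, random distances), optionally pushed through a random rigid
# motion so nothing is axis-aligned.
random_site <- function(scramble = TRUE) {
  low <- runif(1) < 0.5
  theta <- if (low) runif(1, 2, 88) else runif(1, 92, 178)
  psi <- if (low) runif(1, 2, 88) else runif(1, 92, 178)
  spec <- site_spec(
    theta = theta, psi = psi,
    cu_distance = runif(1, 1.8, 2.8),
    phi = runif(1, 5, 175),
    his_cu_distance = runif(1, 1.9, 2.2),
    axial_angle = runif(1, 140, 175),
    equatorial_angle = runif(1, 95, 130)
  )
  site <- make_site(spec)
  if (scramble) {
    rot <- random_rotation_test()
    site <- transform_site(site, rot, rnorm(3, 0, 10))
  }
  attr(site, "spec") <- spec
  site
}

random_rotation_test <- function() {
  d <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(d) %*% diag(sign(diag(qr.R(d))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
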