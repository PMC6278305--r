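#' Construct an active-site object
#'
#' Bundles the labelled coordinates of a T2Cu catalytic site: the copper ion,
#' the three coordinating histidine sidechain nitrogens, the nitrite N/O1/O2
#' atoms, and any auxiliary residues (as full sidechain coordinate blocks).
#' All atoms must come from the same model/frame.
#'
#' @param cu Numeric length-3 Cu position (Angstrom).
#' @param his_n Named list of exactly three length-3 histidine N positions.
#' @param nitrite_n,nitrite_o1,nitrite_o2 Nitrite atom positions.
#' @param aux Named list of auxiliary residues; each entry a list with
#'   `resname`, a coordinate matrix `coords` (rownames = atom names) and
#'   `elements`.
#' @param chain Chain identifier.
#' @param frame Model/frame index (integer >= 1).
#' @return An object of class `active_site`.
#' @export
active_site <- function(cu, his_n, nitrite_n, nitrite_o1, nitrite_o2,
                        aux = list(), chain = "A", frame = 1L) {
  cu <- as.numeric(cu)
  stopifnot(length(cu) == 3, all(is.finite(cu)))
  if (length(his_n) != 3) {
    abort("an active site requires exactly 3 histidine nitrogens")
  }
  his_n <- lapply(his_n, function(v) {
    v <- as.numeric(v)
    stopifnot(length(v) == 3, all(is.finite(v)))
    v
  })
  if (is.null(names(his_n))) names(his_n) <- paste0("His", 1:3)
  nitrite <- lapply(list(nitrite_n, nitrite_o1, nitrite_o2), as.numeric)
  stopifnot(all(vapply(nitrite, length, 1L) == 3))
  if (vnorm(nitrite[[1]] - nitrite[[2]]) <= 0 ||
      vnorm(nitrite[[1]] - nitrite[[3]]) <= 0 ||
      vnorm(nitrite[[2]] - nitrite[[3]]) <= 0) {
    abort("degenerate nitrite: coincident atoms")
  }
  structure(
    list(
      cu = cu, his_n = his_n,
      nitrite_n = nitrite[[1]], nitrite_o1 = nitrite[[2]],
      nitrite_o2 = nitrite[[3]],
      aux = aux, chain = chain, frame = as.integer(frame)
    ),
    class = "active_site"
  )
}

#' @export
print.active_site <- function(x, ...) {
  cat("<active_site> chain", x$chain, "frame", x$frame, "\n")
  cat("  Cu at [", paste(sprintf("%.3f", x$cu), collapse = ", "), "]\n")
  cat("  His N:", paste(names(x$his_n), collapse = ", "), "\n")
  if (length(x$aux)) cat("  aux:", paste(names(x$aux), collapse = ", "), "\n")
  invisible(x)
}

#' Flatten an active site to a coordinate table
#'
#' @param x An `active_site`.
#' @param ... Unused.
#' @return A tibble with columns `role`, `chain`, `frame`, `atom`, `x`, `y`,
#'   `z` — the flat serialisation used for delimited-text export.
#' @export
as_tibble.active_site <- function(x, ...) {
  rows <- list(
    tibble::tibble(role = "Cu", atom = "CU",
                   x = x$cu[1], y = x$cu[2], z = x$cu[3])
  )
  for (h in names(x$his_n)) {
    v <- x$his_n[[h]]
    rows <- c(rows, list(tibble::tibble(role = h, atom = "N",
                                        x = v[1], y = v[2], z = v[3])))
  }
  nit <- rbind(N = x$nitrite_n, O1 = x$nitrite_o1, O2 = x$nitrite_o2)
  rows <- c(rows, list(tibble::tibble(
    role = "nitrite", atom = rownames(nit),
    x = nit[, 1], y = nit[, 2], z = nit[, 3]
  )))
  for (a in names(x$aux)) {
    cm <- x$aux[[a]]$coords
    rows <- c(rows, list(tibble::tibble(
      role = a, atom = rownames(cm),
      x = cm[, 1], y = cm[, 2], z = cm[, 3]
    )))
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(chain = x$chain, frame = x$frame,
                  .after = "role")
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

# Apply a rigid motion (rotation matrix R then translation t) to every atom
# of a site. Used by the invariance tests and exported for completeness.

#' Rigidly transform an active site
#'
#' Applies a proper rotation followed by a translation to every atom of the
#' site. Geometric descriptors (theta, psi, phi, distances) are invariant
#' under this operation.
#'
#' @param site An `active_site`.
#' @param rotation 3x3 proper rotation matrix.
#' @param translation Length-3 translation vector (Angstrom).
#' @return The transformed `active_site`.
#' @export
transform_site <- function(site, rotation = diag(3), translation = c(0, 0, 0)) {
  tr <- function(v) as.numeric(rotation %*% v + translation)
  aux <- lapply(site$aux, function(a) {
    a$coords <- t(apply(a$coords, 1, tr))
    a
  })
  active_site(
    cu = tr(site$cu),
    his_n = lapply(site$his_n, tr),
    nitrite_n = tr(site$nitrite_n),
    nitrite_o1 = tr(site$nitrite_o1),
    nitrite_o2 = tr(site$nitrite_o2),
    aux = aux, chain = site$chain, frame = site$frame
  )
}
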