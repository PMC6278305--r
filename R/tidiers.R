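#' Tidy the Cu-centred angle table of a coordination geometry
#'
#' @param x A `coordination_geometry` from [compute_phi()].
#' @param ... Unused.
#' @return Tibble of the six pairwise Cu-centred angles: `atom_a`, `atom_b`,
#'   `angle` (degrees).
#' @export
tidy.coordination_geometry <- function(x, ...) {
  x$angles
}

#' One-row summary of a coordination geometry
#'
#' @param x A `coordination_geometry`.
#' @param ... Unused.
#' @return One-row tibble: `phi`, `axial_his`, `shape_label`, `cu_o1`,
#'   `cu_o2`, `o_asymmetric`, `max_angle`.
#' @export
glance.coordination_geometry <- function(x, ...) {
  tibble::tibble(
    phi = x$phi, axial_his = x$axial_his, shape_label = x$shape_label,
    cu_o1 = x$cu_o_distances[1], cu_o2 = x$cu_o_distances[2],
    o_asymmetric = x$o_asymmetric, max_angle = max(x$angles$angle)
  )
}

#' Tidy a ligand frame
#'
#' @param x A `ligand_frame` from [build_ligand_frame()].
#' @param ... Unused.
#' @return Tibble with one row per frame element (origin, axes, Cu in local
#'   coordinates) and columns `element`, `x`, `y`, `z`.
#' @export
tidy.ligand_frame <- function(x, ...) {
  m <- rbind(origin = x$origin, x_axis = x$x_axis, y_axis = x$y_axis,
             z_axis = x$z_axis, cu_local = x$cu_local)
  tibble::tibble(element = rownames(m), x = m[, 1], y = m[, 2], z = m[, 3])
}

#' Share of structures per binding mode
#'
#' Aggregates an [analyze_structure()] result into the percentage of
#' analysed structures falling in each binding-mode label, optionally within
#' groups (e.g. system and oxidation state columns joined beforehand).
#'
#' @param results Tibble with a `mode_label` column.
#' @param ... Grouping columns (tidy-select, unquoted).
#' @return Tibble with `mode_label`, `n` and `percent` per group.
#' @export
mode_shares <- function(results, ...) {
  results |>
    dplyr::group_by(..., .data$mode_label) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop_last") |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
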