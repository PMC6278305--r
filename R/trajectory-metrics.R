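# Per-frame distance metrics over multi-model atom tables and their
# summaries: Cu to sidechain-COM distances, the Tyr-phenolic hydrogen bond
# to the Asp/Asn acceptor set, occupancies and split-regime statistics.

#' Hydrogen-bond distance series
#'
#' For every frame, the distance from the donor atom (the phenolic hydrogen
#' of the donor residue, falling back to the phenolic oxygen when the
#' structure carries no hydrogens) to the *nearest* atom of the acceptor set,
#' re-selected every frame: the two carboxylate oxygens for Asp, the
#' sidechain O and N for Asn.
#'
#' @param atoms Multi-model atom tibble.
#' @param chain Chain to analyse.
#' @param donor_resno Donor residue number (default Tyr323).
#' @param acceptor_resno Acceptor residue number (default Asp/Asn 97).
#' @param dt Frame-to-ns conversion: frame i maps to time (i - 1) * dt.
#' @return Tibble: `time` (ns), `value` (Angstrom), `metric`, `chain`.
#' @export
hbond_series <- function(atoms, chain, donor_resno = 323,
                         acceptor_resno = 97, dt = 1) {
  sel <- dplyr::filter(atoms, .data$chain == !!chain)
  models <- sort(unique(sel$model))
  if (length(models) == 0) abort(paste0("no atoms in chain ", chain))

  donors <- dplyr::filter(sel, .data$resno == donor_resno,
                          .data$atom %in% c("HH", "OH"))
  acceptors <- dplyr::filter(
    sel, .data$resno == acceptor_resno,
    (.data$resname == "ASP" & .data$atom %in% c("OD1", "OD2")) |
      (.data$resname == "ASN" & .data$atom %in% c("OD1", "ND2")) |
      (!.data$resname %in% c("ASP", "ASN") & .data$element %in% c("O", "N") &
         !.data$atom %in% c("N", "O"))
  )
  missing_frames <- setdiff(models, unique(donors$model))
  if (length(missing_frames) > 0) {
    abort(paste0("donor residue ", donor_resno,
                 " missing its phenolic H/O in frame(s): ",
                 paste(head(missing_frames, 10), collapse = ", ")))
  }
  missing_acc <- setdiff(models, unique(acceptors$model))
  if (length(missing_acc) > 0) {
    abort(paste0("acceptor residue ", acceptor_resno,
                 " missing in frame(s): ",
                 paste(head(missing_acc, 10), collapse = ", ")))
  }

  value <- vapply(models, function(m) {
    don <- donors[donors$model == m, ]
    # prefer the hydrogen when present
    don <- if (any(don$atom == "HH")) don[don$atom == "HH", ][1, ] else
      don[1, ]
    acc <- acceptors[acceptors$model == m, ]
    min(sqrt((acc$x - don$x)^2 + (acc$y - don$y)^2 + (acc$z - don$z)^2))
  }, 1.0)

  tibble::tibble(
    time = (models - 1) * dt, value = value,
    metric = "hbond", chain = chain
  )
}

#' Cu to sidechain-COM distance series
#'
#' Per frame, the distance between the catalytic copper and the
#' mass-weighted sidechain centre of mass of the named residue.
#'
#' @param atoms Multi-model atom tibble.
#' @param chain Chain to analyse.
#' @param resno Residue number whose sidechain COM is tracked.
#' @param dt Frame-to-ns conversion.
#' @param cu_resname Residue name of the copper ion.
#' @param include_hydrogens Include hydrogens in the COM (see
#'   [sidechain_com()]).
#' @return Tibble: `time`, `value`, `metric`, `chain`.
#' @export
com_distance_series <- function(atoms, chain, resno, dt = 1,
                                cu_resname = "CU",
                                include_hydrogens = FALSE) {
  sel <- dplyr::filter(atoms, .data$chain == !!chain)
  models <- sort(unique(sel$model))
  if (length(models) == 0) abort(paste0("no atoms in chain ", chain))
  value <- vapply(models, function(m) {
    cu_rows <- dplyr::filter(sel, .data$model == m,
                             .data$resname == cu_resname,
                             .data$element == "CU")
    if (nrow(cu_rows) == 0) {
      abort(paste0("no Cu atom in chain ", chain, ", frame ", m))
    }
    com <- sidechain_com(sel, chain, resno, model = m,
                         include_hydrogens = include_hydrogens)
    vnorm(c(cu_rows$x[1] - com$x, cu_rows$y[1] - com$y,
            cu_rows$z[1] - com$z))
  }, 1.0)
  tibble::tibble(
    time = (models - 1) * dt, value = value,
    metric = paste0("com", resno), chain = chain
  )
}

#' Summarise a distance series
#'
#' Arithmetic mean and standard deviation (population form by default) of a
#' series, optionally split at an event time into separate before/after
#' segments — the dual-regime report used when a sidechain displacement
#' changes the baseline mid-trajectory.
#'
#' @param series Tibble with `time` and `value` columns.
#' @param split_time Optional event time (ns) splitting the series into
#'   `time < split_time` and `time >= split_time` segments.
#' @param sample_sd Use the n-1 standard deviation instead of the population
#'   form.
#' @return Tibble: `segment`, `t_start`, `t_end`, `n_frames`, `mean`, `sd`.
#' @export
summarize_series <- function(series, split_time = NULL, sample_sd = FALSE) {
  if (nrow(series) == 0) abort("empty series")
  stat <- function(v, t, segment) {
    s <- if (sample_sd) {
      if (length(v) > 1) sd(v) else 0
    } else {
      sqrt(mean((v - mean(v))^2))
    }
    tibble::tibble(segment = segment, t_start = min(t), t_end = max(t),
                   n_frames = length(v), mean = mean(v), sd = s)
  }
  if (is.null(split_time)) {
    return(stat(series$value, series$time, "all"))
  }
  if (split_time <= min(series$time) || split_time > max(series$time)) {
    abort("split_time outside the series time range")
  }
  pre <- series$time < split_time
  dplyr::bind_rows(
    stat(series$value[pre], series$time[pre], "before"),
    stat(series$value[!pre], series$time[!pre], "after")
  )
}

#' Hydrogen-bond occupancy
#'
#' Fraction of frames whose donor-acceptor distance is at or below the
#' cutoff (default 2.5 Angstrom for a donor-H to acceptor distance).
#'
#' @param series Distance series tibble.
#' @param cutoff Distance cutoff, Angstrom.
#' @return Fraction in \[0, 1\].
#' @export
hbond_occupancy <- function(series, cutoff = 2.5) {
  stopifnot(cutoff > 0)
  mean(series$value <= cutoff)
}
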