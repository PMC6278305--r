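# Paired conformer energy analysis: the binding-preference statistic
# delta E = E(top-hat) - E(N-bound), positive when N-bound is favoured.
# Absolute energies of different snapshots are never comparable (each
# conformer carries its own solvent shell), so energies are only ever
# differenced within a pair key.

#' Filter flagged conformer records
#'
#' Removes records flagged with an unphysically short Cu-O(Asp97) contact —
#' relaxed structures not observed experimentally — when the discard policy
#' is on. Every removal is reported; the discarded rows are attached as the
#' `"discarded"` attribute.
#'
#' @param records Conformer energy tibble with (at least) columns `system`,
#'   `snapshot_id`, `chain`, `oxidation_state`, `orientation`, `energy`,
#'   `flag_short_contact` (logical).
#' @param drop_flagged Apply the discard rule (default `TRUE`).
#' @return The surviving records, with attribute `discarded`.
#' @export
filter_conformers <- function(records, drop_flagged = TRUE) {
  stopifnot("flag_short_contact" %in% names(records))
  if (!drop_flagged) {
    out <- records
    attr(out, "discarded") <- records[0, ]
    return(out)
  }
  flagged <- dplyr::filter(records, .data$flag_short_contact)
  out <- dplyr::filter(records, !.data$flag_short_contact)
  if (nrow(flagged) > 0) {
    rlang::inform(c(
      paste0("discarded ", nrow(flagged),
             " conformer record(s) with short Cu-O contact:"),
      purrr::pmap_chr(
        flagged[, c("system", "snapshot_id", "chain", "oxidation_state")],
        function(system, snapshot_id, chain, oxidation_state) {
          paste(system, snapshot_id, chain, oxidation_state)
        }
      )
    ))
  }
  attr(out, "discarded") <- flagged
  out
}

#' Pair top-hat and N-bound conformer energies
#'
#' For every (system, snapshot, chain, oxidation state) key holding exactly
#' one relaxed top-hat and one relaxed N-bound record, computes
#' delta E = E(top-hat) - E(N-bound). Unpaired records are reported with a
#' warning, excluded, and attached as the `"unpaired"` attribute; duplicate
#' records for a key are a hard error.
#'
#' @param records Conformer energy tibble (see [filter_conformers()]).
#' @return Tibble: `system`, `snapshot_id`, `chain`, `oxidation_state`,
#'   `delta_e` (kcal/mol).
#' @export
pair_and_delta <- function(records) {
  needed <- c("system", "snapshot_id", "chain", "oxidation_state",
              "orientation", "energy")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    abort(paste0("records lack column(s): ", paste(missing, collapse = ", ")))
  }
  if (!all(records$orientation %in% c("top-hat", "N-bound"))) {
    abort("orientation must be 'top-hat' or 'N-bound'")
  }
  dup <- records |>
    dplyr::count(.data$system, .data$snapshot_id, .data$chain,
                 .data$oxidation_state, .data$orientation) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "duplicate conformer records for key(s): ",
      paste(dup$system, dup$snapshot_id, dup$chain, dup$oxidation_state,
            dup$orientation, collapse = "; ")
    ))
  }
  wide <- records |>
    dplyr::select(dplyr::all_of(needed)) |>
    tidyr::pivot_wider(names_from = "orientation", values_from = "energy")
  if (!"top-hat" %in% names(wide)) wide$`top-hat` <- NA_real_
  if (!"N-bound" %in% names(wide)) wide$`N-bound` <- NA_real_
  unpaired <- dplyr::filter(wide, is.na(.data$`top-hat`) |
                              is.na(.data$`N-bound`))
  if (nrow(unpaired) > 0) {
    warn(paste0(
      nrow(unpaired), " unpaired conformer key(s) excluded: ",
      paste(unpaired$system, unpaired$snapshot_id, unpaired$chain,
            unpaired$oxidation_state, collapse = "; ")
    ))
  }
  out <- wide |>
    dplyr::filter(!is.na(.data$`top-hat`), !is.na(.data$`N-bound`)) |>
    dplyr::mutate(delta_e = .data$`top-hat` - .data$`N-bound`) |>
    dplyr::select("system", "snapshot_id", "chain", "oxidation_state",
                  "delta_e")
  attr(out, "unpaired") <- unpaired
  out
}

#' Summarise binding-preference statistics per group
#'
#' Averages the per-pair delta E values over (system, oxidation state),
#' reporting the pair count, mean, standard deviation (sample sd over
#' independent conformer pairs by default) and the sign interpretation:
#' positive means N-bound favoured.
#'
#' @param deltas Output of [pair_and_delta()].
#' @param sample_sd Use the n-1 (sample) standard deviation; `FALSE` for the
#'   population form.
#' @return Tibble: `system`, `oxidation_state`, `n_pairs`, `mean`, `sd`,
#'   `preference`.
#' @examples
#' tbl <- make_energy_table(seed = 1)
#' summarize_delta(pair_and_delta(tbl$records))
#' @export
summarize_delta <- function(deltas, sample_sd = TRUE) {
  if (nrow(deltas) == 0) abort("no delta E values to summarise")
  deltas |>
    dplyr::group_by(.data$system, .data$oxidation_state) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      mean = mean(.data$delta_e),
      sd = if (sample_sd) {
        if (dplyr::n() > 1) stats::sd(.data$delta_e) else 0
      } else {
        sqrt(mean((.data$delta_e - mean(.data$delta_e))^2))
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(preference = dplyr::case_when(
      .data$mean > 0 ~ "N-bound favoured",
      .data$mean < 0 ~ "top-hat favoured",
      TRUE ~ "isoenergetic"
    ))
}

#' Default conformer-count and delta-E parameters per system
#'
#' The study conditions emulated by [make_energy_table()]: three enzyme
#' variants (deprotonated Asp97 "D97", protonated "D97p", the Asn mutant
#' "D97N") with 6, 7 and 9 independent conformer pairs, in both copper
#' oxidation states, with the per-group mean and standard deviation of
#' delta E (kcal/mol) observed in the QM/MM study these conditions mirror.
#'
#' @return Tibble: `system`, `oxidation_state`, `n_pairs`, `mean`, `sd`.
#' @export
energy_parameters <- function() {
  tibble::tibble(
    system = rep(c("D97", "D97p", "D97N"), each = 2),
    oxidation_state = rep(c("CuII", "CuI"), 3),
    n_pairs = rep(c(6L, 7L, 9L), each = 2),
    mean = c(-0.27, 8.66, 0.24, 4.64, -1.22, 5.17),
    sd = c(2.96, 6.39, 2.73, 7.66, 4.29, 4.87)
  )
}

#' Generate a synthetic conformer energy table
#'
#' Draws delta E values from the per-group Gaussians of `params` and emits
#' paired top-hat / N-bound records. Each pair receives an arbitrary common
#' energy offset (absolute energies between snapshots are not comparable, and
#' the analysis must be invariant to them).
#'
#' @param params Group parameters, see [energy_parameters()].
#' @param seed Optional integer seed.
#' @param offset_range Half-width of the uniform per-pair offset, kcal/mol.
#' @return A list: `records` (the energy table), `deltas` (per-pair ground
#'   truth), `params`.
#' @export
make_energy_table <- function(params = energy_parameters(), seed = NULL,
                              offset_range = 1e6) {
  stopifnot(all(params$n_pairs >= 1))
  with_seed(seed, {
    chains <- c("A", "B", "C")
    per_group <- purrr::pmap(params, function(system, oxidation_state,
                                              n_pairs, mean, sd) {
      delta <- rnorm(n_pairs, mean, sd)
      offset <- runif(n_pairs, -offset_range, offset_range)
      key <- tibble::tibble(
        system = system,
        snapshot_id = paste0("s", ceiling(seq_len(n_pairs) / 3)),
        chain = chains[(seq_len(n_pairs) - 1) %% 3 + 1],
        oxidation_state = oxidation_state,
        delta_e = delta, offset = offset
      )
      key
    })
    truth <- dplyr::bind_rows(per_group)
    records <- truth |>
      tidyr::expand_grid(orientation = c("top-hat", "N-bound")) |>
      dplyr::mutate(
        energy = .data$offset +
          ifelse(.data$orientation == "top-hat", .data$delta_e, 0),
        flag_short_contact = FALSE
      ) |>
      dplyr::select("system", "snapshot_id", "chain", "oxidation_state",
                    "orientation", "energy", "flag_short_contact")
    list(records = records,
         deltas = dplyr::select(truth, -"offset"),
         params = params)
  })
}
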