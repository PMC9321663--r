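#' MAD-based intensity gate threshold
#'
#' The plate-based gating rule: a cell is biomarker-positive when its mean
#' intensity exceeds the control population's median plus `multiplier` times
#' its median absolute deviation (default 5*bmad).
#'
#' @param intensities Numeric vector of control-cell intensities (>= 2 finite
#'   values).
#' @param multiplier MAD multiplier (default 5).
#' @param mad_constant MAD scale constant passed to [stats::mad()]; 1.4826
#'   (scaled MAD) by default, set 1 for the raw MAD.
#' @return The threshold, `median + multiplier * mad`.
#' @export
#' @examples
#' mad_threshold(c(1, 2, 3, 4, 5), multiplier = 5, mad_constant = 1) # 3 + 5*1
mad_threshold <- function(intensities, multiplier = 5, mad_constant = 1.4826) {
  intensities <- as.numeric(intensities)
  if (length(intensities) < 2L || any(!is.finite(intensities))) {
    abort("Need at least 2 finite intensity values to set a threshold.")
  }
  median(intensities) + multiplier * mad(intensities, constant = mad_constant)
}

#' Per-plate biomarker gate thresholds from control wells
#'
#' For each plate, pools the cells of the designated baseline control wells
#' and applies [mad_threshold()] per channel. SOX17 and BRA thresholds come
#' from the non-differentiated pluripotent control population (where both
#' markers are near-absent); the SOX2 threshold comes from the
#' endoderm-differentiated control population (where SOX2 is lost). No
#' cross-plate pooling: thresholds are plate-local.
#'
#' @param cells Per-cell table (see [simulate_plate()]): needs `plate_id`,
#'   `well_id`, and intensity columns `sox17`, `sox2`, `bra`.
#' @param layout Layout table(s) covering every plate in `cells`.
#' @param multiplier MAD multiplier (default 5).
#' @param mad_constant MAD scale constant (default 1.4826).
#' @return Tibble: `plate_id`, `channel`, `baseline_role`, `median`, `mad`,
#'   `multiplier`, `threshold`.
#' @export
plate_thresholds <- function(cells, layout, multiplier = 5, mad_constant = 1.4826) {
  if (is.list(layout) && !is.data.frame(layout)) layout <- bind_rows(layout)
  cells_role <- cells |>
    inner_join(layout[c("plate_id", "well_id", "role")], by = c("plate_id", "well_id"))
  baseline <- tibble(channel = c("sox17", "bra", "sox2"),
                     baseline_role = c("pluripotent_control", "pluripotent_control",
                                       "endoderm_control"))
  out <- purrr::pmap_dfr(baseline, function(channel, baseline_role) {
    cells_role |>
      filter(.data$role == baseline_role) |>
      summarise(
        channel = channel, baseline_role = baseline_role,
        n_cells = dplyr::n(),
        median = median(.data[[channel]]),
        mad = mad(.data[[channel]], constant = mad_constant),
        .by = "plate_id"
      )
  })
  missing <- setdiff(unique(cells$plate_id), unique(out$plate_id))
  if (length(missing) || any(out$n_cells < 2L)) {
    abort("Every plate needs pluripotent and endoderm control wells with >= 2 cells.")
  }
  out |>
    mutate(multiplier = multiplier,
           threshold = .data$median + multiplier * .data$mad) |>
    select("plate_id", "channel", "baseline_role", "median", "mad",
           "multiplier", "threshold") |>
    arrange(.data$plate_id, .data$channel)
}

#' Summarize per-cell records into per-well percent responders
#'
#' Applies the plate-local gate thresholds to every cell (positive iff
#' intensity strictly exceeds the threshold; ties count negative), sums cell
#' counts over all imaging fields, and reports the percentage of responders
#' per biomarker. Wells with zero cells are emitted with `cell_count = 0` and
#' missing percentages.
#'
#' @param cells Per-cell table.
#' @param thresholds Output of [plate_thresholds()]; must cover every plate
#'   and channel present.
#' @param layout Optional layout to left-join well metadata (`role`,
#'   `chemical_id`, `conc_uM`) onto the summaries.
#' @return Tibble: `plate_id`, `well_id`, `cell_count`, `pct_sox17_pos`,
#'   `pct_sox2_pos`, `pct_bra_pos` (+ layout columns when supplied).
#' @export
summarize_wells <- function(cells, thresholds, layout = NULL) {
  thr <- thresholds |>
    select("plate_id", "channel", "threshold") |>
    tidyr::pivot_wider(names_from = "channel", values_from = "threshold",
                       names_prefix = "thr_")
  missing <- setdiff(unique(cells$plate_id), thr$plate_id)
  if (length(missing) || !all(c("thr_sox17", "thr_sox2", "thr_bra") %in% names(thr))) {
    abort("Thresholds must cover every plate and channel present in `cells`.")
  }
  out <- cells |>
    inner_join(thr, by = "plate_id") |>
    summarise(
      cell_count = dplyr::n(),
      pct_sox17_pos = 100 * mean(.data$sox17 > .data$thr_sox17),
      pct_sox2_pos = 100 * mean(.data$sox2 > .data$thr_sox2),
      pct_bra_pos = 100 * mean(.data$bra > .data$thr_bra),
      .by = c("plate_id", "well_id")
    )
  if (!is.null(layout)) {
    if (is.list(layout) && !is.data.frame(layout)) layout <- bind_rows(layout)
    out <- layout |>
      select("plate_id", "well_id", "role", "chemical_id", "conc_uM") |>
      left_join(out, by = c("plate_id", "well_id")) |>
      mutate(cell_count = dplyr::coalesce(.data$cell_count, 0L))
  }
  out |> arrange(.data$plate_id, .data$well_id)
}
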