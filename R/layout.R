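#' Default 8-point test-chemical concentration series
#'
#' Concentrations in micromolar spanning 1 pM to 200 uM, half-log spaced over
#' the top decades with sparse low anchors, mirroring a screening dilution
#' series skewed towards the upper end of the range.
#'
#' @return Numeric vector of 8 concentrations (uM), increasing.
#' @export
default_conc_series <- function() {
  c(1e-6, 1e-3, 0.2, 2, 6.32, 20, 63.2, 200)
}

well_role_levels <- c("pluripotent_control", "endoderm_control",
                      "solvent_control", "positive_control", "treatment")

#' Build a 384-well plate layout
#'
#' Lays out one assay plate: four control roles in the outer columns
#' (non-differentiated pluripotent baseline, untreated endoderm
#' differentiation, DMSO solvent, and TGF-beta receptor inhibitor positive
#' control) and treatment wells filling the interior. Treatment wells carry a
#' chemical identifier and a test concentration in micromolar.
#'
#' @param plate_id Plate identifier.
#' @param treatments Data frame with columns `chemical_id` and `conc_uM`, one
#'   row per treatment well, or `NULL` for a control-only plate.
#' @param n_control Wells per control role (default 12, the technical
#'   replicate count used for plate QC).
#'
#' @return A tibble with columns `plate_id`, `well_id`, `row`, `col`, `role`,
#'   `chemical_id`, `conc_uM`.
#' @export
#' @examples
#' trt <- tidyr::crossing(chemical_id = c("chemA", "chemB"),
#'                        conc_uM = default_conc_series())
#' layout <- plate_layout("P01", treatments = trt)
#' dplyr::count(layout, role)
plate_layout <- function(plate_id = "P01", treatments = NULL, n_control = 12L) {
  n_control <- as.integer(n_control)
  if (n_control < 2L) abort("Each control role needs at least 2 wells.")
  rows <- LETTERS[1:16]
  grid <- tidyr::crossing(row = rows, col = 1:24) |>
    mutate(well_id = sprintf("%s%02d", .data$row, .data$col))

  control_cols <- c(pluripotent_control = 1L, endoderm_control = 2L,
                    solvent_control = 23L, positive_control = 24L)
  controls <- purrr::imap_dfr(control_cols, function(col, role) {
    tibble(row = rows[seq_len(n_control)], col = col, role = role)
  })

  interior <- grid |>
    filter(!.data$col %in% control_cols) |>
    arrange(.data$row, .data$col)

  if (!is.null(treatments)) {
    treatments <- as_tibble(treatments)
    stopifnot(all(c("chemical_id", "conc_uM") %in% names(treatments)))
    if (any(treatments$conc_uM <= 0)) abort("Concentrations must be strictly positive.")
    if (nrow(treatments) > nrow(interior)) {
      abort(sprintf("Too many treatment wells (%d) for one plate (capacity %d).",
                    nrow(treatments), nrow(interior)))
    }
    trt_wells <- interior[seq_len(nrow(treatments)), ] |>
      mutate(role = "treatment",
             chemical_id = treatments$chemical_id,
             conc_uM = treatments$conc_uM)
  } else {
    trt_wells <- interior[0, ] |> mutate(role = character(), chemical_id = character(),
                                         conc_uM = numeric())
  }

  controls_full <- controls |>
    left_join(grid, by = c("row", "col")) |>
    mutate(chemical_id = NA_character_, conc_uM = NA_real_)

  out <- bind_rows(controls_full, trt_wells) |>
    mutate(plate_id = plate_id, .before = 1) |>
    select("plate_id", "well_id", "row", "col", "role", "chemical_id", "conc_uM") |>
    arrange(.data$row, .data$col)
  validate_plate_layout(out)
  out
}

#' Validate a plate layout table
#'
#' Checks the structural invariants a layout must satisfy before simulation
#' or gating: one role per well, no duplicated wells, at least two wells per
#' control role present, and strictly positive treatment concentrations.
#'
#' @param layout Layout tibble (see [plate_layout()]).
#' @return The layout, invisibly; errors if invalid.
#' @export
validate_plate_layout <- function(layout) {
  req <- c("plate_id", "well_id", "role", "chemical_id", "conc_uM")
  missing_cols <- setdiff(req, names(layout))
  if (length(missing_cols)) {
    abort(paste("Layout is missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(layout) == 0L) abort("Layout is empty.")
  if (anyDuplicated(layout[c("plate_id", "well_id")])) {
    abort("Each well may appear only once per plate.")
  }
  if (!all(layout$role %in% well_role_levels)) {
    abort(paste("Unknown well role(s):",
                paste(setdiff(unique(layout$role), well_role_levels), collapse = ", ")))
  }
  ctrl <- layout |> filter(.data$role != "treatment") |> count(.data$plate_id, .data$role)
  if (nrow(ctrl) && any(ctrl$n < 2L)) {
    abort("Every control role present must have at least 2 wells per plate.")
  }
  trt <- layout |> filter(.data$role == "treatment")
  if (nrow(trt) && (any(is.na(trt$conc_uM)) || any(trt$conc_uM <= 0))) {
    abort("Treatment wells must carry strictly positive concentrations.")
  }
  invisible(layout)
}
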