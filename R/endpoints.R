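#' Packaged assay endpoint catalogue
#'
#' The six endpoints of the endoderm screen: SOX17 percent responders, SOX2
#' and BRA percent responders, and total cell count, each in an up and/or
#' down direction. SOX17 and cell-count endpoints are normalized as percent
#' change from the plate solvent-control median; the loss-direction series
#' (`*_dn`) are additionally sign-inverted so that decreases score as
#' positive activity and can be fit by gain-type curves. SOX2 and BRA
#' endpoints are left on the raw percent-responder scale (minimal change
#' under endoderm induction).
#'
#' @return Tibble: `endpoint_id`, `endpoint_name`, `source_measure`,
#'   `direction`, `invert`, `normalization`, `interpretation`.
#' @export
devtox_endpoints <- function() {
  tibble(
    endpoint_id = 3093:3098,
    endpoint_name = paste0("CCTE_Deisenroth_DEVTOX_RUES2-GLR_Endo_",
                           c("Sox17_up", "Sox17_dn", "Sox2_up", "Bra_up",
                             "CellCount_up", "CellCount_dn")),
    source_measure = c("pct_sox17_pos", "pct_sox17_pos", "pct_sox2_pos",
                       "pct_bra_pos", "cell_count", "cell_count"),
    direction = c("up", "dn", "up", "up", "up", "dn"),
    invert = c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE),
    normalization = c("percent_of_solvent", "percent_of_solvent", "raw", "raw",
                      "percent_of_solvent", "percent_of_solvent"),
    interpretation = c("SOX17 positive", "SOX17 negative", "SOX2 positive",
                       "BRA positive", "Cell count positive", "Cell count negative")
  )
}

#' Normalize a raw well value against the plate solvent baseline
#'
#' Percent activity relative to the plate's DMSO solvent-control median:
#' `resp = 100 * (rval - bval) / bval`, multiplied by -1 when `invert` so
#' that losses read as positive activity.
#'
#' @param rval Raw well-level value(s) (percent responders or cell count).
#' @param bval Plate solvent-control median, same units; must be > 0.
#' @param invert Sign-invert the response (loss-direction endpoints).
#' @return Normalized response(s) in percent.
#' @export
#' @examples
#' normalize_response(40, 50, invert = TRUE) # +20
#' normalize_response(75, 50)                # +50
normalize_response <- function(rval, bval, invert = FALSE) {
  if (any(!is.finite(bval)) || any(bval <= 0)) {
    abort("Degenerate solvent baseline: `bval` must be finite and > 0.")
  }
  resp <- 100 * (rval - bval) / bval
  if (invert) -resp else resp
}

#' Baseline MAD and efficacy cutoff from solvent-control responses
#'
#' The efficacy cutoff of the screen: `bmad` is the median absolute deviation
#' of the normalized solvent-control responses pooled across plates for one
#' endpoint, and `coff = 3 * bmad` is the minimum response magnitude for a
#' hit.
#'
#' @param solvent_resps Normalized responses at solvent-control wells (>= 4).
#' @param mad_constant MAD scale constant (default 1.4826; use 1 for raw MAD).
#' @return Named list `bmad`, `coff`.
#' @export
#' @examples
#' baseline_cutoff(c(-2, -1, 0, 1, 2), mad_constant = 1) # bmad 1, coff 3
baseline_cutoff <- function(solvent_resps, mad_constant = 1.4826) {
  solvent_resps <- solvent_resps[is.finite(solvent_resps)]
  if (length(solvent_resps) < 4L) {
    abort("Need at least 4 solvent-control responses to set a cutoff.")
  }
  bmad <- mad(solvent_resps, constant = mad_constant)
  list(bmad = bmad, coff = 3 * bmad)
}

#' Normalize well summaries for one endpoint
#'
#' Computes per-plate solvent baselines (`bval` = median of solvent-control
#' wells' raw values) and the normalized response for every well on the
#' endpoint's scale. `raw`-normalization endpoints pass the raw value
#' through unchanged.
#'
#' @param wells Well summaries with layout metadata (see
#'   [summarize_wells()] with `layout`).
#' @param endpoint One row of [devtox_endpoints()] (or a compatible list with
#'   `source_measure`, `invert`, `normalization`).
#' @return `wells` plus columns `rval`, `bval`, `resp`.
#' @export
normalize_wells <- function(wells, endpoint) {
  measure <- endpoint$source_measure
  if (!measure %in% names(wells)) abort(paste("Missing measure column:", measure))
  wells <- wells |> mutate(rval = as.numeric(.data[[measure]]))
  bvals <- wells |>
    filter(.data$role == "solvent_control") |>
    summarise(bval = median(.data$rval, na.rm = TRUE), .by = "plate_id")
  if (!all(unique(wells$plate_id) %in% bvals$plate_id)) {
    abort("Every plate needs at least one solvent-control well.")
  }
  wells |>
    left_join(bvals, by = "plate_id") |>
    mutate(resp = if (identical(endpoint$normalization, "raw")) {
      if (endpoint$invert) -.data$rval else .data$rval
    } else {
      normalize_response(.data$rval, .data$bval, invert = endpoint$invert)
    })
}
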