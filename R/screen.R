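#' Normalize, fit and hit-call one endpoint across a screen
#'
#' The full concentration-response stage for one endpoint: per-plate solvent
#' baselines and normalized responses ([normalize_wells()]), the pooled
#' efficacy cutoff from solvent-control responses across plates
#' ([baseline_cutoff()]), then per chemical a three-model fit
#' ([fit_conc_resp()]) and hit call ([call_hit()]).
#'
#' @param wells Well summaries with layout metadata (role, chemical_id,
#'   conc_uM), e.g. `summarize_wells(cells, thr, layout)`.
#' @param endpoint One row of [devtox_endpoints()].
#' @param mad_constant MAD scale constant for the cutoff (default 1.4826).
#' @param error_model Error model for the fits (`"t4"` or `"gaussian"`).
#' @return List: `endpoint` (the definition), `bmad`, `coff`, `results`
#'   (tibble with one row per chemical: hit columns plus a `fit` list-column)
#'   and `series` (the normalized well table).
#' @export
#' @examples
#' \donttest{
#' trt <- tidyr::crossing(chemical_id = "toxA", conc_uM = default_conc_series())
#' trt <- dplyr::bind_rows(replicate(4, trt, simplify = FALSE))
#' layout <- plate_layout("P01", trt)
#' eff <- chemical_effect("toxA", "positive", sox17_top = 0.8, sox17_log10_ac50 = 0.5)
#' cfg <- sim_config(seed = 3, cells_per_well_mean = 400)
#' cells <- simulate_plate(layout, eff, cfg)
#' wells <- summarize_wells(cells, plate_thresholds(cells, layout), layout)
#' ep <- dplyr::filter(devtox_endpoints(), endpoint_name ==
#'   "CCTE_Deisenroth_DEVTOX_RUES2-GLR_Endo_Sox17_dn")
#' res <- screen_concresp(wells, ep)
#' res$results[c("chemical_id", "hitc", "ac50_uM")]
#' }
screen_concresp <- function(wells, endpoint, mad_constant = 1.4826,
                            error_model = "t4") {
  norm <- normalize_wells(wells, endpoint)
  solvent <- norm |> filter(.data$role == "solvent_control")
  cut <- baseline_cutoff(solvent$resp, mad_constant = mad_constant)
  trt <- norm |>
    filter(.data$role == "treatment", !is.na(.data$resp))
  results <- trt |>
    tidyr::nest(series = -"chemical_id") |>
    mutate(fit = purrr::map(.data$series, ~ fit_conc_resp(.x$conc_uM, .x$resp,
                                                          error_model = error_model)),
           hit = purrr::map(.data$fit, call_hit, coff = cut$coff)) |>
    tidyr::unnest("hit") |>
    select(-"series")
  list(endpoint = endpoint, bmad = cut$bmad, coff = cut$coff,
       results = results, series = norm)
}

#' Simulate, gate and fit one chemical end-to-end
#'
#' Convenience wrapper used for calibration and parameter-recovery checks:
#' builds a single plate carrying one chemical across the concentration
#' series with replicate wells plus the four control roles, simulates the
#' per-cell data, gates it, and runs the concentration-response stage for a
#' chosen endpoint.
#'
#' @param effect One-row effect table from [chemical_effect()].
#' @param config A [sim_config()].
#' @param conc_uM Concentration series (default [default_conc_series()]).
#' @param n_rep Replicate wells per concentration (default 4).
#' @param endpoint_name Short endpoint selector: `"sox17_dn"` (default) or
#'   `"cellcount_dn"`.
#' @param n_control Control wells per role (default 12).
#' @return The [screen_concresp()] result list, plus `wells`.
#' @export
run_chemical_screen <- function(effect, config = sim_config(),
                                conc_uM = default_conc_series(), n_rep = 4L,
                                endpoint_name = c("sox17_dn", "cellcount_dn"),
                                n_control = 12L) {
  endpoint_name <- match.arg(endpoint_name)
  ep_suffix <- c(sox17_dn = "Sox17_dn", cellcount_dn = "CellCount_dn")[[endpoint_name]]
  endpoint <- devtox_endpoints() |>
    filter(grepl(ep_suffix, .data$endpoint_name, fixed = TRUE))
  trt <- tidyr::crossing(rep = seq_len(n_rep), conc_uM = conc_uM) |>
    mutate(chemical_id = effect$chemical_id) |>
    select("chemical_id", "conc_uM")
  layout <- plate_layout("P01", treatments = trt, n_control = n_control)
  cells <- simulate_plate(layout, effect, config)
  thr <- plate_thresholds(cells, layout)
  wells <- summarize_wells(cells, thr, layout)
  out <- screen_concresp(wells, endpoint)
  out$wells <- wells
  out
}
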