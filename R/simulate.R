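# Latent per-well biomarker-positive probabilities by role.
role_fractions <- function(layout, effects, config) {
  base_solvent <- config$baseline_sox17_frac * (1 - config$solvent_sox17_suppression)
  out <- layout |>
    mutate(
      p_sox17 = dplyr::case_match(
        .data$role,
        "pluripotent_control" ~ config$pluripotent_sox17_frac,
        "endoderm_control"    ~ config$baseline_sox17_frac,
        "solvent_control"     ~ base_solvent,
        "positive_control"    ~ config$sb431542_sox17_frac,
        "treatment"           ~ base_solvent
      ),
      p_sox2 = dplyr::case_match(
        .data$role,
        "pluripotent_control" ~ config$pluripotent_sox2_frac,
        .default = config$endoderm_sox2_frac
      ),
      p_bra = config$baseline_bra_frac,
      count_scale = 1
    )
  trt <- which(out$role == "treatment")
  if (length(trt)) {
    eff <- out[trt, c("chemical_id", "conc_uM")] |>
      left_join(effects, by = "chemical_id")
    if (anyNA(eff$sox17_top)) {
      missing <- unique(eff$chemical_id[is.na(eff$sox17_top)])
      abort(paste("No effect specification for chemical(s):",
                  paste(missing, collapse = ", ")))
    }
    x <- log10(eff$conc_uM)
    out$p_sox17[trt] <- out$p_sox17[trt] *
      (1 - eff$sox17_top * hill_occupancy(x, eff$sox17_log10_ac50, eff$hill_coeff))
    out$count_scale[trt] <- 1 - eff$cytotox_top *
      hill_occupancy(x, eff$cytotox_log10_ac50, eff$cytotox_hill)
  }
  out
}

# Logit-normal per-well jitter of a probability, clamped away from {0, 1}.
jitter_prob <- function(p, sd) {
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  plogis(qlogis(p) + rnorm(length(p), 0, sd))
}

#' Simulate per-cell biomarker intensity records for one plate
#'
#' Generates the table a high-content imager's object-level export would
#' contain: one row per segmented cell with mean fluorescence intensity in
#' the SOX17, SOX2 and BRA reporter channels, plus plate/well/field
#' coordinates. Cell counts are negative-binomial with the expected count
#' scaled by each chemical's cytotoxicity Hill term; each cell's latent
#' biomarker-positive state is Bernoulli with a role- and effect-adjusted,
#' per-well jittered probability; intensities come from the state's lognormal
#' component. The same layout, effect table and seed always reproduce the
#' identical table.
#'
#' @param layout Plate layout from [plate_layout()].
#' @param effects Effect table (rows from [chemical_effect()]); may be `NULL`
#'   for control-only layouts.
#' @param config A [sim_config()]; `config$seed` drives all randomness.
#'
#' @return Tibble with one row per cell: `plate_id`, `well_id`, `field`,
#'   `cell_id`, intensity columns `sox17`, `sox2`, `bra`, `nuc`, and latent
#'   state columns `sox17_state`, `sox2_state`, `bra_state` (logical; kept so
#'   gating can be checked against the generator's truth).
#' @export
#' @examples
#' layout <- plate_layout("P01", n_control = 4)
#' cells <- simulate_plate(layout, config = sim_config(seed = 1, cells_per_well_mean = 50))
#' dplyr::count(cells, well_id)[1:3, ]
simulate_plate <- function(layout, effects = NULL, config = sim_config()) {
  validate_plate_layout(layout)
  if (is.null(effects)) effects <- chemical_effect("none")[0, ]
  withr::with_seed(config$seed, simulate_plate_impl(layout, effects, config))
}

simulate_plate_impl <- function(layout, effects, config) {
  wells <- role_fractions(layout, effects, config)
  n_w <- nrow(wells)
  wells$n_cells <- rnbinom(n_w, size = config$cells_per_well_dispersion,
                           mu = config$cells_per_well_mean * wells$count_scale)
  # per-well biological variability in differentiation efficiency
  wells$p_sox17 <- jitter_prob(wells$p_sox17, config$well_effect_sd)
  wells$p_sox2  <- jitter_prob(wells$p_sox2, config$well_effect_sd)
  wells$p_bra   <- jitter_prob(wells$p_bra, config$well_effect_sd)

  idx <- rep.int(seq_len(n_w), wells$n_cells)
  n_cells <- length(idx)
  cell_id <- sequence(wells$n_cells)
  field <- ((cell_id - 1L) %% config$fields_per_well) + 1L

  draw_channel <- function(p) {
    state <- rbinom(n_cells, 1L, p[idx]) == 1L
    ml <- ifelse(state, config$intensity_meanlog[["pos"]], config$intensity_meanlog[["neg"]])
    sl <- ifelse(state, config$intensity_sdlog[["pos"]], config$intensity_sdlog[["neg"]])
    list(state = state, intensity = rlnorm(n_cells, ml, sl))
  }
  s17 <- draw_channel(wells$p_sox17)
  s2 <- draw_channel(wells$p_sox2)
  br <- draw_channel(wells$p_bra)
  nuc <- rlnorm(n_cells, config$intensity_meanlog[["pos"]], config$intensity_sdlog[["pos"]])

  tibble(
    plate_id = wells$plate_id[idx],
    well_id = wells$well_id[idx],
    field = field,
    cell_id = cell_id,
    sox17 = s17$intensity, sox2 = s2$intensity, bra = br$intensity, nuc = nuc,
    sox17_state = s17$state, sox2_state = s2$state, bra_state = br$state
  )
}

#' Simulate a multi-plate screen
#'
#' Runs [simulate_plate()] over a list of layouts, advancing the seed by one
#' per plate so plates are independent but the whole screen remains
#' reproducible from `config$seed`.
#'
#' @param layouts List of plate layouts (or a single layout tibble).
#' @param effects Effect table shared across plates.
#' @param config A [sim_config()].
#' @return Tibble of per-cell records across all plates.
#' @export
simulate_screen <- function(layouts, effects = NULL, config = sim_config()) {
  if (is.data.frame(layouts)) layouts <- list(layouts)
  purrr::imap_dfr(layouts, function(lay, i) {
    cfg <- config
    cfg$seed <- config$seed + as.integer(i) - 1L
    simulate_plate(lay, effects, cfg)
  })
}
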