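#' Define a chemical's simulated concentration-response effect
#'
#' Parameterizes how a test chemical perturbs the screen: a Hill-shaped
#' suppression of the SOX17-positive probability (the developmental-toxicity
#' signal) and an independent Hill-shaped reduction of the expected cell
#' count (cytotoxicity). Tops are fractional (0 = no effect, 1 = complete
#' loss at saturating concentration); midpoints are log10 micromolar.
#'
#' @param chemical_id Chemical identifier.
#' @param truth_class `"positive"` or `"negative"` developmental-toxicant
#'   class, carried through to benchmarking.
#' @param sox17_top Maximum fractional suppression of the SOX17-positive
#'   probability, in `[0, 1]`.
#' @param sox17_log10_ac50 log10 uM midpoint of the SOX17 effect.
#' @param hill_coeff Hill coefficient of the SOX17 effect (> 0).
#' @param cytotox_top,cytotox_log10_ac50,cytotox_hill Analogous parameters
#'   acting on the expected cell count.
#'
#' @return One-row tibble; bind rows to build an effect table.
#' @export
#' @examples
#' effects <- dplyr::bind_rows(
#'   chemical_effect("toxA", "positive", sox17_top = 0.8, sox17_log10_ac50 = 0),
#'   chemical_effect("inert", "negative")
#' )
chemical_effect <- function(chemical_id,
                            truth_class = c("positive", "negative"),
                            sox17_top = 0, sox17_log10_ac50 = 0, hill_coeff = 1,
                            cytotox_top = 0, cytotox_log10_ac50 = 1, cytotox_hill = 1) {
  truth_class <- match.arg(truth_class)
  if (sox17_top < 0 || sox17_top > 1 || cytotox_top < 0 || cytotox_top > 1) {
    abort("Effect tops must lie in [0, 1].")
  }
  if (hill_coeff <= 0 || cytotox_hill <= 0) {
    abort("Hill coefficients must be positive.")
  }
  tibble(chemical_id = chemical_id, truth_class = truth_class,
         sox17_top = sox17_top, sox17_log10_ac50 = sox17_log10_ac50,
         hill_coeff = hill_coeff,
         cytotox_top = cytotox_top, cytotox_log10_ac50 = cytotox_log10_ac50,
         cytotox_hill = cytotox_hill)
}

# Fractional Hill occupancy at log10 concentration x: 0 at -Inf, 1 at +Inf.
hill_occupancy <- function(x, log10_ac50, hill) {
  1 / (1 + 10^((log10_ac50 - x) * hill))
}

#' Expected latent well fractions and count scaling under a chemical effect
#'
#' The deterministic core of the simulator: for a given effect specification
#' and concentration, returns the expected SOX17-positive probability
#' (relative to the solvent-suppressed baseline) and the multiplicative cell
#' count scale. Useful as an oracle when testing monotonicity and recovery.
#'
#' @param effect One-row effect table from [chemical_effect()].
#' @param conc_uM Concentration(s) in uM, strictly positive.
#' @param config A [sim_config()].
#' @return Tibble with `conc_uM`, `sox17_frac`, `count_scale`.
#' @export
effect_expectation <- function(effect, conc_uM, config = sim_config()) {
  stopifnot(all(conc_uM > 0))
  x <- log10(conc_uM)
  base <- config$baseline_sox17_frac * (1 - config$solvent_sox17_suppression)
  tibble(
    conc_uM = conc_uM,
    sox17_frac = base * (1 - effect$sox17_top *
                           hill_occupancy(x, effect$sox17_log10_ac50, effect$hill_coeff)),
    count_scale = 1 - effect$cytotox_top *
      hill_occupancy(x, effect$cytotox_log10_ac50, effect$cytotox_hill)
  )
}
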