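#' Closed-form activity concentration at cutoff for a Hill curve
#'
#' The lowest concentration at which the fitted Hill curve crosses the
#' efficacy cutoff: `acc = 10^(ga - log10(tp / coff - 1) / gw)`. Undefined
#' (NA) when the top never reaches the cutoff.
#'
#' @param tp,ga,gw Hill parameters (top %, log10 uM midpoint, coefficient).
#' @param coff Efficacy cutoff (%).
#' @return ACC in uM, or `NA` when `tp <= coff`.
#' @export
#' @examples
#' hill_acc(tp = 100, ga = 0, gw = 1, coff = 50)   # 1 uM (= AC50)
#' hill_acc(tp = 100, ga = 0, gw = 1, coff = 20.3) # ~0.255 uM
hill_acc <- function(tp, ga, gw, coff) {
  ifelse(tp > coff, 10^(ga - log10(tp / coff - 1) / gw), NA_real_)
}

#' Numeric activity concentration at cutoff for any fitted curve
#'
#' Finds the lowest concentration where `fun(x)` (x in log10 uM) first
#' crosses `coff` from below, by scanning a fine grid for the first sign
#' change and polishing it with [stats::uniroot()]. Works for the
#' non-monotone gain-loss model, where the analytic inversion has no closed
#' form.
#'
#' @param fun Function of log10 concentration returning the model response.
#' @param coff Efficacy cutoff (%).
#' @param lower,upper Search range in log10 uM.
#' @param n_grid Grid resolution.
#' @return ACC in uM, or `NA` when the curve never reaches the cutoff.
#' @export
numeric_acc <- function(fun, coff, lower, upper, n_grid = 2000L) {
  xs <- seq(lower, upper, length.out = n_grid)
  ys <- fun(xs) - coff
  cross <- which(ys[-1] >= 0 & ys[-length(ys)] < 0)
  if (!length(cross)) {
    if (ys[1] >= 0) return(10^xs[1])  # already above cutoff at range start
    return(NA_real_)
  }
  i <- cross[1]
  root <- uniroot(function(x) fun(x) - coff, c(xs[i], xs[i + 1]), tol = 1e-12)
  10^root$root
}

#' Stratify a maximum-inhibition value into effect bands
#'
#' Classifies the maximal observed effect (% max inhibition) into the three
#' response bands used to interpret hit quality: weak `[0, 20)`, moderate
#' `[20, 80)`, high `[80, 100]`. Band boundaries are half-open at the lower
#' edge, so 20 is moderate and 80 is high.
#'
#' @param pct_max_inhibition Value(s) in `[0, 100]`.
#' @return Character vector: `"weak"`, `"moderate"` or `"high"`.
#' @export
#' @examples
#' effect_band(c(0, 20, 79.9, 93))
effect_band <- function(pct_max_inhibition) {
  x <- pct_max_inhibition
  if (any(!is.finite(x)) || any(x < 0 | x > 100)) {
    abort("`pct_max_inhibition` must lie in [0, 100].")
  }
  dplyr::case_when(x >= 80 ~ "high", x >= 20 ~ "moderate", TRUE ~ "weak")
}

#' Call a hit from a fitted series and the efficacy cutoff
#'
#' Applies the hit rule: a series is active (`hitc = 1`) when the maximum
#' per-concentration median response meets or exceeds the cutoff *and* the
#' AIC winner is not the constant model (pure-noise exceedances with a
#' constant winner do not hit). For active series the potencies are derived
#' from the winning curve: `ac50 = 10^ga`, and `acc` is the lowest
#' concentration where the curve crosses the cutoff (closed form for Hill,
#' numeric root for gain-loss). When the fitted top never reaches the cutoff
#' the hit is retained with `acc` absent and a flag.
#'
#' @param fit A [fit_conc_resp()] result.
#' @param coff Efficacy cutoff (%).
#' @return One-row tibble: `hitc`, `acc_uM`, `ac50_uM`,
#'   `pct_max_inhibition` (the max median response), `effect_band`,
#'   `winner`, `flag_borderline` (|max_med - coff| < 0.1 * coff),
#'   `flag_no_acc` (top below cutoff), `flag_acc_extrapolated` (ACC below
#'   the lowest tested concentration).
#' @export
call_hit <- function(fit, coff) {
  stopifnot(inherits(fit, "devtox_fit"), is.finite(coff), coff >= 0)
  med <- fit$data |>
    summarise(med = median(.data$resp), .by = "conc_uM")
  max_med <- max(med$med)
  winner <- fit$winner
  hitc <- as.integer(max_med >= coff && winner != "constant")

  acc <- ac50 <- NA_real_
  flag_no_acc <- FALSE
  if (hitc == 1L) {
    par <- unlist(fit$fits$params[fit$fits$model == winner][[1]])
    ac50 <- 10^par[["ga"]]
    if (winner == "hill") {
      acc <- hill_acc(par[["tp"]], par[["ga"]], par[["gw"]], coff)
    } else {
      rng <- range(fit$data$logc)
      acc <- numeric_acc(function(x) model_mu[[winner]](x, par[model_par_names[[winner]]]),
                         coff, lower = rng[1] - 3, upper = rng[2] + 1)
    }
    flag_no_acc <- is.na(acc)
  }
  band_val <- min(max(max_med, 0), 100)
  tibble(
    hitc = hitc,
    acc_uM = acc,
    ac50_uM = ac50,
    pct_max_inhibition = max_med,
    effect_band = effect_band(band_val),
    winner = winner,
    flag_borderline = coff > 0 && abs(max_med - coff) < 0.1 * coff,
    flag_no_acc = flag_no_acc,
    flag_acc_extrapolated = !is.na(acc) && acc < min(fit$data$conc_uM)
  )
}

#' Combine the SOX17 and cell-count hit calls for one chemical
#'
#' The sensitivity-raising combined rule: a chemical is called a potential
#' developmental toxicant when it reduces the SOX17-positive population *or*
#' reduces the cell count (either loss-endpoint hit).
#'
#' @param sox17_hit,cellcount_hit Hit results (rows from [call_hit()]) or
#'   their `hitc` values (0/1 or logical).
#' @return Logical: positive combined call.
#' @export
#' @examples
#' combined_call(0, 1) # TRUE
#' combined_call(0, 0) # FALSE
combined_call <- function(sox17_hit, cellcount_hit) {
  get_hitc <- function(h) {
    if (is.data.frame(h)) h <- h$hitc
    as.integer(h)
  }
  get_hitc(sox17_hit) == 1L | get_hitc(cellcount_hit) == 1L
}
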