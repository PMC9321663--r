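#' Concentration-response model curves
#'
#' The three candidate models fit to each normalized series, with
#' `x = log10(concentration uM)`: the constant model `f(x) = 0`, the Hill
#' gain model `f(x) = tp / (1 + 10^((ga - x) * gw))`, and the gain-loss model
#' `f(x) = tp * (1 + 10^((ga - x) * gw))^-1 * (1 + 10^((x - la) * lw))^-1`
#' which lets the response fall off again at high concentration (e.g. when
#' cytotoxicity erodes the signal).
#'
#' @param x log10 concentration (uM).
#' @param tp Top (maximal response, %).
#' @param ga log10 AC50 of the gain phase (log10 uM).
#' @param gw Hill coefficient of the gain phase (> 0).
#' @param la,lw log10 midpoint and coefficient of the loss phase (> 0).
#' @return Model response(s), same units as the fitted data.
#' @name curve_models
NULL

#' @rdname curve_models
#' @export
hill_curve <- function(x, tp, ga, gw) {
  tp / (1 + 10^((ga - x) * gw))
}

#' @rdname curve_models
#' @export
gainloss_curve <- function(x, tp, ga, gw, la, lw) {
  tp / ((1 + 10^((ga - x) * gw)) * (1 + 10^((x - la) * lw)))
}

# Negative log-likelihood under the configured error model; the last
# parameter is log(sigma).
make_nll <- function(x, y, mu_fn, error_model) {
  force(x); force(y)
  function(par) {
    sigma <- exp(par[length(par)])
    mu <- mu_fn(x, par[-length(par)])
    r <- (y - mu) / sigma
    ll <- if (error_model == "t4") {
      sum(dt(r, df = 4, log = TRUE)) - length(y) * log(sigma)
    } else {
      sum(dnorm(r, log = TRUE)) - length(y) * log(sigma)
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }
}

model_mu <- list(
  constant = function(x, par) rep(0, length(x)),
  hill = function(x, par) hill_curve(x, par[1], par[2], par[3]),
  gainloss = function(x, par) gainloss_curve(x, par[1], par[2], par[3], par[4], par[5])
)

model_par_names <- list(
  constant = character(),
  hill = c("tp", "ga", "gw"),
  gainloss = c("tp", "ga", "gw", "la", "lw")
)

# Deterministic multi-start bounds/starts per model.
model_setup <- function(model, x, y) {
  tp_hi <- max(1.2 * max(abs(y)), 1e-3)
  tp0 <- min(max(max(y), 1e-4), tp_hi)
  ga_rng <- c(min(x) - 1, max(x) + 1)
  ga0 <- as.numeric(stats::quantile(x, c(0.25, 0.5, 0.75)))
  sig0 <- log(max(stats::sd(y), 1e-3))
  sig_b <- log(c(1e-4, 1e4))
  switch(model,
    constant = list(
      starts = list(sig0),
      lower = sig_b[1], upper = sig_b[2]
    ),
    hill = list(
      starts = purrr::map(ga0, ~ c(tp0, .x, 1.2, sig0)),
      lower = c(0, ga_rng[1], 0.3, sig_b[1]),
      upper = c(tp_hi, ga_rng[2], 8, sig_b[2])
    ),
    gainloss = list(
      starts = purrr::map(ga0, ~ c(tp0, .x, 1.2, max(x) + 0.5, 1.2, sig0)),
      lower = c(0, ga_rng[1], 0.3, ga_rng[1], 0.3, sig_b[1]),
      upper = c(tp_hi, ga_rng[2], 8, max(x) + 2, 8, sig_b[2])
    )
  )
}

fit_one_model <- function(model, x, y, error_model) {
  setup <- model_setup(model, x, y)
  nll <- make_nll(x, y, model_mu[[model]], error_model)
  best <- NULL
  for (start in setup$starts) {
    res <- tryCatch(
      optim(start, nll, method = "L-BFGS-B",
            lower = setup$lower, upper = setup$upper,
            control = list(maxit = 1000, factr = 1e4)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    return(tibble(model = model, params = list(NULL), loglik = NA_real_,
                  n_par = NA_integer_, aic = Inf, converged = FALSE))
  }
  npar <- length(best$par)
  params <- setNames(as.list(best$par[-npar]), model_par_names[[model]])
  params$sigma <- exp(best$par[npar])
  tibble(model = model, params = list(params), loglik = -best$value,
         n_par = npar, aic = 2 * npar + 2 * best$value,
         converged = best$convergence == 0)
}

#' Fit the constant, Hill and gain-loss models to one series
#'
#' Maximum-likelihood fits of the three candidate curves to a normalized
#' concentration-response series, under a Student-t error model with 4
#' degrees of freedom (robust to outlying wells; a Gaussian model is
#' selectable). Each model is optimized from three deterministic starts with
#' box constraints (top in `[0, 1.2 * max|resp|]`, gain midpoint within the
#' tested log-concentration range +/- 1, Hill coefficients in `(0.3, 8]`).
#' The winner is the converged model with minimal AIC; ties go to the
#' simpler model.
#'
#' @param conc_uM Concentrations in uM (>= 4 distinct values across points).
#' @param resp Normalized responses, same length (replicates share a
#'   concentration).
#' @param error_model `"t4"` (default) or `"gaussian"`.
#' @return Object of class `devtox_fit`: list with `data` (tibble `conc_uM`,
#'   `logc`, `resp`), `fits` (per-model tibble with `params` list-column,
#'   `loglik`, `aic`, `converged`, `winner`), `winner`, `error_model`.
#' @export
#' @examples
#' conc <- default_conc_series()
#' resp <- hill_curve(log10(conc), tp = 80, ga = 0, gw = 1.2)
#' fit <- fit_conc_resp(conc, resp)
#' fit$winner
fit_conc_resp <- function(conc_uM, resp, error_model = c("t4", "gaussian")) {
  error_model <- match.arg(error_model)
  keep <- is.finite(conc_uM) & is.finite(resp)
  conc_uM <- conc_uM[keep]; resp <- resp[keep]
  if (length(unique(conc_uM)) < 4L) {
    abort("Need at least 4 distinct concentrations to fit a series.")
  }
  if (any(conc_uM <= 0)) abort("Concentrations must be positive.")
  x <- log10(conc_uM)
  fits <- purrr::map_dfr(c("constant", "hill", "gainloss"),
                         fit_one_model, x = x, y = resp, error_model = error_model)
  ok <- fits$converged & is.finite(fits$aic)
  if (!any(ok)) abort("All candidate models failed to converge; series unfit.")
  # ties favour the simpler model (fits are ordered simple -> complex)
  winner_idx <- which(ok)[which.min(fits$aic[ok])]
  fits$winner <- seq_len(nrow(fits)) == winner_idx
  structure(list(
    data = tibble(conc_uM = conc_uM, logc = x, resp = resp),
    fits = fits,
    winner = fits$model[winner_idx],
    error_model = error_model
  ), class = "devtox_fit")
}

#' @export
print.devtox_fit <- function(x, ...) {
  cat("<devtox_fit>", nrow(x$data), "points,",
      length(unique(x$data$conc_uM)), "concentrations; winner:", x$winner, "\n")
  print(x$fits[c("model", "loglik", "aic", "converged", "winner")])
  invisible(x)
}

#' Predict the winning (or a chosen) model curve
#'
#' @param object A `devtox_fit`.
#' @param conc_uM Concentrations (uM) at which to evaluate.
#' @param model Model name; default the AIC winner.
#' @param ... Unused.
#' @return Numeric vector of model responses.
#' @export
predict.devtox_fit <- function(object, conc_uM = object$data$conc_uM,
                               model = object$winner, ...) {
  row <- object$fits[object$fits$model == model, ]
  if (!nrow(row) || !row$converged) abort(paste("No converged fit for model", model))
  par <- unlist(row$params[[1]])
  model_mu[[model]](log10(conc_uM), par[model_par_names[[model]]])
}
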