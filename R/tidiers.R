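#' Tidy a concentration-response fit
#'
#' One row per fitted parameter per candidate model, broom-style.
#'
#' @param x A `devtox_fit`.
#' @param ... Unused.
#' @return Tibble: `model`, `term`, `estimate`, `winner`.
#' @export
tidy.devtox_fit <- function(x, ...) {
  purrr::pmap_dfr(x$fits[c("model", "params", "winner")],
                  function(model, params, winner) {
                    if (is.null(params)) return(tibble())
                    tibble(model = model, term = names(params),
                           estimate = unlist(params), winner = winner)
                  })
}

#' One-row summary of a concentration-response fit
#'
#' @param x A `devtox_fit`.
#' @param ... Unused.
#' @return Tibble: `winner`, per-model AICs, `n_points`, `n_conc`,
#'   `error_model`.
#' @export
glance.devtox_fit <- function(x, ...) {
  aics <- setNames(x$fits$aic, paste0("aic_", x$fits$model))
  dplyr::bind_cols(
    tibble(winner = x$winner),
    as_tibble(as.list(aics)),
    tibble(n_points = nrow(x$data),
           n_conc = length(unique(x$data$conc_uM)),
           error_model = x$error_model)
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
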