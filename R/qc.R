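#' Robust plate performance metrics
#'
#' Median/MAD-based assay quality statistics computed from the %SOX17+
#' values of a plate's positive and negative control wells: the
#' signal-to-background ratio `S/B = xPos / xNeg`, the robust coefficient of
#' variation `rCV = 100 * madPos / xPos` (%), and the robust Z'-factor
#' `rZ' = 1 - 3 * (madPos + madNeg) / |xPos - xNeg|`. A screen with
#' `rZ' > 0.5` is conventionally considered of screening quality.
#'
#' @param x_pos,x_neg Median %SOX17+ of the positive (differentiated) and
#'   negative (pluripotent) control wells.
#' @param mad_pos,mad_neg MADs of the same control populations.
#' @return The metric value; `NA` with a warning where undefined
#'   (`x_neg = 0` for S/B, `x_pos = 0` for rCV, `x_pos = x_neg` for rZ').
#' @name qc_metrics
#' @examples
#' signal_to_background(63, 1)      # 63
#' robust_cv(70, 3.71)              # 5.3
#' robust_zprime(70, 1, 2, 1)       # 0.8696
NULL

#' @rdname qc_metrics
#' @export
signal_to_background <- function(x_pos, x_neg) {
  ifelse(x_neg == 0, {
    warning("S/B undefined: negative-control median is 0.")
    NA_real_
  }, x_pos / x_neg)
}

#' @rdname qc_metrics
#' @export
robust_cv <- function(x_pos, mad_pos) {
  ifelse(x_pos == 0, {
    warning("rCV undefined: positive-control median is 0.")
    NA_real_
  }, 100 * mad_pos / x_pos)
}

#' @rdname qc_metrics
#' @export
robust_zprime <- function(x_pos, x_neg, mad_pos, mad_neg) {
  ifelse(x_pos == x_neg, {
    warning("rZ' undefined: control medians are equal.")
    NA_real_
  }, 1 - 3 * (mad_pos + mad_neg) / abs(x_pos - x_neg))
}

#' Per-plate and pooled QC metrics from well summaries
#'
#' Computes plate-wise control statistics (medians and MADs of %SOX17+ for
#' the chosen positive and negative control roles) and the three robust
#' metrics, plus a pooled summary across plates. The positive control is
#' configurable between the solvent-exposed endoderm wells (default; the
#' population treatment wells are compared to) and the plain endoderm
#' differentiation wells.
#'
#' @param wells Well summaries with layout metadata (`role`,
#'   `pct_sox17_pos`).
#' @param pos_role Positive-control role (default `"solvent_control"`).
#' @param neg_role Negative-control role (default `"pluripotent_control"`).
#' @param mad_constant MAD scale constant (default 1.4826).
#' @return List with `per_plate` (tibble: plate_id, x_pos, x_neg, mad_pos,
#'   mad_neg, n_pos, n_neg, sb, rcv, rzprime) and `pooled` (one-row tibble
#'   with the median S/B and rZ' and the inter-plate rCV, defined as the
#'   median of per-plate rCVs).
#' @export
plate_qc <- function(wells, pos_role = c("solvent_control", "endoderm_control"),
                     neg_role = "pluripotent_control", mad_constant = 1.4826) {
  pos_role <- match.arg(pos_role)
  stat <- function(data, role) {
    data |>
      filter(.data$role == !!role, is.finite(.data$pct_sox17_pos)) |>
      summarise(x = median(.data$pct_sox17_pos),
                mad = mad(.data$pct_sox17_pos, constant = mad_constant),
                n = dplyr::n(), .by = "plate_id")
  }
  pos <- stat(wells, pos_role) |> rename(x_pos = "x", mad_pos = "mad", n_pos = "n")
  neg <- stat(wells, neg_role) |> rename(x_neg = "x", mad_neg = "mad", n_neg = "n")
  per_plate <- inner_join(pos, neg, by = "plate_id") |>
    mutate(sb = signal_to_background(.data$x_pos, .data$x_neg),
           rcv = robust_cv(.data$x_pos, .data$mad_pos),
           rzprime = robust_zprime(.data$x_pos, .data$x_neg,
                                   .data$mad_pos, .data$mad_neg))
  if (!nrow(per_plate)) abort("No plate has both control roles with data.")
  pooled <- per_plate |>
    summarise(n_plates = dplyr::n(),
              sb = median(.data$sb, na.rm = TRUE),
              rcv = median(.data$rcv, na.rm = TRUE),
              rzprime = median(.data$rzprime, na.rm = TRUE))
  list(per_plate = per_plate, pooled = pooled)
}
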