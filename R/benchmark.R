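#' Parse printed potency strings into values and censor flags
#'
#' Benchmark tables print potencies as plain numbers, censored bounds
#' (`">200"`, `"<0.01"`) or `"NA"` (not reached / not tested; a trailing
#' asterisk marks inactivity inferred from a single-concentration screen).
#' Returns the numeric bound and a censor code.
#'
#' @param x Character vector of printed potency entries.
#' @return Tibble with `value` (numeric, the printed bound) and `cens`
#'   (`"lt"`, `"gt"`, or `NA` for uncensored/absent).
#' @export
#' @examples
#' parse_potency(c("0.16", ">200", "<0.01", "NA", "246,664"))
parse_potency <- function(x) {
  x <- trimws(gsub("\\*", "", as.character(x)))
  x <- gsub(",", "", x)
  cens <- dplyr::case_when(grepl("^<", x) ~ "lt", grepl("^>", x) ~ "gt",
                           TRUE ~ NA_character_)
  num <- suppressWarnings(as.numeric(sub("^[<>]", "", x)))
  tibble(value = num, cens = ifelse(is.na(num), NA_character_, cens))
}

#' Load a packaged benchmark chemical table
#'
#' Reads one of the chemical benchmark tables shipped with the package
#' (transcriptions of the reference-chemical set and the two cross-assay
#' comparison sets) and parses every `*_uM` potency column into a numeric
#' column plus a `*_cens` censor column.
#'
#' @param which `"table1"` (8 reference chemicals), `"table3"` (34-chemical
#'   comparison with the antecedent SOX17 assay, hPST) or `"table4"`
#'   (40-chemical comparison with the metabolite-based devTOX quickPredict
#'   assay).
#' @return Tibble of chemical records.
#' @export
#' @examples
#' tbl3 <- benchmark_table("table3")
#' dplyr::count(tbl3, devtox_call)
benchmark_table <- function(which = c("table1", "table3", "table4")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, ".csv"), package = "devtoxglr",
                      mustWork = TRUE)
  raw <- as_tibble(read.csv(path, colClasses = "character", check.names = FALSE))
  pot_cols <- grep("_uM$", names(raw), value = TRUE)
  for (col in pot_cols) {
    parsed <- parse_potency(raw[[col]])
    raw[[col]] <- parsed$value
    raw[[paste0(col, "_cens")]] <- parsed$cens
  }
  if ("pct_max_inhibition" %in% names(raw)) {
    raw$pct_max_inhibition <- suppressWarnings(as.numeric(raw$pct_max_inhibition))
  }
  raw
}

#' Validate CAS registry number checksums
#'
#' A CAS number's final digit is a checksum: the remaining digits, weighted
#' by their position counted from the right, must equal it modulo 10.
#'
#' @param casrn Character vector of CAS numbers (with hyphens).
#' @return Logical vector.
#' @export
#' @examples
#' casrn_valid(c("50-76-0", "50-76-1"))
casrn_valid <- function(casrn) {
  purrr::map_lgl(casrn, function(cas) {
    digits <- suppressWarnings(as.integer(strsplit(gsub("-", "", cas), "")[[1]]))
    if (length(digits) < 4L || anyNA(digits)) return(FALSE)
    check <- digits[length(digits)]
    body <- rev(digits[-length(digits)])
    sum(body * seq_along(body)) %% 10L == check
  })
}

confusion_metrics <- function(tp, fp, tn, fn) {
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    balanced_accuracy = 100 * (tp / (tp + fn) + tn / (tn + fp)) / 2
  )
}

#' Confusion-matrix metrics from call counts
#'
#' @param tp,fp,tn,fn Counts of true/false positive/negative calls.
#' @return One-row tibble with the counts, sensitivity, specificity and
#'   balanced accuracy (all in percent).
#' @export
#' @examples
#' confusion_from_counts(tp = 30, fp = 8, tn = 11, fn = 9)
confusion_from_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fn > 0, tn + fp > 0)
  confusion_metrics(tp, fp, tn, fn)
}

#' Confusion-matrix metrics from per-chemical calls
#'
#' Tallies an assay's calls (`TP`/`FP`/`TN`/`FN`, or `active`/`inactive`
#' combined with the truth class column) and computes sensitivity,
#' specificity and balanced accuracy.
#'
#' @param records Chemical records (e.g. from [benchmark_table()]).
#' @param call_col Name of the call column.
#' @param truth_col Truth-class column (`"Pos"`/`"Neg"`), used when calls are
#'   `active`/`inactive`.
#' @return One-row metrics tibble (see [confusion_from_counts()]).
#' @export
#' @examples
#' confusion(benchmark_table("table3"), "devtox_call")
confusion <- function(records, call_col, truth_col = "dt_class") {
  calls <- records[[call_col]]
  if (is.null(calls) || anyNA(calls) || any(calls == "")) {
    abort("Every record needs a call in `call_col`.")
  }
  if (all(calls %in% c("active", "inactive"))) {
    truth <- records[[truth_col]]
    calls <- dplyr::case_when(
      truth == "Pos" & calls == "active" ~ "TP",
      truth == "Pos" & calls == "inactive" ~ "FN",
      truth == "Neg" & calls == "active" ~ "FP",
      TRUE ~ "TN"
    )
  }
  if (!all(calls %in% c("TP", "FP", "TN", "FN"))) {
    abort("Calls must be TP/FP/TN/FN or active/inactive.")
  }
  confusion_metrics(sum(calls == "TP"), sum(calls == "FP"),
                    sum(calls == "TN"), sum(calls == "FN"))
}

# TRUE when a (possibly censored) potency is at or below the threshold.
potency_le <- function(value, cens, threshold) {
  dplyr::case_when(
    is.na(value) ~ FALSE,                       # potency never reached
    !is.na(cens) & cens == "gt" ~ FALSE,        # censored above the bound
    !is.na(cens) & cens == "lt" ~ value <= threshold,
    TRUE ~ value <= threshold
  )
}

#' Re-call actives under a potency threshold
#'
#' Applies a potency-based activity requirement: an active call (TP or FP)
#' whose potency is absent, censored above its bound, or greater than
#' `threshold_uM` is reclassified as inactive; truth classes are untouched
#' and calls are recomputed against them. This mirrors stratifying hit calls
#' with a 30 uM AC50 cutoff.
#'
#' @param records Chemical records.
#' @param call_col Call column to re-derive.
#' @param potency_col Numeric potency column (uM); its `*_cens` companion is
#'   used automatically when present.
#' @param threshold_uM Positive threshold; `Inf` leaves calls unchanged.
#' @param truth_col Truth-class column.
#' @return `records` with `call_col` replaced by the filtered calls.
#' @export
#' @examples
#' filtered <- potency_filter(benchmark_table("table3"), "devtox_call",
#'                            "devtox_ac50_uM", 30)
#' confusion(filtered, "devtox_call")
potency_filter <- function(records, call_col, potency_col, threshold_uM,
                           truth_col = "dt_class") {
  if (!potency_col %in% names(records)) {
    abort(paste("Unknown potency column:", potency_col))
  }
  if (!is.numeric(threshold_uM) || threshold_uM < 0) {
    abort("`threshold_uM` must be non-negative.")
  }
  cens_col <- paste0(potency_col, "_cens")
  cens <- if (cens_col %in% names(records)) records[[cens_col]] else NA_character_
  active <- records[[call_col]] %in% c("TP", "FP")
  still_active <- active & potency_le(records[[potency_col]], cens, threshold_uM)
  truth <- records[[truth_col]]
  records[[call_col]] <- dplyr::case_when(
    truth == "Pos" & still_active ~ "TP",
    truth == "Pos" & !still_active ~ "FN",
    truth == "Neg" & still_active ~ "FP",
    TRUE ~ "TN"
  )
  records
}

#' Side-by-side assay comparison with discordance listing
#'
#' Computes confusion metrics for two assays' call columns over the same
#' chemical records and lists the chemicals on which the calls disagree.
#'
#' @param records Chemical records with both call columns.
#' @param call_a,call_b Call column names.
#' @return List: `metrics` (two-row tibble keyed by `assay`) and
#'   `discordant` (tibble of chemicals with differing calls).
#' @export
#' @examples
#' cmp <- compare_assays(benchmark_table("table4"), "qp_call", "devtox_call")
#' cmp$metrics
compare_assays <- function(records, call_a, call_b) {
  metrics <- bind_rows(
    confusion(records, call_a) |> mutate(assay = call_a, .before = 1),
    confusion(records, call_b) |> mutate(assay = call_b, .before = 1)
  )
  discordant <- records |>
    filter(.data[[call_a]] != .data[[call_b]]) |>
    select(dplyr::any_of(c("casrn", "chemical", "dt_class")),
           dplyr::all_of(c(call_a, call_b)))
  list(metrics = metrics, discordant = discordant)
}

#' Printed training-set confusion counts
#'
#' The 58-chemical training screen's outcome as printed: 38 chemicals called
#' positive and 20 called negative, of which 8 were false positives and 9
#' false negatives (so 30 TP and 11 TN).
#'
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`.
#' @export
training_set_counts <- function() {
  called_pos <- 38L; called_neg <- 20L; fp <- 8L; fn <- 9L
  tibble(tp = called_pos - fp, fp = fp, tn = called_neg - fn, fn = fn)
}
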