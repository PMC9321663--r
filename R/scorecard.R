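#' Per-replicate delta-Ct values against the housekeeping panel
#'
#' For every gene and replicate, subtracts the mean Ct of the housekeeping
#' genes of that replicate: `dCt(gene, rep) = Ct(gene, rep) -
#' mean(Ct(housekeeping, rep))`. Lower delta-Ct means higher expression.
#'
#' @param ct_table Tibble with columns `gene`, `replicate`, `ct` (and
#'   optionally `gene_set`).
#' @param housekeeping Character vector of housekeeping gene names (default
#'   the five-gene scorecard panel).
#' @return `ct_table` plus a `dct` column.
#' @export
#' @examples
#' ct <- tibble::tibble(gene = c("ACTB-1", "ACTB-2", "CTCF", "EP300", "SMAD1", "SOX17"),
#'                      replicate = 1, ct = c(20, 20, 20, 20, 20, 25))
#' delta_ct(ct, housekeeping = c("ACTB-1", "ACTB-2", "CTCF", "EP300", "SMAD1"))
delta_ct <- function(ct_table,
                     housekeeping = c("ACTB-1", "ACTB-2", "CTCF", "EP300", "SMAD1")) {
  missing_hk <- setdiff(housekeeping, unique(ct_table$gene))
  if (length(missing_hk)) {
    abort(paste("Housekeeping gene(s) missing from the Ct table:",
                paste(missing_hk, collapse = ", ")))
  }
  hk <- ct_table |>
    filter(.data$gene %in% housekeeping) |>
    summarise(hk_mean = mean(.data$ct), .by = "replicate")
  ct_table |>
    inner_join(hk, by = "replicate") |>
    mutate(dct = .data$ct - .data$hk_mean) |>
    select(-"hk_mean")
}

#' Delta-delta-Ct fold change against a reference panel
#'
#' `ddCt = mean(sample dCt) - reference mean dCt`; `log2FC = -ddCt`;
#' linear fold change `FC = 2^-ddCt`. Positive log2FC means higher
#' expression than the reference pluripotent state.
#'
#' @param dct_table Output of [delta_ct()].
#' @param reference Tibble with columns `gene`, `ref_mean` (reference panel
#'   delta-Ct means, e.g. from [simulate_ct_panel()]).
#' @return Tibble per gene: `gene`, `n_rep`, `dct_mean`, `dct_se`, `ddct`,
#'   `log2_fc`, `fold_change`.
#' @export
#' @examples
#' dct <- tibble::tibble(gene = "SOX17", replicate = 1:3, dct = c(5, 5, 5))
#' ref <- tibble::tibble(gene = "SOX17", ref_mean = 8)
#' fold_change(dct, ref) # ddct -3, fold change 8
fold_change <- function(dct_table, reference) {
  dct_table |>
    summarise(n_rep = dplyr::n(),
              dct_mean = mean(.data$dct),
              dct_se = stats::sd(.data$dct) / sqrt(dplyr::n()),
              .by = "gene") |>
    inner_join(reference[c("gene", "ref_mean")], by = "gene") |>
    mutate(ddct = .data$dct_mean - .data$ref_mean,
           log2_fc = -.data$ddct,
           fold_change = 2^(-.data$ddct)) |>
    select(-"ref_mean")
}

#' One-sided gene-level p-value against the reference mean
#'
#' One-sample, one-sided t-test of the sample delta-Ct replicates against
#' the reference-panel mean, with the alternative that expression increased
#' (delta-Ct decreased). The tail probability is clipped to
#' `[1e-12, 1 - 1e-12]` so its normal quantile stays finite. With zero
#' sample variance the p-value degenerates to the relevant clip value by the
#' sign of the mean difference.
#'
#' @param sample_dct Numeric vector of sample delta-Ct replicates (>= 2).
#' @param ref_mean Reference-panel mean delta-Ct for the gene.
#' @param clip Clipping bound keeping the p-value strictly inside (0, 1).
#' @return P-value in (0, 1).
#' @export
#' @examples
#' gene_pvalue(c(3.0, 3.2, 2.8), ref_mean = 6) # strongly increased expression
gene_pvalue <- function(sample_dct, ref_mean, clip = 1e-12) {
  if (length(sample_dct) < 2L) abort("Need >= 2 sample replicates.")
  if (stats::sd(sample_dct) == 0) {
    p <- if (mean(sample_dct) < ref_mean) clip else 1 - clip
    return(p)
  }
  p <- t.test(sample_dct, mu = ref_mean, alternative = "less")$p.value
  min(max(p, clip), 1 - clip)
}

#' Correlation-adjusted Stouffer combination of gene p-values
#'
#' Converts each gene's p-value to a normal quantile `Z_k = qnorm(1 - P_k)`
#' and combines them over the `N` genes of a classifier set:
#' `Z = sum(Z_k) / sqrt(N + 2 * sum_{k<j} r_kj)`, where `r_kj` are the
#' pairwise correlations of the gene statistics (0, i.e. independence, when
#' unsupplied). The combined tail probability is `1 - pnorm(Z)`. Higher Z
#' means more genes with significantly increased expression relative to the
#' reference pluripotent state.
#'
#' @param p_values Gene-level p-values for one gene set (length N >= 1).
#' @param correlations Optional N x N correlation matrix (symmetric,
#'   |r| <= 1); only the upper triangle is used.
#' @return List: `n_genes`, `z_genes`, `z_combined`, `p_combined`.
#' @export
#' @examples
#' combine_zscores(rep(1 - pnorm(2), 2))$z_combined # 4 / sqrt(2)
combine_zscores <- function(p_values, correlations = NULL) {
  n <- length(p_values)
  if (n < 1L) abort("Need at least one p-value.")
  if (any(p_values <= 0 | p_values >= 1)) abort("P-values must lie strictly in (0, 1).")
  z <- qnorm(1 - p_values)
  r_sum <- 0
  if (!is.null(correlations)) {
    correlations <- as.matrix(correlations)
    if (!all(dim(correlations) == n) ||
        any(abs(correlations - t(correlations)) > 1e-8) ||
        any(abs(correlations) > 1 + 1e-8)) {
      abort("`correlations` must be a symmetric N x N matrix with |r| <= 1.")
    }
    r_sum <- sum(correlations[upper.tri(correlations)])
  }
  denom <- n + 2 * r_sum
  if (denom <= 0) abort("Invalid correlation structure: non-positive variance.")
  z_comb <- sum(z) / sqrt(denom)
  list(n_genes = n, z_genes = z, z_combined = z_comb,
       p_combined = 1 - pnorm(z_comb))
}

#' Full scorecard analysis of a Ct table
#'
#' Runs the whole gene-expression scorecard: delta-Ct normalization against
#' the housekeeping genes, per-gene delta-delta-Ct fold changes and one-sided
#' p-values against the reference pluripotent panel, and per-set
#' Stouffer-type Z-test scores for the four classifier gene sets.
#'
#' @param ct_table Tibble: `gene`, `gene_set`, `replicate`, `ct`.
#' @param reference Tibble: `gene`, `ref_mean` (see [simulate_ct_panel()]).
#' @param housekeeping Housekeeping gene names.
#' @param correlations Optional named list of per-set correlation matrices.
#' @return List: `genes` (per-gene tibble with fold changes, p-values and
#'   Z_k) and `sets` (per-set tibble: `gene_set`, `n_genes`, `z_score`,
#'   `p_tail`).
#' @export
scorecard_scores <- function(ct_table, reference,
                             housekeeping = c("ACTB-1", "ACTB-2", "CTCF",
                                              "EP300", "SMAD1"),
                             correlations = NULL) {
  dct <- delta_ct(ct_table, housekeeping = housekeeping)
  classifier <- dct |> filter(!.data$gene %in% housekeeping)
  fc <- fold_change(classifier, reference)
  pvals <- classifier |>
    tidyr::nest(reps = -c("gene", "gene_set")) |>
    inner_join(reference[c("gene", "ref_mean")], by = "gene") |>
    mutate(p_value = purrr::map2_dbl(.data$reps, .data$ref_mean,
                                     ~ gene_pvalue(.x$dct, .y)),
           z_gene = qnorm(1 - .data$p_value)) |>
    select("gene", "gene_set", "p_value", "z_gene")
  genes <- fc |> inner_join(pvals, by = "gene")
  sets <- genes |>
    tidyr::nest(gs = -"gene_set") |>
    mutate(score = purrr::map2(.data$gs, .data$gene_set, function(g, set) {
      cmb <- combine_zscores(g$p_value, correlations = correlations[[set]])
      tibble(n_genes = cmb$n_genes, z_score = cmb$z_combined,
             p_tail = cmb$p_combined)
    })) |>
    select("gene_set", "score") |>
    tidyr::unnest("score")
  list(genes = genes, sets = sets)
}
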