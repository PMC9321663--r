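#' Scorecard gene panel
#'
#' The gene catalogue used by the qPCR scorecard simulator and analysis:
#' five housekeeping genes plus four classifier gene sets (pluripotency,
#' ectoderm, mesoderm, endoderm) of trilineage markers.
#'
#' @return Tibble with columns `gene`, `gene_set`.
#' @export
scorecard_gene_panel <- function() {
  bind_rows(
    tibble(gene = c("ACTB-1", "ACTB-2", "CTCF", "EP300", "SMAD1"),
           gene_set = "housekeeping"),
    tibble(gene = c("POU5F1", "NANOG", "LIN28A", "DNMT3B", "SOX2",
                    "ZFP42", "TDGF1", "FOXD3"),
           gene_set = "pluripotency"),
    tibble(gene = c("PAX6", "OTX2", "SOX1", "NES", "TUBB3", "MAP2",
                    "DLK1", "WNT1"),
           gene_set = "ectoderm"),
    tibble(gene = c("T", "HAND1", "MSX1", "TBX2", "PDGFRA", "CDX2",
                    "ESM1", "GATA2"),
           gene_set = "mesoderm"),
    tibble(gene = c("SOX17", "FOXA2", "GATA4", "GATA6", "EOMES", "NODAL",
                    "CXCR4", "HNF1B"),
           gene_set = "endoderm")
  )
}

#' Default log2 expression shifts for the directed-endoderm state
#'
#' Named vector of log2 fold-change effect sizes the Ct-panel simulator
#' applies when `state = "directed_endoderm"`: endoderm markers up (SOX17
#' +5.5, EOMES +9.2, GATA6 +8.9, NODAL +6.9, ...), pluripotency markers down
#' (SOX2 -5.3, ...), BRA (gene `T`) mildly down (-3.1), ectoderm essentially
#' unchanged.
#'
#' @return Named numeric vector of log2 effects; genes not listed shift by 0.
#' @export
endoderm_log2_effects <- function() {
  c(SOX17 = 5.5, EOMES = 9.2, GATA6 = 8.9, NODAL = 6.9, FOXA2 = 6.0,
    GATA4 = 5.0, CXCR4 = 4.2, HNF1B = 4.6,
    SOX2 = -5.3, POU5F1 = -3.6, NANOG = -4.1, LIN28A = -2.2, DNMT3B = -2.6,
    ZFP42 = -3.0, TDGF1 = -2.1, FOXD3 = -1.6,
    T = -3.1, HAND1 = -0.4, MSX1 = -0.3)
}

# Deterministic "published panel" baseline delta-Ct per gene in the
# pluripotent state: pluripotency genes are expressed (low delta-Ct),
# lineage genes mostly silent (high delta-Ct).
reference_base_dct <- function(panel) {
  base <- dplyr::case_match(panel$gene_set,
                            "housekeeping" ~ 0,
                            "pluripotency" ~ 2.5,
                            .default = 10)
  # small fixed per-gene stagger so genes are distinguishable; the
  # housekeeping normalizers stay exactly at 0 by construction
  stagger <- 0.3 * (seq_len(nrow(panel)) %% 5 - 2)
  ifelse(panel$gene_set == "housekeeping", 0, base + stagger)
}

#' Simulate a qPCR scorecard Ct table with a pluripotent reference panel
#'
#' Generates replicate Ct values for the scorecard gene panel in either the
#' pluripotent or the directed-endoderm state, together with a synthetic
#' stand-in for the published reference panel of pluripotent stem cell
#' lines (per-gene delta-Ct values across `n_reference_lines` lines). In the
#' directed-endoderm state each gene's Ct is lowered by its log2 effect size
#' (higher expression), so downstream delta-delta-Ct analysis recovers the
#' injected fold changes.
#'
#' @param n_replicates Biological replicates (>= 2).
#' @param state `"pluripotent"` or `"directed_endoderm"`.
#' @param config A [sim_config()] (only the seed is used).
#' @param effects Named log2 effect vector applied under
#'   `"directed_endoderm"`; default [endoderm_log2_effects()].
#' @param noise_sd Replicate-level Ct noise (cycles, default 0.25).
#' @param ref_sd Between-line spread of reference delta-Ct values (default 0.5).
#' @param n_reference_lines Reference stem-cell lines (default 10).
#'
#' @return List with `ct` (tibble: gene, gene_set, replicate, ct),
#'   `reference` (tibble: gene, gene_set, ref_mean, ref_sd, n_lines) and
#'   `reference_lines` (tibble: gene, line, dct).
#' @export
#' @examples
#' panel <- simulate_ct_panel(3, "directed_endoderm", sim_config(seed = 2))
#' head(panel$ct)
simulate_ct_panel <- function(n_replicates = 3L,
                              state = c("pluripotent", "directed_endoderm"),
                              config = sim_config(),
                              effects = endoderm_log2_effects(),
                              noise_sd = 0.25,
                              ref_sd = 0.5,
                              n_reference_lines = 10L) {
  state <- match.arg(state)
  if (n_replicates < 2L) abort("`n_replicates` must be at least 2.")
  panel <- scorecard_gene_panel()
  panel$base_dct <- reference_base_dct(panel)
  withr::with_seed(config$seed + 101L, {
    ref_lines <- tidyr::crossing(gene = panel$gene, line = seq_len(n_reference_lines)) |>
      left_join(panel, by = "gene") |>
      mutate(dct = .data$base_dct + rnorm(dplyr::n(), 0, ref_sd)) |>
      select("gene", "line", "dct")
    reference <- ref_lines |>
      summarise(ref_mean = mean(.data$dct), ref_sd = stats::sd(.data$dct),
                n_lines = dplyr::n(), .by = "gene") |>
      left_join(panel[c("gene", "gene_set")], by = "gene")

    eff <- if (state == "directed_endoderm") effects else numeric()
    shift <- setNames(rep(0, nrow(panel)), panel$gene)
    shift[names(eff)[names(eff) %in% panel$gene]] <- eff[names(eff) %in% panel$gene]

    hk_genes <- panel$gene[panel$gene_set == "housekeeping"]
    ct <- tidyr::crossing(gene = panel$gene, replicate = seq_len(n_replicates)) |>
      left_join(panel, by = "gene") |>
      left_join(reference[c("gene", "ref_mean")], by = "gene") |>
      mutate(hk_base = 20,
             ct = .data$hk_base + .data$ref_mean - shift[.data$gene] +
               rnorm(dplyr::n(), 0, noise_sd)) |>
      select("gene", "gene_set", "replicate", "ct")
    # housekeeping genes anchor the per-replicate normalizer at ~20 cycles
    ct$ct[ct$gene %in% hk_genes] <- 20 +
      rnorm(sum(ct$gene %in% hk_genes), 0, noise_sd / 4)
    list(ct = ct, reference = reference, reference_lines = ref_lines)
  })
}
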