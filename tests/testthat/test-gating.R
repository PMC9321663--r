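test_that("mad_threshold follows the median + k * MAD rule", {
  expect_equal(mad_threshold(rep(4.2, 10), multiplier = 5), 4.2)
  expect_equal(mad_threshold(1:5, multiplier = 5, mad_constant = 1), 8)
  expect_equal(mad_threshold(c(3, 9, 1, 7, 5), multiplier = 0), 5)
  expect_error(mad_threshold(1), "at least 2")
  expect_error(mad_threshold(c(1, NA)), "finite")
})

test_that("plate thresholds are plate-local and role-sourced", {
  lay1 <- one_chem_layout(n_rep = 1, n_control = 4, plate_id = "A")
  lay2 <- one_chem_layout(n_rep = 1, n_control = 4, plate_id = "B")
  eff <- chemical_effect("chemA")
  cells <- dplyr::bind_rows(
    simulate_plate(lay1, eff, small_config(seed = 1)),
    simulate_plate(lay2, eff, small_config(seed = 2, intensity_sdlog = c(neg = 0.8, pos = 0.8)))
  )
  thr <- plate_thresholds(cells, list(lay1, lay2))
  expect_setequal(thr$channel, c("sox17", "sox2", "bra"))
  tA <- thr$threshold[thr$plate_id == "A" & thr$channel == "sox17"]
  tB <- thr$threshold[thr$plate_id == "B" & thr$channel == "sox17"]
  expect_false(isTRUE(all.equal(tA, tB)))
  expect_equal(unique(thr$baseline_role[thr$channel == "sox2"]), "endoderm_control")
  expect_equal(unique(thr$baseline_role[thr$channel %in% c("sox17", "bra")]),
               "pluripotent_control")

  # constant control intensities -> threshold equals the constant
  cells_const <- cells |> dplyr::mutate(sox17 = 7)
  thr_const <- plate_thresholds(cells_const, list(lay1, lay2))
  expect_equal(thr_const$threshold[thr_const$channel == "sox17"], c(7, 7))
})

test_that("well summaries aggregate fields, apply strict thresholds, flag empty wells", {
  cells <- tidyr::crossing(field = 1:5, i = 1:20) |>
    dplyr::mutate(plate_id = "P", well_id = "A01", cell_id = dplyr::row_number(),
                  sox17 = rep(c(10, 100), 50), sox2 = 1, bra = 1, nuc = 1)
  thr <- tibble::tibble(plate_id = "P", channel = c("sox17", "sox2", "bra"),
                        threshold = c(50, 0.5, 2))
  ws <- summarize_wells(cells, thr)
  expect_equal(ws$cell_count, 100L)          # 5 fields x 20 cells
  expect_equal(ws$pct_sox17_pos, 50)         # half the cells above threshold
  expect_equal(ws$pct_sox2_pos, 100)         # threshold below all intensities
  expect_equal(ws$pct_bra_pos, 0)

  # ties go negative: threshold exactly at the intensity
  thr$threshold[1] <- 100
  expect_equal(summarize_wells(cells, thr)$pct_sox17_pos, 0)

  # zero-cell well appears with count 0 and missing percentages
  layout <- tibble::tibble(plate_id = "P", well_id = c("A01", "A02"),
                           role = "treatment", chemical_id = "x", conc_uM = 1)
  ws2 <- summarize_wells(cells, thr, layout)
  expect_equal(ws2$cell_count, c(100L, 0L))
  expect_true(is.na(ws2$pct_sox17_pos[2]))
})

test_that("raising the multiplier never raises percent responders, and order is irrelevant", {
  layout <- one_chem_layout(n_rep = 2, n_control = 6)
  eff <- chemical_effect("chemA", "positive", sox17_top = 0.5)
  cells <- simulate_plate(layout, eff, small_config(seed = 4))
  pcts <- purrr::map(c(2, 5, 10), function(k) {
    ws <- summarize_wells(cells, plate_thresholds(cells, layout, multiplier = k))
    ws$pct_sox17_pos
  })
  expect_true(all(pcts[[2]] <= pcts[[1]]))
  expect_true(all(pcts[[3]] <= pcts[[2]]))

  shuffled <- cells[sample(nrow(cells)), ]
  ws_a <- summarize_wells(cells, plate_thresholds(cells, layout), layout)
  ws_b <- summarize_wells(shuffled, plate_thresholds(shuffled, layout), layout)
  expect_equal(ws_a, ws_b)
})

test_that("with separated mixture components gating matches the latent states exactly", {
  layout <- one_chem_layout(n_rep = 2, n_control = 6)
  eff <- chemical_effect("chemA", "positive", sox17_top = 0.6, sox17_log10_ac50 = 0.5)
  cfg <- small_config(seed = 5, intensity_sdlog = c(neg = 0.05, pos = 0.05))
  cells <- simulate_plate(layout, eff, cfg)
  ws <- summarize_wells(cells, plate_thresholds(cells, layout))
  latent <- cells |>
    dplyr::summarise(pct = 100 * mean(sox17_state), .by = c(plate_id, well_id))
  joined <- dplyr::inner_join(ws, latent, by = c("plate_id", "well_id"))
  expect_equal(joined$pct_sox17_pos, joined$pct, tolerance = 1e-12)
})
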