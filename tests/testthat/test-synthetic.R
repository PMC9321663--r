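test_that("the same layout, effects and seed reproduce identical tables", {
  layout <- one_chem_layout(n_rep = 2, n_control = 4)
  eff <- chemical_effect("chemA", "positive", sox17_top = 0.5, sox17_log10_ac50 = 1)
  cfg <- small_config(seed = 99)
  a <- simulate_plate(layout, eff, cfg)
  b <- simulate_plate(layout, eff, cfg)
  expect_identical(a, b)
  c2 <- simulate_plate(layout, eff, small_config(seed = 100))
  expect_false(identical(a$sox17, c2$sox17))

  p1 <- simulate_ct_panel(3, "pluripotent", cfg)
  p2 <- simulate_ct_panel(3, "pluripotent", cfg)
  expect_identical(p1$ct, p2$ct)
  expect_identical(p1$reference, p2$reference)
})

test_that("a zero-effect chemical is indistinguishable from solvent controls", {
  # 100 treatment wells of a null chemical at a fixed concentration vs 100
  # solvent wells, compared on %SOX17+ via a rank-sum test at alpha = 0.01
  trt <- tibble::tibble(chemical_id = "null", conc_uM = rep(10, 100))
  layout <- plate_layout("P01", treatments = trt, n_control = 12)
  solvent_extra <- single_role_layout("solvent_control", plate_id = "P01")
  # carve 100 solvent wells out of unused interior wells
  free <- setdiff(solvent_extra$well_id, layout$well_id)
  layout <- dplyr::bind_rows(layout,
                             solvent_extra[solvent_extra$well_id %in% free[1:100], ])
  eff <- chemical_effect("null", "negative")  # all tops zero
  cells <- simulate_plate(layout, eff, small_config(seed = 3))
  thr <- plate_thresholds(cells, layout)
  wells <- summarize_wells(cells, thr, layout)
  pv <- stats::wilcox.test(
    wells$pct_sox17_pos[wells$role == "treatment"],
    wells$pct_sox17_pos[wells$role == "solvent_control"]
  )$p.value
  expect_gt(pv, 0.01)
})

test_that("endoderm-control wells reproduce the expected differentiation efficiency", {
  layout <- single_role_layout("endoderm_control")
  cells <- simulate_plate(layout, config = sim_config(seed = 21, cells_per_well_mean = 500))
  # oracle: classify by the generator's latent state, pooled over 384 wells
  pct <- cells |>
    dplyr::summarise(p = 100 * mean(sox17_state), .by = well_id)
  expect_equal(mean(pct$p), 70.2, tolerance = 2.8 / 70.2)
})

test_that("expected responses are monotone in concentration", {
  eff <- chemical_effect("tox", "positive", sox17_top = 0.9, sox17_log10_ac50 = 0,
                         hill_coeff = 1.3, cytotox_top = 0.6,
                         cytotox_log10_ac50 = 1, cytotox_hill = 2)
  conc <- 10^seq(-4, 3, length.out = 40)
  exp_tbl <- effect_expectation(eff, conc)
  expect_true(all(diff(exp_tbl$sox17_frac) <= 0))
  expect_true(all(diff(exp_tbl$count_scale) <= 0))
  # no effect -> flat
  flat <- effect_expectation(chemical_effect("none"), conc)
  expect_equal(diff(range(flat$sox17_frac)), 0)
})

test_that("simulate_plate validates its inputs", {
  layout <- one_chem_layout(n_rep = 1, n_control = 4)
  expect_error(simulate_plate(layout, effects = NULL, small_config()),
               "effect specification")
  expect_error(simulate_plate(layout[0, ], config = small_config()), "empty")
  expect_error(chemical_effect("x", sox17_top = 1.5), "\\[0, 1\\]")
  expect_error(chemical_effect("x", hill_coeff = 0), "positive")
})

test_that("ct panel nulls recover zero fold change and injected effects round-trip", {
  cfg <- sim_config(seed = 8)
  null_panel <- simulate_ct_panel(3, "pluripotent", cfg)
  dct <- delta_ct(null_panel$ct)
  fc <- fold_change(dplyr::filter(dct, gene_set != "housekeeping"),
                    null_panel$reference)
  expect_lt(max(abs(mean(fc$log2_fc)), abs(stats::median(fc$log2_fc))), 0.2)

  endo <- simulate_ct_panel(3, "directed_endoderm", cfg)
  fc_endo <- fold_change(delta_ct(endo$ct), endo$reference)
  sox17 <- fc_endo[fc_endo$gene == "SOX17", ]
  expect_lt(abs(sox17$log2_fc - 5.5), 3 * sox17$dct_se + 0.3)
  sox2 <- fc_endo[fc_endo$gene == "SOX2", ]
  expect_lt(abs(sox2$log2_fc - (-5.3)), 1)

  expect_error(simulate_ct_panel(1, "pluripotent", cfg), "at least 2")
})
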