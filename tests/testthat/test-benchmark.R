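test_that("printed potency strings parse with censoring", {
  p <- parse_potency(c("0.16", ">200", "<0.01", "NA", "246,664", "NA *"))
  expect_equal(p$value, c(0.16, 200, 0.01, NA, 246664, NA))
  expect_equal(p$cens, c(NA, "gt", "lt", NA, NA, NA))
})

test_that("packaged tables load with valid structure and CAS checksums", {
  t1 <- benchmark_table("table1")
  t3 <- benchmark_table("table3")
  t4 <- benchmark_table("table4")
  expect_equal(nrow(t1), 8)
  expect_equal(nrow(t3), 34)
  expect_equal(nrow(t4), 40)
  expect_true(all(casrn_valid(c(t1$casrn, t3$casrn, t4$casrn))))
  # calls are consistent with truth classes
  consistent <- function(tbl, col) {
    all((tbl[[col]] %in% c("TP", "FN")) == (tbl$dt_class == "Pos"))
  }
  expect_true(consistent(t3, "devtox_call") && consistent(t3, "hpst_call"))
  expect_true(consistent(t4, "devtox_call") && consistent(t4, "qp_call"))
})

test_that("confusion metrics add up and ignore record order", {
  t3 <- benchmark_table("table3")
  m <- confusion(t3, "devtox_call")
  expect_equal(m$tp + m$fp + m$tn + m$fn, nrow(t3))
  m_shuffled <- confusion(t3[sample(nrow(t3)), ], "devtox_call")
  expect_equal(m, m_shuffled)
  # active/inactive coding is equivalent to TP/FP/TN/FN coding
  t3b <- t3 |>
    dplyr::mutate(devtox_call = ifelse(devtox_call %in% c("TP", "FP"),
                                       "active", "inactive"))
  expect_equal(confusion(t3b, "devtox_call"), m)
  expect_error(confusion(dplyr::mutate(t3, devtox_call = NA), "devtox_call"),
               "call")
})

test_that("all-correct calls give perfect metrics and random calls converge to 50%", {
  perfect <- tibble::tibble(dt_class = rep(c("Pos", "Neg"), 10),
                            call = rep(c("TP", "TN"), 10))
  m <- confusion(perfect, "call")
  expect_equal(c(m$sensitivity, m$specificity, m$balanced_accuracy),
               c(100, 100, 100))

  ba <- withr::with_seed(5, purrr::map_dbl(1:300, function(i) {
    truth <- rep(c("Pos", "Neg"), c(30, 20))
    call <- sample(c("active", "inactive"), 50, replace = TRUE)
    confusion(tibble::tibble(dt_class = truth, call = call), "call")$balanced_accuracy
  }))
  expect_lt(abs(mean(ba) - 50), 2)
})

test_that("the potency filter reclassifies actives and is monotone", {
  t3 <- benchmark_table("table3")
  unchanged <- potency_filter(t3, "devtox_call", "devtox_ac50_uM", Inf)
  expect_equal(confusion(unchanged, "devtox_call"),
               confusion(t3, "devtox_call"))
  all_off <- potency_filter(t3, "devtox_call", "devtox_ac50_uM", 0)
  expect_equal(confusion(all_off, "devtox_call")$sensitivity, 0)
  expect_error(potency_filter(t3, "devtox_call", "nope_uM", 30), "Unknown")

  thresholds <- c(0.5, 5, 30, 100, 1000)
  mets <- purrr::map_dfr(thresholds, function(thr) {
    confusion(potency_filter(t3, "devtox_call", "devtox_ac50_uM", thr),
              "devtox_call")
  })
  expect_true(all(diff(mets$sensitivity) >= 0))  # raising threshold only adds actives
  expect_true(all(diff(mets$specificity) <= 0))
})

test_that("effect bands use half-open lower edges", {
  expect_equal(effect_band(c(0, 19.99, 20, 79.9, 80, 93, 100)),
               c("weak", "weak", "moderate", "moderate", "high", "high", "high"))
  expect_error(effect_band(120), "\\[0, 100\\]")
  expect_error(effect_band(-1), "\\[0, 100\\]")
  # the strongest reference chemical sits in the high band
  t1 <- benchmark_table("table1")
  atra <- t1$pct_max_inhibition[t1$chemical == "All-Trans Retinoic Acid"]
  expect_equal(effect_band(atra), "high")
})

test_that("assay comparison surfaces discordant chemicals", {
  t3 <- benchmark_table("table3")
  cmp_same <- compare_assays(dplyr::mutate(t3, other = devtox_call),
                             "devtox_call", "other")
  expect_equal(nrow(cmp_same$discordant), 0)

  cmp3 <- compare_assays(t3, "hpst_call", "devtox_call")
  fp_only_devtox <- cmp3$discordant$chemical[cmp3$discordant$devtox_call == "FP"]
  expect_setequal(fp_only_devtox, c("Cianidanol", "Esomeprazole", "Ketanserin",
                                    "Ibuprofen", "Methyldopa"))

  cmp4 <- compare_assays(benchmark_table("table4"), "qp_call", "devtox_call")
  expect_true(all(c("Diethylstilbestrol", "Dexamethasone") %in%
                    cmp4$discordant$chemical))
})

test_that("CAS checksum validation catches corrupted registry numbers", {
  expect_true(casrn_valid("50-76-0"))
  expect_false(casrn_valid("50-76-1"))
  expect_false(casrn_valid("not-a-cas"))
})
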