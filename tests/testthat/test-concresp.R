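test_that("normalization follows percent-of-baseline with optional inversion", {
  expect_equal(normalize_response(50, 50), 0)
  expect_equal(normalize_response(40, 50, invert = TRUE), 20)
  expect_equal(normalize_response(75, 50), 50)
  # scale equivariance: rescaling rval and bval together changes nothing
  expect_equal(normalize_response(40 * 7, 50 * 7, invert = TRUE), 20)
  expect_error(normalize_response(40, 0), "baseline")
  expect_error(normalize_response(40, -3), "baseline")
})

test_that("baseline cutoff is three baseline MADs", {
  expect_equal(baseline_cutoff(rep(0, 10))$coff, 0)
  bc <- baseline_cutoff(c(-2, -1, 0, 1, 2), mad_constant = 1)
  expect_equal(bc$bmad, 1)
  expect_equal(bc$coff, 3)
  expect_error(baseline_cutoff(c(0, 1, 2)), "at least 4")
})

test_that("noiseless Hill data are recovered by the Hill model", {
  conc <- default_conc_series()
  resp <- hill_curve(log10(conc), tp = 100, ga = 0, gw = 1)
  fit <- fit_conc_resp(conc, resp)
  expect_equal(fit$winner, "hill")
  par <- fit$fits$params[fit$fits$model == "hill"][[1]]
  expect_equal(par$tp, 100, tolerance = 1e-4)
  expect_equal(par$ga, 0, tolerance = 1e-4)
  expect_equal(par$gw, 1, tolerance = 1e-4)
})

test_that("the constant model wins on null series at the AIC boundary rate", {
  # On pure noise a Hill-family model out-scores the constant by AIC at
  # roughly the boundary chi-square rate (~6%), so the constant model is
  # expected to win ~94% of series; the hit rule's cutoff requirement is
  # what keeps such series from becoming hits (tested in the acceptance
  # suite). Assert the selection stays at that level.
  conc <- default_conc_series()
  wins <- withr::with_seed(17, {
    purrr::map_chr(1:200, function(i) {
      resp <- rnorm(3 * length(conc), 0, 5)
      fit_conc_resp(rep(conc, 3), resp)$winner
    })
  })
  expect_gte(mean(wins == "constant"), 0.90)
})

test_that("gain-loss data prefer the gain-loss model over Hill", {
  conc <- default_conc_series()
  x <- log10(conc)
  truth <- gainloss_curve(x, tp = 90, ga = -0.5, gw = 1.5, la = 1.8, lw = 2)
  resp <- withr::with_seed(9, rep(truth, 4) + rnorm(4 * length(x), 0, 3))
  fit <- fit_conc_resp(rep(conc, 4), resp)
  aic <- setNames(fit$fits$aic, fit$fits$model)
  expect_lt(aic[["gainloss"]], aic[["hill"]])
})

test_that("fit_conc_resp validates its inputs", {
  expect_error(fit_conc_resp(c(1, 10, 100), c(0, 0, 0)), "4 distinct")
  expect_error(fit_conc_resp(c(-1, 1, 10, 100), rep(0, 4)), "positive")
})

test_that("hit calls require both cutoff exceedance and a non-constant winner", {
  conc <- default_conc_series()
  strong <- hill_curve(log10(conc), tp = 100, ga = 0, gw = 1)
  fit <- fit_conc_resp(conc, strong)
  hit <- call_hit(fit, coff = 50)
  expect_equal(hit$hitc, 1L)
  expect_equal(hit$ac50_uM, 1, tolerance = 1e-4)
  expect_equal(hit$acc_uM, 1, tolerance = 1e-4)  # coff = tp/2 symmetry

  hit2 <- call_hit(fit, coff = 20.3)
  expect_equal(hit2$acc_uM, 10^(-log10(100 / 20.3 - 1)), tolerance = 1e-4)

  # below cutoff -> no hit, no potencies
  null_fit <- fit_conc_resp(conc, rep(0, length(conc)) + c(0.2, -0.1, 0.05, 0, 0.1, -0.2, 0.15, -0.05))
  miss <- call_hit(null_fit, coff = 30)
  expect_equal(miss$hitc, 0L)
  expect_true(is.na(miss$acc_uM) && is.na(miss$ac50_uM))
})

test_that("analytic and numeric ACC agree, and ACC <= AC50 when coff <= tp/2", {
  cases <- withr::with_seed(31, tibble::tibble(
    tp = runif(100, 30, 120),
    ga = runif(100, -2, 2),
    gw = runif(100, 0.4, 6),
    coff = runif(100, 1, 0.5 * tp)
  ))
  acc_analytic <- hill_acc(cases$tp, cases$ga, cases$gw, cases$coff)
  acc_num <- purrr::pmap_dbl(cases, function(tp, ga, gw, coff) {
    numeric_acc(function(x) hill_curve(x, tp, ga, gw), coff,
                lower = ga - 12 / gw, upper = ga + 12 / gw, n_grid = 4000)
  })
  expect_equal(acc_num, acc_analytic, tolerance = 1e-6)
  expect_true(all(acc_analytic <= 10^cases$ga + 1e-12))
})

test_that("the combined SOX17-or-cytotoxicity rule is a logical OR", {
  expect_true(combined_call(0, 1))
  expect_true(combined_call(1, 0))
  expect_false(combined_call(0, 0))
  h1 <- tibble::tibble(hitc = 1L); h0 <- tibble::tibble(hitc = 0L)
  expect_true(combined_call(h0, h1))
})

test_that("the endpoint catalogue matches the assay design", {
  ep <- devtox_endpoints()
  expect_equal(nrow(ep), 6)
  expect_equal(range(ep$endpoint_id), c(3093, 3098))
  expect_equal(ep$invert, ep$direction == "dn")
  expect_setequal(ep$source_measure[ep$normalization == "raw"],
                  c("pct_sox2_pos", "pct_bra_pos"))
})
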