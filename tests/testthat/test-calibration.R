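net_full <- build_network("full")
p_true <- set_vmax(default_parameters("model1"), 5)
sc_cal <- scenario_spec(t_end = 240, grid_dt = 5, label = "cal")
des_cal <- design_spec(times_h = c(0, 1, 2, 3, 4), replicates = 3)

test_that("parameter addresses read and write the right slots", {
  p <- default_parameters("model1")
  expect_equal(param_get(p, "aGP.keq"), 0.4)
  expect_equal(param_get(p, "XPK.km.Xu5P"), 0.3)
  expect_equal(param_get(p, "PhaC.c_bind"), 140)
  p2 <- param_set(p, "XPK.km.Xu5P", 1.23)
  expect_equal(param_get(p2, "XPK.km.Xu5P"), 1.23)
  expect_equal(param_get(p, "XPK.km.Xu5P"), 0.3)  # original untouched
  expect_error(param_get(p, "nope.keq"), "unknown")
  expect_error(param_set(p, "nope.keq", 1), "unknown")
})

test_that("the loss is zero on noise-free data and quadratic in residuals", {
  ds <- generate_timecourse(net_full, p_true, sc_cal, des_cal,
                            noise_model(0, 0), seed = 1)
  base <- objective(net_full, p_true, list(ds))
  expect_lt(base, 1e-8)

  # perturb the measurements by known deltas and recompute the loss by hand
  deltas <- seq_len(nrow(ds)) / 50
  ds2 <- ds
  ds2$value_mM <- ds$value_mM + deltas
  means2 <- aggregate(value_mM ~ time_h + observable, ds2, mean)
  means0 <- aggregate(value_mM ~ time_h + observable, ds, mean)
  expected <- 0
  for (obs in c("MD", "PHB")) {
    d <- means2$value_mM[means2$observable == obs] -
      means0$value_mM[means0$observable == obs]
    scale <- max(means2$value_mM[means2$observable == obs])
    expected <- expected + sum((d / scale)^2)
  }
  got <- objective(net_full, p_true, list(ds2))
  expect_equal(got, expected, tolerance = 1e-4)

  # doubling all residuals quadruples the loss
  ds4 <- ds
  ds4$value_mM <- ds$value_mM + 2 * deltas
  scale_ratio <- local({
    m2 <- aggregate(value_mM ~ observable, ds2, max)
    m4 <- aggregate(value_mM ~ observable, ds4, max)
    max(abs(m4$value_mM / m2$value_mM - 1))
  })
  # scales barely move (deltas are small), so the quadratic law holds to ~1%
  expect_lt(scale_ratio, 0.01)
  expect_equal(objective(net_full, p_true, list(ds4)) / got, 4,
               tolerance = 0.05)
})

test_that("a failing simulation yields an infinite loss with a diagnostic", {
  ds <- generate_timecourse(net_full, p_true, sc_cal, des_cal,
                            noise_model(0, 0), seed = 1)
  bad <- p_true
  bad$reactions$XPK$km <- bad$reactions$XPK$km["Pi"]  # drop a Km
  loss <- objective(net_full, bad, list(ds))
  expect_true(is.infinite(loss))
  expect_match(attr(loss, "diagnostic"), "XPK")
})

test_that("fitting from the truth returns the truth with ~zero loss", {
  ds <- generate_timecourse(net_full, p_true, sc_cal, des_cal,
                            noise_model(0, 0), seed = 1)
  spec <- fit_spec(c("XPK.km.Xu5P", "PhaC.c_bind"))
  f <- fit_parameters(net_full, list(ds), spec, p_true, n_starts = 1,
                      maxiter = 3)
  expect_lt(f$loss, 1e-6)
  expect_equal(unname(f$estimate["XPK.km.Xu5P"]),
               param_get(p_true, "XPK.km.Xu5P"), tolerance = 1e-3)
  expect_lte(f$loss, f$start_loss)
})

test_that("fit bounds and start validation are enforced", {
  expect_error(fit_spec(character()), "non-empty")
  expect_error(fit_spec("XPK.km.Xu5P", lower = -1), "positive")
  ds <- generate_timecourse(net_full, p_true, sc_cal,
                            design_spec(c(0, 2)), noise_model(0, 0), seed = 1)
  spec <- fit_spec("XPK.km.Xu5P", lower = 10, upper = 100)
  expect_error(fit_parameters(net_full, list(ds), spec, p_true),
               "outside bounds")
})

test_that("goodness-of-fit reports zero RMSE for a perfect fit and matches a
           direct recomputation", {
  ds <- generate_timecourse(net_full, p_true, sc_cal, des_cal,
                            noise_model(0, 0), seed = 2)
  rep0 <- compare_fit(p_true, net_full, list(ds))
  expect_true(all(rep0$rmse$rmse_mM < 1e-5))

  ds2 <- ds
  ds2$value_mM <- ds$value_mM + 1        # constant offset on every replicate
  rep1 <- compare_fit(p_true, net_full, list(ds2))
  expect_equal(rep1$rmse$rmse_mM, rep(1, nrow(rep1$rmse)), tolerance = 1e-4)
  # overlay table recomputes the same residuals
  expect_equal(rep1$overlay$data_mM - rep1$overlay$model_mM,
               rep(1, nrow(rep1$overlay)), tolerance = 1e-4)
})

test_that("fits are seed-reproducible", {
  ds <- generate_timecourse(net_full, p_true, sc_cal,
                            design_spec(c(0, 1, 2)), noise_model(), seed = 4)
  spec <- fit_spec("XPK.km.Xu5P")
  start <- param_set(p_true, "XPK.km.Xu5P", 0.6)
  # maxiter deliberately tiny: the iteration-cap warning is expected
  f1 <- suppressWarnings(fit_parameters(net_full, list(ds), spec, start,
                                        n_starts = 2, seed = 10, maxiter = 4))
  f2 <- suppressWarnings(fit_parameters(net_full, list(ds), spec, start,
                                        n_starts = 2, seed = 10, maxiter = 4))
  expect_identical(f1$estimate, f2$estimate)
  expect_identical(f1$loss, f2$loss)
})
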