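test_that("plateau baseline removes a constant offset", {
  flat <- itc_thermogram(rep(1.3, 20), itc_protocol())
  corr <- baseline_correct(flat, "plateau")
  expect_equal(corr$heat_ucal, rep(0, 20))

  tg <- gen_itc_thermogram(10, binding_params(kd = 8e-6, dh = -10000,
                                              baseline = 0.4),
                           sigma_heat = 0)
  corr2 <- baseline_correct(tg, "plateau")
  ideal <- itc_heats(binding_params(kd = 8e-6, dh = -10000))
  # the plateau estimate absorbs the offset plus the small residual heat of
  # the final injections
  resid_plateau <- mean(tail(ideal$heat_ucal, 3))
  expect_equal(corr2$heat_ucal, ideal$heat_ucal - resid_plateau,
               tolerance = 1e-9)
})

test_that("unsaturated curves trigger the plateau warning; buffer mode fixes them", {
  tg <- gen_itc_thermogram(11, binding_params(kd = 62e-6, dh = -10000,
                                              baseline = 0.4),
                           sigma_heat = 0)
  expect_warning(baseline_correct(tg, "plateau"), "buffer")
  buf <- itc_thermogram(rep(0.4, 20), itc_protocol())
  corr <- baseline_correct(tg, "buffer", buffer_run = buf)
  ideal <- itc_heats(binding_params(kd = 62e-6, dh = -10000))
  expect_equal(corr$heat_ucal, ideal$heat_ucal, tolerance = 1e-9)

  other <- itc_thermogram(rep(0.4, 10), itc_protocol(n_inj = 10))
  expect_error(baseline_correct(tg, "buffer", buffer_run = other),
               class = "nrpsdock_protocol_error")
  expect_error(baseline_correct(tg, "buffer"),
               class = "nrpsdock_value_error")
})

test_that("one-site fit recovers noise-free truth exactly", {
  tg <- gen_itc_thermogram(12, binding_params(n = 1, kd = 8e-6, dh = -10000),
                           sigma_heat = 0)
  fit <- fit_one_site(baseline_correct(tg, "plateau"))
  expect_lt(abs(fit$kd - 8e-6) / 8e-6, 0.01)
  expect_lt(abs(fit$n - 1), 0.01)
  expect_lt(abs(fit$dh - (-10000)) / 10000, 0.01)
  expect_equal(fit$verdict, "reliable")
  expect_equal(fit$c_value, c_value(fit$n, fit$kd, 50e-6))
  # fixed-n mode agrees
  fit1 <- fit_one_site(baseline_correct(tg, "plateau"), float_n = FALSE)
  expect_lt(abs(fit1$kd - 8e-6) / 8e-6, 0.01)
})

test_that("the verdict is gated by c alone, not by fit quality", {
  # weak binding fitted essentially perfectly (zero noise) is still
  # qualitative because c < 1
  buf <- itc_thermogram(rep(0, 20), itc_protocol())
  tw <- gen_itc_thermogram(13, binding_params(kd = 100e-6, dh = -10000),
                           sigma_heat = 0)
  fw <- fit_one_site(baseline_correct(tw, "buffer", buffer_run = buf),
                     float_n = FALSE)
  expect_lt(fw$rss, 1e-6)
  expect_equal(fw$verdict, "weak_qualitative")
  # strong binding fitted with visible noise is still reliable
  ts <- gen_itc_thermogram(14, binding_params(kd = 8e-6, dh = -10000),
                           sigma_heat = 0.3)
  fs <- fit_one_site(baseline_correct(ts, "plateau"))
  expect_gt(fs$rss, 0.1)
  expect_equal(fs$verdict, "reliable")
})

test_that("a zero-enthalpy thermogram is flagged unidentifiable", {
  tz <- gen_itc_thermogram(15, binding_params(kd = 8e-6, dh = 0),
                           sigma_heat = 0)
  expect_warning(fz <- fit_one_site(baseline_correct(tz, "plateau")),
                 "unidentifiable")
  expect_false(fz$identifiable)
  expect_true(is.na(fz$kd))
})

test_that("noisy Kd recovery is unbiased enough across replicates", {
  errs <- vapply(1:10, function(s) {
    tg <- gen_itc_thermogram(300 + s,
                             binding_params(n = 1, kd = 8e-6, dh = -10000),
                             sigma_heat = 0.2)
    fit <- fit_one_site(suppressWarnings(baseline_correct(tg, "plateau")))
    abs(fit$kd - 8e-6) / 8e-6
  }, 0)
  expect_lt(median(errs), 0.15)
})

test_that("replicate summaries follow the mean +/- SD convention", {
  fits <- lapply(1:3, function(s) {
    tg <- gen_itc_thermogram(400 + s,
                             binding_params(n = 1, kd = 8e-6, dh = -10000),
                             sigma_heat = 0.2, label = "C-NDD/B-CDD")
    fit_one_site(suppressWarnings(baseline_correct(tg, "plateau")))
  })
  summ <- replicate_summary(fits)
  expect_equal(summ$n_replicates, 3)
  expect_lt(abs(summ$kd_mean - 8e-6), 2 * max(summ$kd_sd, 1e-7))

  same <- replicate_summary(list(fits[[1]], fits[[1]], fits[[1]]))
  expect_equal(same$kd_sd, 0)

  other <- fits[[2]]
  other$label <- "B-NDD/B-CDD"
  expect_error(replicate_summary(list(fits[[1]], other)),
               class = "nrpsdock_pairing_error")
})

test_that("tidy and glance expose the fit in broom style", {
  tg <- gen_itc_thermogram(16, binding_params(kd = 8e-6, dh = -10000),
                           sigma_heat = 0)
  fit <- fit_one_site(baseline_correct(tg, "plateau"))
  td <- tidy(fit)
  expect_equal(td$term, c("n", "kd", "dh", "baseline"))
  expect_true(all(c("estimate", "std.error") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$verdict, "reliable")
  expect_s3_class(autoplot(fit), "ggplot")
})
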