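test_that("calibration forward and inverse are exact round trips", {
  cv <- default_igg_calibration()
  cc <- seq(0, 5e-8, length.out = 20)
  expect_equal(as.numeric(concentration(cv, predict(cv, cc))), cc,
               tolerance = 1e-9)
  lv <- default_lactate_calibration()
  cu <- seq(0, 60, length.out = 20)
  expect_equal(as.numeric(concentration(lv, predict(lv, cu))), cu,
               tolerance = 1e-9)
})

test_that("readouts below baseline clamp to zero concentration with a flag", {
  cv <- default_igg_calibration()
  z <- concentration(cv, 0.5)  # below baseline 1.0
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "clamped"))
  expect_false(attr(concentration(cv, 2), "clamped"))
})

test_that("IgG calibration fit recovers exact-model standards", {
  true <- calibration_curve("igg_relocation", baseline = 1.2, span = 3.5,
                            c0 = 2e-8)
  st <- generate_calibration_standards(
    true, c(0, 5e-9, 1e-8, 2e-8, 4e-8, 8e-8), replicates = 2, seed = 2)
  fit <- fit_igg_calibration(st)
  expect_equal(unname(coef(fit)), unname(coef(true)), tolerance = 1e-6)
  expect_error(fit_igg_calibration(st[st$concentration > 0, ]), "including 0")
})

test_that("non-monotone standards raise the fit warning flag", {
  true <- default_igg_calibration()
  st <- generate_calibration_standards(true, c(0, 1e-8, 2e-8, 4e-8),
                                       replicates = 3, seed = 3)
  st$readout[st$concentration == 4e-8] <- 0.5  # collapse the top standard
  expect_warning(fit <- fit_igg_calibration(st), "non-monotone")
  expect_true(fit$fit$monotone_warning)
})

test_that("lactate fit anchors the intercept on the blank standards", {
  true <- default_lactate_calibration()
  st <- generate_calibration_standards(true, c(0, 10, 25, 50),
                                       replicates = 3, noise_sd = 2,
                                       seed = 4)
  fit <- fit_lactate_calibration(st)
  expect_equal(coef(fit)[["intercept"]],
               mean(st$readout[st$concentration == 0]))
  expect_equal(coef(fit)[["slope"]], 20, tolerance = 0.05)
})

test_that("unit chain: 1 pM per 10 min in 50 pL is about 0.05 molecules/s", {
  cv <- default_igg_calibration()
  conc <- c(0, 1e-12, 2e-12, 3e-12, 4e-12, 5e-12)  # +1 pM per frame
  tr <- data.frame(droplet_id = 1L, frame = 1:6, time_s = (0:5) * 600,
                   channel = "a647", droplet_mean = 500,
                   beadline_mean = predict(cv, conc) * 500,
                   cell_mean = NA_real_, n_cells = 1L,
                   condition = "c", track_quality = "ok")
  est <- igg_secretion_rate(tr)
  expect_equal(est$rate, 1e-12 * 5e-11 * 6.02214076e23 / 600,
               tolerance = 1e-6)
  expect_equal(est$rate, 0.0502, tolerance = 1e-3)
})

test_that("planted IgG rates are recovered on noiseless traces", {
  rates <- c(20, 50, 150, 280)
  ph <- do.call(rbind, lapply(rates, function(r) one_droplet(igg = r)))
  ts <- quiet_traces(ph)
  est <- igg_secretion_rate(ts$traces)
  expect_equal(est$rate, rates, tolerance = 0.02)
  expect_true(all(est$gate %in% c("igg_sc")))
  expect_true(all(est$in_quant_range[rates < 285]))
})

test_that("IgG gate boundaries honor the LoD (included) and upper bound", {
  ph <- rbind(one_droplet(igg = 5), one_droplet(igg = 9.000001),
              one_droplet(igg = 100), one_droplet(igg = 290))
  ts <- quiet_traces(ph)
  est <- igg_secretion_rate(ts$traces)
  expect_identical(est$gate, c("below_lod", "igg_sc", "igg_sc",
                               "above_range"))
  expect_identical(est$in_quant_range, c(FALSE, TRUE, TRUE, FALSE))
  # the alternate printed upper bound is available via configuration
  est258 <- igg_secretion_rate(ts$traces,
                               constants = assay_constants(igg_upper = 258))
  expect_identical(est258$gate[4], "above_range")
})

test_that("constant relocation gives zero rate below the LoD", {
  ts <- quiet_traces(one_droplet(igg = 0))
  est <- igg_secretion_rate(ts$traces)
  expect_equal(est$rate, 0)
  expect_identical(est$gate, "below_lod")
})

test_that("NOX-positive droplets get no IgG rate", {
  ph <- rbind(one_droplet(igg = 50, nox = TRUE, loss = 30),
              one_droplet(igg = 50))
  ts <- quiet_traces(ph)
  calls <- classify_nox(signal_loss_table(ts$traces))
  est <- igg_secretion_rate(ts$traces, nox_calls = calls)
  expect_identical(est$gate[1], "igg_uninterpretable")
  expect_true(is.na(est$rate[1]))
  expect_equal(est$rate[2], 50, tolerance = 0.02)
})

test_that("planted lactate rates are recovered and gated", {
  ph <- rbind(one_droplet(lactate = 0.05), one_droplet(lactate = 0.4),
              one_droplet(lactate = 0.85))
  ts <- quiet_traces(ph)
  est <- lactate_secretion_rate(ts$traces)
  expect_equal(est$rate, c(0.05, 0.4, 0.85), tolerance = 0.02)
  expect_identical(est$gate, c("below_lod", "in_range", "above_range"))
})

test_that("multi-cell droplets are excluded from lactate rates", {
  ph <- rbind(one_droplet(lactate = 0.4),
              one_droplet(n_cells = 2, lactate = 0.4))
  ts <- quiet_traces(ph)
  est <- lactate_secretion_rate(ts$traces)
  expect_identical(est$gate[2], "excluded_multicell")
  expect_true(is.na(est$rate[2]))
})

test_that("flat lactate trace yields a zero rate", {
  ts <- quiet_traces(one_droplet(lactate = 0))
  expect_equal(lactate_secretion_rate(ts$traces)$rate, 0)
})

test_that("ROS slope averages increases up to the signal maximum", {
  expect_equal(ros_slope(rep(100, 6), 600), 0)
  expect_equal(ros_slope(c(100, 130, 160, 190, 220, 250), 600), 30)
  # falling tail after the max is ignored
  expect_equal(ros_slope(c(100, 120, 140, 160, 150, 130), 600), 20)
  # maximum at the first frame
  expect_equal(ros_slope(c(200, 150, 120), 600), 0)
  # 12-minute frames rescale to the 10-minute window
  expect_equal(ros_slope(c(100, 136, 172), 720), 30)
  expect_error(ros_slope(5), "frames")
})

test_that("estimates are monotone in the planted rate on noiseless data", {
  igg_rates <- seq(5, 280, length.out = 12)
  lac_rates <- seq(0.05, 0.9, length.out = 12)
  ph <- do.call(rbind, lapply(seq_along(igg_rates), function(i)
    one_droplet(igg = igg_rates[i], lactate = lac_rates[i])))
  ts <- quiet_traces(ph)
  expect_true(all(diff(igg_secretion_rate(ts$traces)$rate) > 0))
  expect_true(all(diff(lactate_secretion_rate(ts$traces)$rate) > 0))
})

test_that("recovery under realistic noise keeps median error small", {
  n <- 200
  set.seed(31)
  ph <- do.call(rbind, lapply(seq_len(n), function(i)
    one_droplet(igg = runif(1, 9, 285), lactate = runif(1, 0.1, 0.8),
                ros = runif(1, 5, 50))))
  ts <- generate_trace_set(chamber_spec(n), acquisition_spec(noise_sd = 5),
                           ph, seed = 31)
  igg <- igg_secretion_rate(ts$traces)
  lac <- lactate_secretion_rate(ts$traces)
  expect_lt(median(abs(igg$rate - ph$igg_rate) / ph$igg_rate), 0.15)
  expect_lt(median(abs(lac$rate - ph$lactate_rate) / ph$lactate_rate), 0.15)
})

test_that("joint table merges phenotypes and warns on disjoint ids", {
  ph <- rbind(one_droplet(nox = TRUE, loss = 30, lactate = 0.6, ros = 40),
              one_droplet(igg = 60, lactate = 0.2, ros = 10))
  ts <- quiet_traces(ph)
  calls <- classify_nox(signal_loss_table(ts$traces))
  igg <- igg_secretion_rate(ts$traces, nox_calls = calls)
  lac <- lactate_secretion_rate(ts$traces)
  ros <- ros_slope_table(ts$traces)
  j <- joint_phenotype_table(calls, igg, lac, ros)
  expect_equal(nrow(j), 2)
  expect_true(is.na(j$igg_rate[j$label == "NOX_drop_pos"]))
  expect_equal(j$ros_slope, c(40, 10), tolerance = 1e-9)
  bad <- igg; bad$droplet_id <- bad$droplet_id + 100
  expect_warning(joint_phenotype_table(calls, bad), "no shared")
})
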