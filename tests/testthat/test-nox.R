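test_that("signal loss follows the first-to-lowest formula", {
  expect_equal(signal_loss(c(200, 190, 170, 180, 185, 190))$x_pct, 15.0)
  expect_equal(signal_loss(rep(100, 6))$x_pct, 0.0)
  expect_equal(signal_loss(c(100, 105, 110))$x_pct, -5.0)
  # the lowest value is searched from the second frame on only
  expect_equal(signal_loss(c(50, 100, 80))$x_pct, -60)
})

test_that("signal loss rejects degenerate traces", {
  expect_error(signal_loss(100), "frames")
  expect_error(signal_loss(c(0, 10, 20)), "first-frame")
  expect_error(signal_loss(c(-5, 10)), "first-frame")
})

test_that("loss is invariant to positive rescaling of the trace", {
  set.seed(42)
  for (i in 1:25) {
    tr <- runif(6, 50, 500)
    s <- runif(1, 0.01, 100)
    expect_equal(signal_loss(tr * s)$x_pct, signal_loss(tr)$x_pct,
                 tolerance = 1e-9)
  }
})

test_that("formula identity holds when recomputing from components", {
  set.seed(7)
  for (i in 1:20) {
    r <- signal_loss(runif(5, 10, 300))
    expect_identical(r$x_pct,
                     100 * (r$signal_t1 - r$signal_lowest) / r$signal_t1)
  }
})

test_that("control threshold is median plus three sample SDs", {
  m <- fit_threshold(c(1, 2, 3))
  expect_equal(m$threshold_pct, 5.0)
  expect_equal(m$median_pct, 2)
  expect_equal(m$sd_pct, 1)
  expect_identical(m$source, "control_derived")
  # zero spread collapses the threshold onto the common value
  expect_equal(fit_threshold(rep(7.5, 10))$threshold_pct, 7.5)
  expect_error(fit_threshold(4.2), "fixed_threshold")
})

test_that("the fixed default threshold is 10.3 percent", {
  m <- fixed_threshold()
  expect_equal(m$threshold_pct, 10.3)
  expect_identical(m$source, "fixed")
})

test_that("classification is strictly greater-than the threshold", {
  m <- fixed_threshold()
  expect_identical(classify_nox(15.0, m), "NOX_drop_pos")
  expect_identical(classify_nox(10.3, m), "NOX_drop_neg")
  expect_identical(classify_nox(10.3 + 1e-9, m), "NOX_drop_pos")
  expect_identical(classify_nox(-5.0, m), "NOX_drop_neg")
})

test_that("noiseless losses above threshold always classify positive", {
  losses <- seq(10.4, 95, by = 5)
  ph <- do.call(rbind, lapply(losses, function(L)
    one_droplet(nox = TRUE, loss = L)))
  ts <- generate_trace_set(chamber_spec(nrow(ph)),
                           acquisition_spec(noise_sd = 0), ph, seed = 1)
  calls <- classify_nox(signal_loss_table(ts$traces))
  expect_true(all(calls$label == "NOX_drop_pos"))
})

test_that("planted NOX frequency is recovered under modest noise", {
  n <- 8000
  ph <- sample_phenotypes(n, lambda_occupancy = 0.3, nox_fraction = 0.3,
                          terminal_loss_mean = 20, seed = 13)
  ts <- generate_trace_set(chamber_spec(n), acquisition_spec(), ph,
                           seed = 13)
  calls <- classify_nox(signal_loss_table(ts$traces))
  freq <- nox_frequency(calls, ts$truth)
  n_cell <- sum(ph$n_cells >= 1)
  planted <- 100 * mean(ph$nox_active[ph$n_cells >= 1])
  se <- 100 * sqrt(0.3 * 0.7 / n_cell)
  expect_equal(freq$n_total, n_cell)
  expect_lt(abs(freq$pct_pos - planted), 3 * se)
})

test_that("scavenger-like null condition stays below one percent positive", {
  ts <- null_chamber(2000, seed = 17)
  calls <- classify_nox(signal_loss_table(ts$traces))
  freq <- nox_frequency(calls, ts$truth)
  expect_lte(freq$pct_pos, 1)
})

test_that("frequency excludes non-ok tracks and reports NA when undefined", {
  calls <- data.frame(droplet_id = 1:4,
                      label = c("NOX_drop_pos", "NOX_drop_pos",
                                "NOX_drop_neg", "NOX_drop_neg"))
  drops <- data.frame(droplet_id = 1:4, n_cells = c(1, 1, 1, 0),
                      track_quality = c("ok", "tracking_failed", "ok", "ok"),
                      condition = c("a", "a", "a", "b"))
  f <- nox_frequency(calls, drops)
  expect_equal(f$n_total[f$condition == "a"], 2)  # failed track dropped
  expect_equal(f$pct_pos[f$condition == "a"], 50)
  expect_true(is.na(f$pct_pos[f$condition == "b"]))  # no cell droplets
})

test_that("condition contrasts dispatch to Welch t and Welch/BF ANOVA", {
  two <- data.frame(condition = rep(c("a", "b"), each = 4),
                    pct_pos = c(10, 11, 9, 10.5, 60, 61, 58, 59))
  r2 <- condition_contrast(two, value = "pct_pos")
  expect_identical(r2$test, "Welch t-test")
  expect_lt(r2$p, 0.05)

  same <- data.frame(condition = rep(c("a", "b"), each = 3),
                     pct_pos = rep(c(10, 12, 11), 2))
  expect_gt(condition_contrast(same, value = "pct_pos")$p, 0.99)

  three <- data.frame(condition = rep(c("a", "b", "c"), each = 3),
                      pct_pos = c(10, 11, 9, 30, 31, 29, 60, 61, 59))
  r3 <- condition_contrast(three, value = "pct_pos")
  expect_match(r3$test, "ANOVA")
  expect_lt(r3$p, 0.05)
  expect_false(is.null(r3$brown_forsythe))

  single <- data.frame(condition = c("a", "b"), pct_pos = c(1, 2))
  expect_true(is.na(condition_contrast(single, value = "pct_pos")$p))
})

test_that("Brown-Forsythe means test approaches classic ANOVA when balanced", {
  set.seed(5)
  v <- rnorm(60, rep(c(0, 1, 2), each = 20))
  g <- rep(letters[1:3], each = 20)
  bf <- dropnox:::brown_forsythe_anova(v, g)
  cl <- summary(aov(v ~ factor(g)))[[1]]
  expect_equal(bf$statistic, cl[["F value"]][1], tolerance = 0.15)
  expect_lt(bf$p.value, 0.001)
})
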