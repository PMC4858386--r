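# Concentration-model fitting and surface building.

test_that("THM model recovers monthly means generated from its own family", {
  set.seed(21)
  d <- gen_thm_family(n = 400)
  fit <- fit_thm_model(d, "TTHM")
  grid <- expand.grid(wsz_id = c("Z1", "Z2"),
                      time_cell = cell_seq("2008-01", "2009-12"),
                      stringsAsFactors = FALSE)
  pred <- predict(fit, grid)
  month <- as.integer(substr(grid$time_cell, 6, 7))
  truth <- gen_thm_truth(match(grid$wsz_id, c("Z1", "Z2")), month)
  expect_true(all(abs(pred / truth - 1) < 0.10))
  # zone offset of +0.5 on the log scale appears as a ratio of e^0.5
  z1 <- pred[grid$wsz_id == "Z1"]; z2 <- pred[grid$wsz_id == "Z2"]
  expect_equal(mean(z2 / z1), exp(0.5), tolerance = 0.05)
})

test_that("constant-valued data give a flat surface at that constant", {
  dates <- rep(seq(as.Date("2008-01-10"), as.Date("2009-12-10"), by = "month"),
               2)
  d <- mk_samples(42, sample_date = dates,
                  wsz_id = rep(c("Z1", "Z2"), each = length(dates) / 2))
  # perfect fit on the log scale; summary.lm warns about it, which is the point
  fit <- suppressWarnings(fit_thm_model(d, "TTHM"))
  s <- build_surface(fit)
  expect_equal(s$pred_ugL, rep(42, nrow(s)), tolerance = 1e-8)
  expect_true(all(s$provenance == "fitted"))
})

test_that("degenerate designs and disallowed analytes are refused", {
  d <- mk_samples(c(40, 41), sample_date = as.Date(c("2008-03-01", "2009-03-01")),
                  wsz_id = c("Z1", "Z2"))
  expect_error(fit_thm_model(d, "TTHM"), "singular|zones")
  expect_error(fit_thm_model(gen_thm_family(50), "bromoform"), "THMBr")
  expect_error(fit_thm_model(gen_thm_family(50), "DCAA"), "not a modellable")
})

test_that("generating coefficients are recovered within 95% CIs ~95% of the time", {
  set.seed(77)
  hits <- 0L
  for (r in 1:100) {
    d <- gen_thm_family(n = 150, zone_off = c(0, 0.4), amp = 0.15, sd = 0.12)
    fit <- fit_thm_model(d, "TTHM", month_df = 3)
    ci <- confint(fit$fit)[".wszZ2", ]
    hits <- hits + (ci[1] <= 0.4 && 0.4 <= ci[2])
  }
  expect_gte(hits, 90)
})

test_that("HAA monitoring grid: 8 zones x 63 months arithmetic", {
  set.seed(5)
  d <- gen_thm_family(n = 800, zone_off = seq(-0.07, 0.07, length.out = 8),
                      years = 2006:2010)
  d <- rbind(d, gen_thm_family(n = 60, zone_off = seq(-0.07, 0.07, length.out = 8),
                               years = 2011))
  d$sample_date[d$sample_date >= as.Date("2011-04-01")] <-
    as.Date("2011-02-15")  # keep 2011 inside Q1
  fit <- fit_thm_model(d, "TTHM")
  s <- build_surface(fit, cells = cell_seq("2006-01", "2011-03"))
  expect_equal(nrow(s), 8 * 63)
  expect_true(all(s$pred_ugL > 0))
})

test_that("frequentist HAA model recovers a known conductivity effect", {
  set.seed(31)
  cfg <- scenario_config(seed = 31)
  mon <- substitute_half_lod(simulate_monitoring(cfg))
  fit <- fit_haa_model(mon, "DCAA", mode = "frequentist")
  est <- coef(fit)[["conductivity"]]
  se <- summary(fit$fit)$coefficients["conductivity", "Std. Error"]
  expect_lt(abs(est - cfg$haa_coef$DCAA[["conductivity"]]), 2 * se)
  expect_error(fit_haa_model(mon, "TTHM"), "not an HAA")
})

test_that("Bayesian HAA model imputes missing covariates and recovers effects", {
  set.seed(32)
  cfg <- scenario_config(seed = 32, haa_covariate_missing = 0.20)
  mon <- substitute_half_lod(simulate_monitoring(cfg))
  d <- mon[mon$analyte == "DCAA", ]
  expect_gt(mean(is.na(d$conductivity)), 0.1)  # missingness really present
  cells <- sort(unique(time_cell(d$sample_date, "quarter")))
  fit <- fit_haa_model(d, "DCAA", mode = "bayesian", grid_cells = cells,
                       seed = 32)
  expect_true(fit$converged)
  # posterior surface exists for every (zone, quarter) despite missing data
  s <- build_surface(fit, cells = cells)
  expect_equal(nrow(s), length(cfg$zones) * length(cells))
  expect_true(all(is.finite(s$pred_ugL)) && all(s$pred_ugL > 0))
  # raw-scale conductivity coefficient within 2 posterior SDs of truth
  g <- fit$gamma[fit$gamma$covariate == "conductivity", ]
  expect_lt(abs(g$mean_raw - cfg$haa_coef$DCAA[["conductivity"]]),
            2 * g$sd_raw)
})

test_that("near-zero-noise data reproduce the generating surface closely", {
  set.seed(33)
  cfg <- scenario_config(seed = 33, haa_noise = c(DCAA = 1e-3, TCAA = 1e-3,
                                                  BDCAA = 1e-3),
                         haa_zone_sd = 0, haa_covariate_missing = 0)
  mon <- substitute_half_lod(simulate_monitoring(cfg))
  d <- mon[mon$analyte == "TCAA", ]
  cells <- sort(unique(time_cell(d$sample_date, "quarter")))
  fit <- fit_haa_model(d, "TCAA", mode = "bayesian", grid_cells = cells,
                       seed = 33)
  s <- build_surface(fit, cells = cells)
  # generating value at each sampled point (transform-scale linear predictor)
  idx <- match(paste(d$wsz_id, time_cell(d$sample_date, "quarter")),
               paste(s$wsz_id, s$time_cell))
  eta <- sqrt(cfg$haa_means[["TCAA"]]) +
    cfg$haa_coef$TCAA[["conductivity"]] * (d$conductivity - 250) +
    cfg$haa_coef$TCAA[["temperature"]] * (d$temperature - 12) +
    cfg$haa_coef$TCAA[["toc"]] * (d$toc - 1.5)
  expect_lt(stats::median(abs(s$pred_ugL[idx] / eta^2 - 1)), 0.01)
})

test_that("excluded and extrapolated cells are produced and flagged", {
  set.seed(34)
  cfg <- scenario_config(seed = 34)
  mon <- simulate_monitoring(cfg)
  res <- fit_concentration_surface(
    mon, "DCAA", "quarter", mode = "bayesian",
    grid_cells = cell_seq("2007Q2", "2010Q4"),
    exclude_cells = "2009Q2",
    extrapolate_cells = c("2007Q1", "2011Q1"), seed = 34)
  s <- res$surface
  expect_setequal(unique(s$time_cell), cell_seq("2007Q1", "2011Q1"))
  expect_true(all(s$provenance[s$time_cell == "2009Q2"] == "gap_filled"))
  expect_true(all(s$provenance[s$time_cell %in% c("2007Q1", "2011Q1")] ==
                    "extrapolated"))
  expect_true(all(s$provenance[!s$time_cell %in%
                                 c("2009Q2", "2007Q1", "2011Q1")] == "fitted"))
  expect_true(all(s$pred_ugL > 0))
  # the 2009Q2 gap-fill interpolates sensibly between its neighbours
  q <- function(cell) mean(s$pred_ugL[s$time_cell == cell])
  expect_lt(abs(q("2009Q2") - (q("2009Q1") + q("2009Q3")) / 2),
            0.25 * q("2009Q2"))
})

test_that("extrapolation beyond one grid step is refused", {
  set.seed(35)
  d <- gen_thm_family(n = 200, years = 2008:2009)
  fit <- fit_thm_model(d, "TTHM")
  expect_error(build_surface(fit, extrapolation = "2010-03"),
               "one grid step")
  # excluded cells must not have been trained on
  expect_error(build_surface(fit, exclusions = "2008-06"),
               "training data")
})

test_that("with no exclusions the surface equals direct model prediction", {
  set.seed(36)
  d <- gen_thm_family(n = 300)
  fit <- fit_thm_model(d, "TTHM")
  s <- build_surface(fit)
  direct <- predict(fit, s[c("wsz_id", "time_cell")])
  expect_equal(s$pred_ugL, direct, tolerance = 1e-12)
  expect_true(all(s$provenance == "fitted"))
})

test_that("surfaces round-trip through CSV", {
  set.seed(37)
  fit <- fit_thm_model(gen_thm_family(300), "TTHM")
  s <- build_surface(fit)
  path <- tempfile(fileext = ".csv")
  write_surface(s, path)
  s2 <- read_surface(path)
  expect_equal(s2$pred_ugL, s$pred_ugL)
  expect_equal(attr(s2, "resolution"), "month")
  unlink(path)
})
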