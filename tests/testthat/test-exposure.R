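# TWA concentrations, ingestion, integrated uptake, categorization and
# metric correlations.

test_that("work/residence weighting follows the 72/112 + 40/112 split", {
  win <- exposure_window("whole", as.Date("2008-04-01"), as.Date("2008-12-20"))
  s <- constant_surface(c(56, 0))  # Z1 = 56, Z2 = 0
  # employed, workplace zone with zero concentration
  expect_equal(twa_concentration(s, win, "Z1", "Z2"), 56 * 72 / 112)
  # equal concentrations: the weighting cannot matter
  s2 <- constant_surface(c(47.3, 47.3))
  expect_equal(twa_concentration(s2, win, "Z1", "Z2"), 47.3)
  # non-employed woman gets the pure residence value
  s3 <- constant_surface(c(45.6, 0))
  expect_equal(twa_concentration(s3, win, "Z1", NA), 45.6)
})

test_that("TWA is missing (not zero) when coverage is incomplete", {
  win <- exposure_window("whole", as.Date("2007-10-01"), as.Date("2008-06-20"))
  s <- constant_surface(50, cells = cell_seq("2008-01", "2009-12"))
  expect_true(is.na(twa_concentration(s, win, "Z1", NA)))
  expect_true(is.na(twa_concentration(s, win, "ZX", NA)))  # unknown zone
})

test_that("TWA of a constant surface is the constant and scales linearly", {
  set.seed(8)
  for (i in 1:10) {
    conc <- as.Date("2008-03-01") + sample.int(300, 1)
    win <- exposure_window("whole", conc, conc + sample(260:290, 1))
    s <- constant_surface(45.6, cells = cell_seq("2008-01", "2009-12"))
    expect_equal(twa_concentration(s, win, "Z1", NA), 45.6)
    k <- runif(1, 0.5, 3)
    sk <- s; sk$pred_ugL <- sk$pred_ugL * k
    expect_equal(twa_concentration(sk, win, "Z1", NA),
                 k * twa_concentration(s, win, "Z1", NA))
  }
})

test_that("boiling and filtering adjustments are applied exactly", {
  f <- uptake_factor_table()
  # published constants
  expect_equal(unname(f$boil_adjust[c("TTHM", "DCAA", "TCAA", "BDCAA")]),
               c(-0.92, 0.435, -0.369, -0.565))
  expect_equal(unname(f$filter_adjust[c("TTHM", "DCAA", "TCAA", "BDCAA")]),
               c(-0.90, -0.618, -0.674, -0.785))
  # 1 L/day hot beverage at TTHM 50 ug/L -> 4.0 ug/day
  hot <- water_use_profile(tea_Lday = 1)
  expect_equal(unname(ingestion(hot, c(TTHM = 50), f)["TTHM"]), 4.0)
  # 1 L/day hot beverage at DCAA 10 ug/L -> 14.35 ug/day
  expect_equal(unname(ingestion(hot, c(DCAA = 10), f)["DCAA"]), 14.35)
  # filtering hits the tap component only; squash stays unfiltered
  filt <- water_use_profile(tap_Lday = 1, squash_Lday = 1, filter_home = TRUE)
  expect_equal(unname(ingestion(filt, c(TTHM = 10), f)["TTHM"]),
               10 * (1 * 0.10 + 1))
  unfilt <- water_use_profile(tap_Lday = 1, squash_Lday = 1)
  expect_equal(unname(ingestion(unfilt, c(TTHM = 10), f)["TTHM"]), 20)
})

test_that("ingestion aggregates and degenerate cases behave", {
  f <- uptake_factor_table()
  prof <- water_use_profile(tap_Lday = 1.5, bottled_Lday = 2)
  twa <- c(TTHM = 40, DCAA = 8, TCAA = 12, BDCAA = 1)
  ing <- ingestion(prof, twa, f)
  expect_equal(unname(ing["HAA3"]), unname(sum(ing[c("DCAA", "TCAA", "BDCAA")])))
  expect_equal(unname(ing["DBP7"]), unname(ing["TTHM"] + ing["HAA3"]))
  # bottled water contributes nothing: same result without it
  prof2 <- water_use_profile(tap_Lday = 1.5)
  expect_equal(ingestion(prof2, twa, f), ing)
  # all volumes zero -> all metrics zero
  ing0 <- ingestion(water_use_profile(), twa, f)
  expect_true(all(ing0 == 0))
  expect_error(water_use_profile(tap_Lday = -1), "nonnegative")
})

test_that("integrated uptake is the pathway sum with correct unit handling", {
  f <- uptake_factor_table(ingestion = 0.005, shower = 0.001, bath = 0.001,
                           swim = 0.001, pool_tthm = 100)
  # 70 min/week showering at TWA 50 and factor 0.001 -> 50 * 0.001 * 10 = 0.5
  prof <- water_use_profile(shower_minwk = 70)
  up <- integrated_uptake(prof, c(TTHM = 50), f)
  expect_equal(unname(up$pathway["shower", "TTHM"]), 0.5)
  # swimming uses the pool concentration, not the tap TWA
  swimmer <- water_use_profile(swim_minwk = 7)
  up_sw <- integrated_uptake(swimmer, c(TTHM = 0.001), f)
  expect_equal(unname(up_sw$pathway["swim", "TTHM"]), 100 * 0.001 * 1)
  # zero activity minutes: integrated equals the ingestion pathway
  drinker <- water_use_profile(tap_Lday = 2)
  up_d <- integrated_uptake(drinker, c(TTHM = 50), f)
  expect_equal(unname(up_d$integrated["TTHM"]),
               unname(up_d$pathway["ingestion", "TTHM"]))
  # doubling shower minutes doubles exactly the shower term
  prof2 <- water_use_profile(shower_minwk = 140)
  up2 <- integrated_uptake(prof2, c(TTHM = 50), f)
  expect_equal(unname(up2$pathway["shower", "TTHM"]),
               2 * unname(up$pathway["shower", "TTHM"]))
  # the invariant: integrated = sum over pathways; sbs = non-ingestion sum
  full <- water_use_profile(tap_Lday = 1, tea_Lday = 0.5, shower_minwk = 80,
                            bath_minwk = 120, swim_minwk = 30)
  upf <- integrated_uptake(full, c(TTHM = 45), f)
  expect_equal(unname(upf$integrated["TTHM"]),
               sum(upf$pathway[, "TTHM"]))
  expect_equal(unname(upf$sbs["TTHM"]),
               sum(upf$pathway[c("shower", "bath", "swim"), "TTHM"]))
  expect_error(integrated_uptake(full, c(DCAA = 8), f), "no THM analytes")
})

test_that("exposure metrics are homogeneous of degree 1 in concentration", {
  f <- uptake_factor_table()
  prof <- water_use_profile(tap_Lday = 1.2, tea_Lday = 0.4, shower_minwk = 90)
  twa <- c(TTHM = 45, DCAA = 9, TCAA = 12, BDCAA = 1.3)
  for (k in c(0.5, 2, 10)) {
    expect_equal(ingestion(prof, k * twa, f), k * ingestion(prof, twa, f))
    expect_equal(integrated_uptake(prof, k * twa, f)$integrated[["TTHM"]],
                 k * integrated_uptake(prof, twa, f)$integrated[["TTHM"]],
                 tolerance = 1e-12)
  }
})

test_that("categorization uses the stated bins and tertile rules", {
  t <- categorize(1:9, "tertile")
  expect_equal(as.integer(table(t)), c(3, 3, 3))
  expect_equal(categorize(c(0, 30, 80, 121, 120), "bath"),
               factor(c("0", "1-60", "61-120", ">120", "61-120"),
                      levels = c("0", "1-60", "61-120", ">120")))
  expect_equal(as.character(categorize(c(0, 45, 90, 110), "shower")),
               c("0", "1-60", "61-105", ">105"))
  expect_equal(as.character(categorize(c(0.4, 0.8, 1.4, 1.6), "cold_tap")),
               c("0.0-0.4", "0.6-1.0", "1.2-1.4", ">=1.6"))
  expect_equal(as.character(categorize(c(0, 20), "swim")), c("no", "yes"))
  # missing values stay missing, never binned
  expect_true(is.na(categorize(c(NA, 1, 2, 3), "tertile")[1]))
  # cutpoints reproduce an independent quantile computation
  set.seed(12)
  x <- rlnorm(1000)
  cp <- attr(categorize(x, "tertile"), "cutpoints")
  expect_equal(cp, unname(quantile(x, c(1, 2) / 3)), tolerance = 1e-12)
  # lower-closed intervals, top tertile closed: a value equal to both
  # cutpoints lands in T3 (matching ">= cutpoint" notation)
  ties <- c(1, 4, 4, 9)  # tertile cutpoints are both 4 here
  expect_equal(attr(categorize(ties, "tertile"), "cutpoints"), c(4, 4))
  expect_equal(as.character(categorize(ties, "tertile")),
               c("T1", "T3", "T3", "T3"))
})

test_that("Spearman correlations behave at the boundaries", {
  set.seed(13)
  x <- rlnorm(1000); y <- rlnorm(1000)
  m <- cbind(a = x, b = -x, c = y)
  rho <- correlate_metrics(m)
  expect_equal(diag(rho), c(a = 1, b = 1, c = 1))
  expect_equal(rho["a", "b"], -1)
  expect_lt(abs(rho["a", "c"]), 0.1)  # independent samples
  expect_equal(rho, t(rho))
  expect_warning(correlate_metrics(cbind(a = x, k = rep(1, 1000))),
                 "constant")
})

test_that("end-to-end exposure table matches hand arithmetic on constants", {
  thm_s <- rbind(constant_surface(45, "TTHM", zones = c("Z1", "Z2"),
                                  cells = cell_seq("2008-01", "2009-12")),
                 constant_surface(7.5, "THMBr", zones = c("Z1", "Z2"),
                                  cells = cell_seq("2008-01", "2009-12")))
  qcells <- cell_seq("2008Q1", "2009Q4")
  haa_s <- rbind(
    constant_surface(9, "DCAA", zones = c("Z1", "Z2"), cells = qcells),
    constant_surface(12, "TCAA", zones = c("Z1", "Z2"), cells = qcells),
    constant_surface(1.3, "BDCAA", zones = c("Z1", "Z2"), cells = qcells))
  cohort <- data.frame(
    pregnancy_id = 1:2,
    conception_date = as.Date("2008-03-01"),
    delivery_date = as.Date("2008-12-01"),
    residence_wsz = "Z1", work_wsz = c(NA, "Z2"),
    tap_Lday = 1, squash_Lday = 0, tea_Lday = 1, coffee_Lday = 0,
    bottled_Lday = 0, filter_home = FALSE,
    shower_minwk = 0, bath_minwk = 0, swim_minwk = 0,
    stringsAsFactors = FALSE)
  f <- uptake_factor_table()
  ex <- compute_exposure(cohort, thm_s, haa_s, f, windows = c("whole", "T1"))
  expect_equal(nrow(ex), 4)
  w1 <- ex[ex$pregnancy_id == 1 & ex$window == "whole", ]
  expect_equal(w1$twa_TTHM, 45)
  # 1 L cold + 1 L boiled at TTHM 45: 45 * (1 + 0.08) = 48.6
  expect_equal(w1$ing_TTHM, 45 * (1 + (1 - 0.92)))
  expect_equal(w1$ing_DCAA, 9 * (1 + (1 + 0.435)))
  expect_equal(w1$conc_DBP7, 45 + 9 + 12 + 1.3)
  expect_equal(w1$ing_DBP7, w1$ing_TTHM + w1$ing_DCAA + w1$ing_TCAA + w1$ing_BDCAA)
  # constant equal surfaces: the work weighting cannot change anything
  w2 <- ex[ex$pregnancy_id == 2 & ex$window == "whole", ]
  expect_equal(w2$twa_TTHM, 45)
  expect_equal(w1$sbs_TTHM, 0)
})

test_that("workplace assignment bookkeeping reports the right rate", {
  fx <- make_workplace_fixture(n_total = 100, n_employed = 40, n_assigned = 10)
  wa <- workplace_assignment(fx)
  expect_equal(wa$n_employed, 40)
  expect_equal(wa$n_assigned, 10)
  expect_equal(wa$rate_pct, 25)
})
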