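# Adjusted birth-weight models and their tests.

test_that("OLS agrees with a normal-equations oracle", {
  set.seed(61)
  d <- gen_null_data(n = 120)
  fit <- fit_bw_model(d, "exp_tert", covariates = c("age", "smoking",
                                                    "ethnicity"))
  X <- model.matrix(fit$fit)
  y <- d$birth_weight_g[as.integer(rownames(X))]
  beta_oracle <- solve(t(X) %*% X, t(X) %*% fit$fit$model$birth_weight_g)
  expect_equal(unname(coef(fit)), c(beta_oracle), tolerance = 1e-8)
})

test_that("known tertile effects are recovered on synthetic data", {
  set.seed(62)
  d <- simulate_stratum("tthm_uptake", n = 3000,
                        truth = list(up_TTHM_tert = c(T1 = 0, T2 = -20,
                                                      T3 = -55)))
  fit <- fit_bw_model(d, "up_TTHM_tert", stratum = "Pakistani_origin")
  tab <- summary(fit)
  expect_equal(tab$estimate[tab$level == "T1"], 0)
  # truth inside the 95% CI (single draw; n = 3000 gives SE ~ 20)
  expect_true(tab$ci_lo[3] <= -55 && -55 <= tab$ci_hi[3])
  expect_true(tab$ci_lo[2] <= -20 && -20 <= tab$ci_hi[2])
  # reference level difference is identically zero and CI brackets estimates
  expect_true(all(tab$ci_lo[-1] <= tab$estimate[-1] &
                    tab$estimate[-1] <= tab$ci_hi[-1]))
})

test_that("null exposure gives small estimates and sane p-values", {
  set.seed(63)
  d <- gen_null_data(n = 5000)
  fit <- fit_bw_model(d, "exp_tert",
                      covariates = c("age", "smoking", "ethnicity"))
  tab <- summary(fit)
  se <- (tab$ci_hi - tab$ci_lo)[2:3] / (2 * qt(0.975, fit$n - 20))
  expect_true(all(abs(tab$estimate[2:3]) < 3 * se))
  for (p in c(test_overall(fit), test_trend(fit), test_interaction(fit))) {
    expect_true(p > 0 && p <= 1)
  }
})

test_that("adding a constant to birth weight shifts only the intercept", {
  set.seed(64)
  d <- gen_null_data(n = 400)
  f1 <- fit_bw_model(d, "exp_tert", covariates = c("age", "smoking",
                                                   "ethnicity"))
  d2 <- d; d2$birth_weight_g <- d2$birth_weight_g + 250
  f2 <- fit_bw_model(d2, "exp_tert", covariates = c("age", "smoking",
                                                    "ethnicity"))
  cf1 <- coef(f1); cf2 <- coef(f2)
  expect_equal(cf2["(Intercept)"] - cf1["(Intercept)"], c(`(Intercept)` = 250),
               tolerance = 1e-8)
  expect_equal(cf1[-1], cf2[-1], tolerance = 1e-8)
})

test_that("trend test detects a linear dose-response and refuses 2 levels", {
  set.seed(65)
  d <- gen_null_data(n = 4000)
  d$birth_weight_g <- d$birth_weight_g -
    60 * (as.numeric(d$exp_tert) - 1)  # -60 g per tertile step
  fit <- fit_bw_model(d, "exp_tert", covariates = c("age", "smoking",
                                                    "ethnicity"))
  expect_lt(test_trend(fit), 1e-6)
  d$bin <- factor(ifelse(as.numeric(d$exp_tert) > 1, "hi", "lo"),
                  levels = c("lo", "hi"))
  fb <- fit_bw_model(d, "bin", covariates = c("age", "smoking", "ethnicity"))
  expect_error(test_trend(fb), ">= 3")
})

test_that("interaction test requires the total model and mixed ethnicity", {
  set.seed(66)
  d <- gen_null_data(n = 800)
  fit_pk <- fit_bw_model(d, "exp_tert", stratum = "Pakistani_origin",
                         covariates = c("age", "smoking", "ethnicity"))
  expect_error(test_interaction(fit_pk), "total-population")
  d1 <- gen_null_data(n = 800, two_ethnicities = FALSE)
  expect_error(
    fit_bw_model(d1, "exp_tert", covariates = c("age", "smoking",
                                                "ethnicity")),
    "aliased|contrasts")
})

test_that("interaction test has power against differing effects by ethnicity", {
  set.seed(67)
  hits <- 0L
  for (r in 1:20) {
    d <- gen_null_data(n = 6000)
    # top-tertile effect -60 g in one ethnicity only
    d$birth_weight_g <- d$birth_weight_g -
      60 * (d$exp_tert == "T3") * (d$ethnicity == "Pakistani_origin")
    fit <- fit_bw_model(d, "exp_tert", covariates = c("age", "smoking",
                                                      "ethnicity"))
    hits <- hits + (test_interaction(fit) < 0.05)
  }
  expect_gt(hits / 20, 0.5)
})

test_that("exposure-level floor and rank deficiency raise clear errors", {
  set.seed(68)
  d <- gen_null_data(n = 100)
  d$exp_tert[d$exp_tert == "T3"] <- "T2"
  expect_error(fit_bw_model(d, "exp_tert", covariates = c("age", "smoking",
                                                          "ethnicity"),
                            min_per_level = 200),
               "fewer than")
  d2 <- gen_null_data(n = 200)
  d2$age2 <- d2$age  # exact copy => aliased column
  expect_error(fit_bw_model(d2, "exp_tert",
                            covariates = c("age", "age2", "smoking",
                                           "ethnicity")),
               "aliased")
})

test_that("the analysis suite covers metrics x windows x strata", {
  set.seed(69)
  # compact synthetic exposure table + cohort (two windows, two metrics,
  # one joint pair)
  n <- 2400
  d <- simulate_stratum("tthm_uptake", n = n,
                        truth = list(up_TTHM_tert = c(T1 = 0, T2 = 0, T3 = -50)))
  d$ethnicity <- factor(sample(c("white_British", "Pakistani_origin"), n, TRUE),
                        levels = c("white_British", "Pakistani_origin"))
  d$birth_weight_g <- simulate_outcomes(
    d, d["up_TTHM_tert"], list(up_TTHM_tert = c(T1 = 0, T2 = 0, T3 = -50)))
  d$pregnancy_id <- seq_len(n)
  d$ing_HAA3 <- rlnorm(n, 3.4, 0.6)
  ex <- rbind(
    data.frame(pregnancy_id = d$pregnancy_id, window = "whole",
               up_TTHM = d$up_TTHM, ing_HAA3 = d$ing_HAA3),
    data.frame(pregnancy_id = d$pregnancy_id, window = "T1",
               up_TTHM = d$up_TTHM * runif(n, 0.8, 1.2),
               ing_HAA3 = d$ing_HAA3))
  cohort_cols <- setdiff(names(d), c("up_TTHM", "ing_HAA3", "up_TTHM_tert"))
  res <- run_analysis_suite(ex, d[cohort_cols],
                            metrics = list("up_TTHM", "ing_HAA3"),
                            windows = c("whole", "T1"),
                            strata = c("total", "white_British",
                                       "Pakistani_origin"))
  expect_setequal(unique(res$stratum),
                  c("total", "white_British", "Pakistani_origin"))
  expect_setequal(unique(res$window), c("whole", "T1"))
  expect_setequal(unique(res$metric), c("up_TTHM", "ing_HAA3"))
  expect_equal(nrow(res), 2 * 2 * 3 * 3)  # metrics x windows x strata x levels
  # interaction p only reported in the total model
  expect_true(all(is.na(res$p_interaction[res$stratum != "total"])))
  expect_true(all(!is.na(res$p_interaction[res$stratum == "total"])))
  # stratified design matrices carry no ethnicity columns
  fit_pk <- fit_bw_model(d, "up_TTHM_tert", stratum = "Pakistani_origin")
  expect_false(any(grepl("ethnicity", colnames(model.matrix(fit_pk$fit)))))
  expect_error(run_analysis_suite(ex, d[cohort_cols],
                                  metrics = list("nope")),
               "available")
})
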