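# Synthetic-data generator: monitoring records, a multi-ethnic pregnancy
# cohort and birth-weight outcomes with the statistical structure the analysis
# assumes, so the whole pipeline is testable and its parameter recovery can be
# demonstrated without restricted data. Distributional forms (log-normal
# concentrations, gamma water volumes, Bernoulli participation) are the
# package's own modelling choices; their parameters default to the published
# summary statistics of the emulated cohort.

#' Scenario configuration for the synthetic-data generator
#'
#' Bundles every tunable of the generator with defaults emulating the study
#' conditions: 8 water supply zones sampled ~9 times/year for THMs
#' (2006-01 to 2011-03) and quarterly for HAAs (2007-06 to 2010-11); a
#' register of ~13,500 babies whose eligibility cascade leaves ~9,200; an
#' ethnicity mix of 40% white British / 45% Pakistani origin / 15% other;
#' ethnicity-specific water use (total tap 1.84 vs 1.51 L/day, bathing 151 vs
#' 96 min/week, showering 86 vs 94 min/week, swimming participation 14% vs
#' 2%); concentration targets TTHM 45.6, DCAA 8.9, TCAA 12.5, BDCAA 1.3 ug/L;
#' term birth-weight baselines 3,424 / 3,186 g and residual SD 450 g.
#'
#' @param seed default integer seed used when a generator call gives none.
#' @param n_babies size of the raw register before the cascade.
#' @param ... overrides for any named default (see the returned list).
#' @return list of class `"scenario_config"`.
#' @export
scenario_config <- function(seed = 1L, n_babies = 13525L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_zones = 8L,
    zones = sprintf("WSZ%d", 1:8),
    thm_samples_per_year = 9,
    thm_span = as.Date(c("2006-01-01", "2011-03-31")),
    haa_span = as.Date(c("2007-06-01", "2010-11-30")),
    # log-normal THM generator: target means (ug/L), seasonal amplitude and
    # residual sd on the log scale, fixed sum-to-zero zone offsets
    thm_means = c(chloroform = 37.8, BDCM = 6.6, DBCM = 0.9, bromoform = 0.2),
    thm_seasonal_amp = 0.15,
    thm_log_sd = 0.15,
    zone_offsets = c(-0.07, -0.05, -0.03, -0.01, 0.01, 0.03, 0.05, 0.07),
    thm_lods = c(chloroform = 1, BDCM = 0.5, DBCM = 0.3, bromoform = 0.3),
    # HAA generator: target means, transform-scale coefficients and noise
    haa_means = c(DCAA = 8.9, TCAA = 12.5, BDCAA = 1.3),
    haa_noise = c(DCAA = 0.10, TCAA = 0.10, BDCAA = 0.15),
    haa_zone_sd = 0.05,
    haa_coef = list(
      DCAA = c(conductivity = 0.003, temperature = 0.02),
      TCAA = c(conductivity = 0.003, temperature = 0.02, toc = 0.10),
      BDCAA = c(conductivity = 0.002, total_chlorine = 0.15)),
    haa_covariate_missing = 0.05,
    haa_lod = 0.2,
    covariate_dists = list(conductivity = c(250, 30), temperature = c(12, 1.5),
                           toc = c(1.5, 0.3), total_chlorine = c(1.0, 0.2)),
    # cohort
    n_babies = as.integer(n_babies),
    ethnicity_mix = c(white_British = 0.40, Pakistani_origin = 0.45,
                      other = 0.15),
    conception_span = as.Date(c("2007-03-01", "2010-05-31")),
    employment = c(white_British = 0.64, Pakistani_origin = 0.23,
                   other = 0.40),
    p_work_assigned = 0.584,
    swim_participation = c(white_British = 0.14, Pakistani_origin = 0.02,
                           other = 0.08),
    # (mean L/day or min/week among users; gamma shapes fixed below)
    water_use = list(
      white_British = c(tap = 0.90, squash = 0.21, tea = 0.50, coffee = 0.22,
                        bottled = 0.40, shower = 86, bath = 151, swim = 72,
                        p_shower = 0.71, p_bath = 0.76),
      Pakistani_origin = c(tap = 0.95, squash = 0.23, tea = 0.25,
                           coffee = 0.08, bottled = 0.15, shower = 94,
                           bath = 96, swim = 75, p_shower = 0.69,
                           p_bath = 0.66),
      other = c(tap = 0.92, squash = 0.22, tea = 0.38, coffee = 0.15,
                bottled = 0.28, shower = 90, bath = 120, swim = 73,
                p_shower = 0.70, p_bath = 0.70)),
    p_filter_home = 0.10,
    # cascade rates (raw register -> eligible)
    p_multiple = 0.0241,
    repeat_mother_frac = 0.1066,
    p_water_missing = 0.176,
    p_thm_incomputable = 0.010,
    p_bw_missing = 1e-4,
    p_preterm = 0.0546,
    # covariate missingness (MCAR)
    covariate_missing = c(parity = 0.035, bmi_quartile = 0.036,
                          fasting_glucose = 0.041, postload_glucose = 0.041,
                          caffeine_ge200 = 0.089, education = 0.002,
                          imd_quintile = 0.002, smoking = 0.001),
    # outcome model
    baseline_bw = c(white_British = 3424, Pakistani_origin = 3186,
                    other = 3300),
    resid_sd = 450,
    covariate_effects = list(
      sex_male = 120, ga_linear = 140, ga_quad = -5,
      smoking = c(never = 0, ever = -40, current = -180),
      parity = c(`0` = 0, `1` = 90, `2+` = 50),
      age_per_yr = 1.5, age_center = 27,
      caffeine = -40,
      fasting_per_mmol = 25, fasting_center = 4.5,
      postload_per_mmol = 8, postload_center = 5.7,
      bmi_quartile = c(Q1 = 0, Q2 = 60, Q3 = 110, Q4 = 160),
      education = c(none = 0, school = 10, further = 20, higher = 40,
                    other = 0),
      imd_per_quintile = 18))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (abs(sum(cfg$ethnicity_mix) - 1) > 1e-8) {
    stop("ethnicity mix must sum to 1")
  }
  if (cfg$resid_sd <= 0) stop("residual SD must be positive")
  structure(cfg, class = "scenario_config")
}

#' Simulate water-quality monitoring records
#'
#' THMs: log-normal with fixed zone offsets, an annual sinusoid peaking in
#' late summer and independent log-scale noise; each zone is sampled the
#' configured number of times per year, and per-sample TTHM rows are the sum
#' of the four component THMs. HAAs: quarterly samples per zone, with the
#' stated covariate dependencies on the square-root (DCAA, TCAA) or log
#' (BDCAA) scale and covariate entries missing at random. Values below the
#' configured LODs are flagged censored.
#'
#' @param config a [scenario_config()].
#' @param seed integer seed (default: the config seed).
#' @return validated monitoring data.frame (THM and HAA rows stacked).
#' @export
simulate_monitoring <- function(config = scenario_config(),
                                seed = config$seed) {
  if (config$thm_samples_per_year <= 0) stop("sampling rate must be positive")
  set.seed(seed)
  thm <- simulate_thm_rows(config)
  haa <- simulate_haa_rows(config)
  out <- rbind_fill(list(thm, haa))
  rownames(out) <- NULL
  validate_monitoring(out)
  out
}

seasonal <- function(month, amp) amp * sin(2 * pi * (month - 4) / 12)

simulate_thm_rows <- function(config) {
  span_years <- seq(as.integer(format(config$thm_span[1], "%Y")),
                    as.integer(format(config$thm_span[2], "%Y")))
  rows <- list()
  for (zi in seq_along(config$zones)) {
    for (yr in span_years) {
      y0 <- as.Date(sprintf("%d-01-01", yr))
      y1 <- min(as.Date(sprintf("%d-12-31", yr)), config$thm_span[2])
      n_days <- as.integer(y1 - y0) + 1L
      n <- max(1L, round(config$thm_samples_per_year * n_days / 365))
      dates <- y0 + sort(sample.int(n_days, n, replace = FALSE)) - 1L
      month <- as.integer(format(dates, "%m"))
      vals <- sapply(names(config$thm_means), function(a) {
        mu <- log(config$thm_means[[a]]) -
          0.5 * (config$thm_log_sd^2 + config$thm_seasonal_amp^2 / 2)
        exp(mu + config$zone_offsets[zi] +
              seasonal(month, config$thm_seasonal_amp) +
              stats::rnorm(n, 0, config$thm_log_sd))
      })
      vals <- matrix(vals, nrow = n)
      colnames(vals) <- names(config$thm_means)
      for (a in colnames(vals)) {
        lod <- config$thm_lods[[a]]
        rows[[length(rows) + 1]] <- data.frame(
          wsz_id = config$zones[zi], sample_date = dates, analyte = a,
          value = vals[, a], below_lod = vals[, a] < lod, lod = lod,
          stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1]] <- data.frame(
        wsz_id = config$zones[zi], sample_date = dates, analyte = "TTHM",
        value = rowSums(vals), below_lod = FALSE, lod = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

simulate_haa_rows <- function(config) {
  q0 <- time_cell(config$haa_span[1], "quarter")
  q1 <- time_cell(config$haa_span[2], "quarter")
  cells <- cell_seq(q0, q1)
  zone_off <- stats::rnorm(length(config$zones), 0, config$haa_zone_sd)
  rows <- list()
  for (zi in seq_along(config$zones)) {
    b <- cell_bounds(cells)
    dates <- b$start + 40 + sample.int(14, nrow(b), replace = TRUE)
    month <- as.integer(format(dates, "%m"))
    n <- length(dates)
    covs <- data.frame(
      conductivity = stats::rnorm(n, config$covariate_dists$conductivity[1],
                                  config$covariate_dists$conductivity[2]),
      temperature = config$covariate_dists$temperature[1] +
        7 * sin(2 * pi * (month - 4) / 12) +
        stats::rnorm(n, 0, config$covariate_dists$temperature[2]),
      toc = stats::rnorm(n, config$covariate_dists$toc[1],
                         config$covariate_dists$toc[2]),
      total_chlorine = stats::rnorm(n, config$covariate_dists$total_chlorine[1],
                                    config$covariate_dists$total_chlorine[2]))
    for (a in names(config$haa_means)) {
      transform <- HAA_TRANSFORM[[a]]
      noise <- config$haa_noise[[a]]
      base <- if (transform == "sqrt") {
        sqrt(config$haa_means[[a]])
      } else {
        log(config$haa_means[[a]]) - 0.5 * noise^2
      }
      eta <- base + zone_off[zi]
      for (cv in names(config$haa_coef[[a]])) {
        eta <- eta + config$haa_coef[[a]][[cv]] *
          (covs[[cv]] - config$covariate_dists[[cv]][1])
      }
      val <- inv_transform(eta + stats::rnorm(n, 0, noise), transform)
      row <- data.frame(wsz_id = config$zones[zi], sample_date = dates,
                        analyte = a, value = val,
                        below_lod = val < config$haa_lod,
                        lod = config$haa_lod, stringsAsFactors = FALSE)
      cm <- covs
      for (cv in names(cm)) {
        cm[[cv]][stats::runif(n) < config$haa_covariate_missing] <- NA
      }
      rows[[length(rows) + 1]] <- cbind(row, cm)
    }
  }
  do.call(rbind, rows)
}

# shared covariate generator; returns full (unmasked) covariates
simulate_covariates <- function(n, ethnicity, config) {
  pick <- function(wb, pk, oth) {
    v <- numeric(n)
    v[ethnicity == "white_British"] <- wb
    v[ethnicity == "Pakistani_origin"] <- pk
    v[ethnicity == "other"] <- oth
    v
  }
  rcat <- function(levels, p_wb, p_pk, p_oth) {
    out <- character(n)
    for (e in c("white_British", "Pakistani_origin", "other")) {
      idx <- which(ethnicity == e)
      p <- switch(e, white_British = p_wb, Pakistani_origin = p_pk,
                  other = p_oth)
      out[idx] <- sample(levels, length(idx), replace = TRUE, prob = p)
    }
    out
  }
  age <- pmax(16, pmin(45, stats::rnorm(n, pick(27.8, 27.2, 27.5), 5.6)))
  bmi <- pmax(15, stats::rnorm(n, pick(28.9, 27.9, 28.3), pick(5.8, 5.2, 5.5)))
  data.frame(
    age = age,
    education = factor(rcat(
      c("none", "school", "further", "higher", "other"),
      c(0.20, 0.34, 0.17, 0.19, 0.10), c(0.26, 0.31, 0.13, 0.26, 0.04),
      c(0.23, 0.32, 0.15, 0.22, 0.08)),
      levels = c("none", "school", "further", "higher", "other")),
    smoking = factor(rcat(c("never", "ever", "current"),
                          c(0.55, 0.17, 0.28), c(0.93, 0.04, 0.03),
                          c(0.75, 0.11, 0.14)),
                     levels = c("never", "ever", "current")),
    parity = factor(rcat(c("0", "1", "2+"),
                         c(0.50, 0.30, 0.20), c(0.33, 0.25, 0.42),
                         c(0.42, 0.28, 0.30)),
                    levels = c("0", "1", "2+")),
    imd_quintile = factor(rcat(as.character(1:5),
                               c(0.50, 0.22, 0.18, 0.06, 0.04),
                               c(0.79, 0.14, 0.06, 0.007, 0.003),
                               c(0.66, 0.18, 0.11, 0.03, 0.02)),
                          levels = as.character(1:5)),
    caffeine_ge200 = stats::runif(n) < pick(0.31, 0.06, 0.17),
    fasting_glucose = stats::rnorm(n, pick(4.4, 4.6, 4.5),
                                   pick(0.4, 0.6, 0.5)),
    postload_glucose = stats::rnorm(n, pick(5.4, 5.9, 5.7),
                                    pick(1.3, 1.6, 1.5)),
    bmi = bmi,
    bmi_quartile = factor(paste0("Q", findInterval(
      bmi, stats::quantile(bmi, c(0.25, 0.5, 0.75)), left.open = FALSE) + 1),
      levels = paste0("Q", 1:4)),
    sex = factor(ifelse(stats::runif(n) < 0.512, "male", "female"),
                 levels = c("female", "male")),
    stringsAsFactors = FALSE)
}

# gamma draws with a given mean and shape
rgamma_mean <- function(n, mean, shape) {
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

simulate_water_use <- function(n, ethnicity, config) {
  out <- data.frame(tap_Lday = numeric(n), squash_Lday = numeric(n),
                    tea_Lday = numeric(n), coffee_Lday = numeric(n),
                    bottled_Lday = numeric(n), shower_minwk = numeric(n),
                    bath_minwk = numeric(n), swim_minwk = numeric(n))
  for (e in names(config$water_use)) {
    idx <- which(ethnicity == e)
    if (!length(idx)) next
    w <- config$water_use[[e]]
    m <- length(idx)
    out$tap_Lday[idx] <- rgamma_mean(m, w[["tap"]], 1.6)
    out$squash_Lday[idx] <- rgamma_mean(m, w[["squash"]], 0.8)
    out$tea_Lday[idx] <- rgamma_mean(m, w[["tea"]], 1.2)
    out$coffee_Lday[idx] <- rgamma_mean(m, w[["coffee"]], 0.8)
    out$bottled_Lday[idx] <- rgamma_mean(m, w[["bottled"]], 0.7)
    shower_yes <- stats::runif(m) < w[["p_shower"]]
    out$shower_minwk[idx] <- ifelse(shower_yes,
                                    rgamma_mean(m, w[["shower"]], 1.6), 0)
    bath_yes <- stats::runif(m) < w[["p_bath"]]
    out$bath_minwk[idx] <- ifelse(bath_yes,
                                  rgamma_mean(m, w[["bath"]], 1.4), 0)
    swim_yes <- stats::runif(m) < config$swim_participation[[e]]
    out$swim_minwk[idx] <- ifelse(swim_yes,
                                  rgamma_mean(m, w[["swim"]], 2.5), 0)
  }
  out$filter_home <- stats::runif(n) < config$p_filter_home
  out
}

#' Simulate a multi-ethnic pregnancy cohort
#'
#' Generates a raw register of pregnancy records with the configured ethnicity
#' mix, ethnicity-conditional water use, employment and covariates, conception
#' dates spanning the recruitment window, repeated pregnancies and singleton
#' status at the configured rates, and covariate/water-use missingness
#' injected MCAR. Birth weight is generated from the covariate model (no
#' exposure effect); use [simulate_outcomes()] to impose exposure effects.
#'
#' @param config a [scenario_config()].
#' @param n number of babies in the register (default `config$n_babies`).
#' @param seed integer seed (default: the config seed).
#' @return data.frame of pregnancy records.
#' @export
simulate_cohort <- function(config = scenario_config(), n = config$n_babies,
                            seed = config$seed) {
  set.seed(seed)
  # repeat-pregnancy structure: a fraction of mothers contribute two babies
  n_pairs <- round(config$repeat_mother_frac * n /
                     (1 + 2 * config$repeat_mother_frac))
  n_single <- n - 2L * n_pairs
  if (n_single < 0) stop("infeasible repeat-mother fraction for n = ", n)
  mother_id <- c(rep(seq_len(n_pairs), each = 2L),
                 n_pairs + seq_len(n_single))
  n <- length(mother_id)
  eth_m <- sample(names(config$ethnicity_mix),
                  max(mother_id), replace = TRUE,
                  prob = config$ethnicity_mix)
  ethnicity <- eth_m[mother_id]
  cov <- simulate_covariates(n, ethnicity, config)
  wu <- simulate_water_use(n, ethnicity, config)
  conception <- config$conception_span[1] +
    sample.int(as.integer(diff(config$conception_span)) + 1L, n,
               replace = TRUE) - 1L
  preterm <- stats::runif(n) < config$p_preterm
  ga <- ifelse(preterm,
               stats::runif(n, 30, 36.9),
               pmin(42.5, pmax(37, stats::rnorm(n, 39.9, 1.15))))
  employed <- stats::runif(n) <
    config$employment[match(ethnicity, names(config$employment))]
  work_wsz <- ifelse(employed & stats::runif(n) < config$p_work_assigned,
                     sample(config$zones, n, replace = TRUE), NA_character_)
  rec <- data.frame(
    mother_id = mother_id,
    pregnancy_id = seq_len(n),
    singleton = stats::runif(n) >= config$p_multiple,
    ethnicity = factor(ethnicity, levels = names(config$ethnicity_mix)),
    conception_date = conception,
    gestational_age_wk = ga,
    delivery_date = conception + round(ga * 7),
    residence_wsz = sample(config$zones, n, replace = TRUE),
    employed = employed,
    work_wsz = work_wsz,
    stringsAsFactors = FALSE)
  rec <- cbind(rec, cov, wu)
  # outcome from the covariate model alone (exposure effects added later)
  rec$birth_weight_g <- bw_linear_predictor(rec, config) +
    stats::rnorm(n, 0, config$resid_sd)
  rec$birth_weight_g[stats::runif(n) < config$p_bw_missing] <- NA
  # MCAR missingness, injected after the outcome is generated
  rec$water_use_missing <- stats::runif(n) < config$p_water_missing
  wu_cols <- c("tap_Lday", "squash_Lday", "tea_Lday", "coffee_Lday",
               "bottled_Lday", "shower_minwk", "bath_minwk", "swim_minwk")
  for (cl in wu_cols) rec[[cl]][rec$water_use_missing] <- NA
  rec$thm_computable <- stats::runif(n) >= config$p_thm_incomputable
  for (cv in names(config$covariate_missing)) {
    rec[[cv]][stats::runif(n) < config$covariate_missing[[cv]]] <- NA
  }
  rec
}

# deterministic part of the outcome model
bw_linear_predictor <- function(records, config) {
  ce <- config$covariate_effects
  num0 <- function(x) ifelse(is.na(x), 0, x)
  lp <- config$baseline_bw[match(as.character(records$ethnicity),
                                 names(config$baseline_bw))]
  lp <- lp + num0(ce$smoking[as.character(records$smoking)])
  lp <- lp + num0(ce$parity[as.character(records$parity)])
  lp <- lp + num0(ce$education[as.character(records$education)])
  lp <- lp + num0(ce$bmi_quartile[as.character(records$bmi_quartile)])
  lp <- lp + ce$age_per_yr * num0(records$age - ce$age_center)
  lp <- lp + ifelse(records$caffeine_ge200 %in% TRUE, ce$caffeine, 0)
  lp <- lp + ce$fasting_per_mmol * num0(records$fasting_glucose - ce$fasting_center)
  lp <- lp + ce$postload_per_mmol * num0(records$postload_glucose - ce$postload_center)
  lp <- lp + num0(ce$imd_per_quintile *
                    (as.numeric(as.character(records$imd_quintile)) - 1))
  lp <- lp + ifelse(records$sex == "male", ce$sex_male, 0)
  ga_c <- records$gestational_age_wk - 40
  lp <- lp + ce$ga_linear * ga_c + ce$ga_quad * ga_c^2
  unname(lp)
}

#' Simulate birth weights under known exposure effects
#'
#' Birth weight = ethnicity baseline + covariate effects + the configured true
#' effect of each exposure category + normal noise. Effects may be a named
#' vector over exposure levels (common to all ethnicities) or a matrix with
#' ethnicities as rows for effect modification. Records with missing
#' covariates contribute zero for the missing term (such records are excluded
#' from complete-case fits anyway).
#'
#' @param cohort pregnancy records (e.g. from [simulate_cohort()]).
#' @param exposure data.frame of exposure category factors, one column per
#'   exposure term, aligned row-by-row with `cohort`.
#' @param true_effects named list, one element per exposure column: a named
#'   vector `c(level = grams, ...)` or a matrix `[ethnicity, level]`.
#' @param config a [scenario_config()].
#' @param noise_sd residual SD (default `config$resid_sd`; 0 gives the exact
#'   linear predictor).
#' @return numeric vector of birth weights (g).
#' @export
simulate_outcomes <- function(cohort, exposure, true_effects,
                              config = scenario_config(),
                              noise_sd = config$resid_sd) {
  exposure <- as.data.frame(exposure)
  if (nrow(exposure) != nrow(cohort)) {
    stop("exposure and cohort are misaligned: ", nrow(exposure), " vs ",
         nrow(cohort), " rows")
  }
  lp <- bw_linear_predictor(cohort, config)
  for (term in names(true_effects)) {
    eff <- true_effects[[term]]
    lev <- as.character(exposure[[term]])
    if (is.matrix(eff)) {
      add <- eff[cbind(as.character(cohort$ethnicity), lev)]
    } else {
      add <- eff[lev]
    }
    add[is.na(add)] <- 0
    lp <- lp + add
  }
  unname(lp + stats::rnorm(nrow(cohort), 0, noise_sd))
}

#' Exact-cascade fixture
#'
#' Builds a register whose eligibility cascade reproduces the reference stage
#' counts deterministically: 13,525 babies; 326 non-singleton; 1,271 excluded
#' when one pregnancy per mother is kept (1,271 mothers with two pregnancies
#' carrying identical downstream flags, so the seeded choice cannot change the
#' counts); 2,100 missing water use; 98 with THM exposure not computable for
#' all trimesters; 1 missing birth weight; 531 preterm; 9,198 eligible.
#'
#' @param counts named integer vector of stage counts; the defaults are the
#'   reference cascade.
#' @return data.frame of minimal pregnancy records for [apply_exclusions()].
#' @export
make_cascade_fixture <- function(counts = c(total = 13525L,
                                            non_singleton = 326L,
                                            repeat_excluded = 1271L,
                                            water_missing = 2100L,
                                            thm_incomputable = 98L,
                                            bw_missing = 1L,
                                            preterm = 531L)) {
  n_singleton <- counts[["total"]] - counts[["non_singleton"]]
  n_pairs <- counts[["repeat_excluded"]]
  n_units <- n_singleton - n_pairs  # mothers after one-per-mother selection
  # per-mother downstream flags, in cascade order
  f_water <- c(rep(TRUE, counts[["water_missing"]]),
               rep(FALSE, n_units - counts[["water_missing"]]))
  rest <- which(!f_water)
  f_thm <- rep(FALSE, n_units)
  f_thm[rest[seq_len(counts[["thm_incomputable"]])]] <- TRUE
  rest <- which(!f_water & !f_thm)
  f_bw <- rep(FALSE, n_units)
  f_bw[rest[seq_len(counts[["bw_missing"]])]] <- TRUE
  rest <- which(!f_water & !f_thm & !f_bw)
  f_pre <- rep(FALSE, n_units)
  f_pre[rest[seq_len(counts[["preterm"]])]] <- TRUE

  # mothers 1..n_pairs contribute two singleton pregnancies each
  mother <- c(rep(seq_len(n_pairs), each = 2L),
              n_pairs + seq_len(n_units - n_pairs))
  unit <- mother  # flag index: both pregnancies of a pair share flags
  rec <- data.frame(
    mother_id = mother,
    pregnancy_id = seq_along(mother),
    singleton = TRUE,
    water_use_missing = f_water[unit],
    thm_computable = !f_thm[unit],
    birth_weight_g = ifelse(f_bw[unit], NA_real_, 3300),
    gestational_age_wk = ifelse(f_pre[unit], 34, 40),
    stringsAsFactors = FALSE)
  multi <- data.frame(
    mother_id = max(mother) + seq_len(counts[["non_singleton"]]),
    pregnancy_id = nrow(rec) + seq_len(counts[["non_singleton"]]),
    singleton = FALSE, water_use_missing = FALSE, thm_computable = TRUE,
    birth_weight_g = 3300, gestational_age_wk = 40,
    stringsAsFactors = FALSE)
  out <- rbind(rec, multi)
  stopifnot(nrow(out) == counts[["total"]])
  out
}

#' Workplace-assignment fixture
#'
#' A cohort-shaped table with the reference workplace bookkeeping: of
#' `n_employed` employed women, `n_assigned` have a geocodable in-zone
#' workplace; the remainder of `n_total` are not employed.
#'
#' @param n_total,n_employed,n_assigned integers.
#' @return data.frame with `employed` and `work_wsz` columns.
#' @export
make_workplace_fixture <- function(n_total = 9198L, n_employed = 4024L,
                                   n_assigned = 2353L) {
  stopifnot(n_assigned <= n_employed, n_employed <= n_total)
  data.frame(
    employed = c(rep(TRUE, n_employed), rep(FALSE, n_total - n_employed)),
    work_wsz = c(rep("WSZ1", n_assigned),
                 rep(NA_character_, n_total - n_assigned)),
    stringsAsFactors = FALSE)
}
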