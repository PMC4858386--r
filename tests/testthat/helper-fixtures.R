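# Shared fixtures built in code.

# constant-concentration surface over a run of cells
constant_surface <- function(value, analyte = "TTHM",
                             zones = c("Z1", "Z2"),
                             cells = cell_seq("2008-01", "2009-12")) {
  res <- cell_resolution(cells)
  g <- expand.grid(wsz_id = zones, time_cell = cells, stringsAsFactors = FALSE)
  structure(
    data.frame(analyte = analyte, g,
               pred_ugL = if (length(value) == 1) value else
                 value[match(g$wsz_id, zones)],
               sd = NA_real_, provenance = "fitted", stringsAsFactors = FALSE),
    resolution = res, class = c("conc_surface", "data.frame"))
}

# minimal monitoring table
mk_samples <- function(value, below_lod = FALSE, lod = NA_real_,
                       analyte = "TTHM", wsz_id = "Z1",
                       sample_date = as.Date("2008-06-15")) {
  data.frame(wsz_id = wsz_id, sample_date = sample_date, analyte = analyte,
             value = value, below_lod = below_lod, lod = lod,
             stringsAsFactors = FALSE)
}

# THM monitoring data drawn from the model family the fitter assumes:
# log c = mu + zone offset + sinusoid(month) + N(0, sd)
gen_thm_family <- function(n = 400, mu = log(45), zone_off = c(0, 0.5),
                           amp = 0.2, sd = 0.1, years = 2008:2009,
                           analyte = "TTHM") {
  zones <- paste0("Z", seq_along(zone_off))
  z <- sample(seq_along(zone_off), n, replace = TRUE)
  yr <- years[sample.int(length(years), n, replace = TRUE)]
  dates <- as.Date(sprintf("%d-01-01", yr)) +
    sample.int(364, n, replace = TRUE) - 1L
  month <- as.integer(format(dates, "%m"))
  eta <- mu + zone_off[z] + amp * sin(2 * pi * month / 12)
  data.frame(wsz_id = zones[z], sample_date = dates, analyte = analyte,
             value = exp(eta + rnorm(n, 0, sd)), below_lod = FALSE,
             lod = NA_real_, stringsAsFactors = FALSE)
}

# expected log-scale monthly mean of gen_thm_family
gen_thm_truth <- function(zone_idx, month, mu = log(45),
                          zone_off = c(0, 0.5), amp = 0.2) {
  exp(mu + zone_off[zone_idx] + amp * sin(2 * pi * month / 12))
}

# small null analysis dataset: exposure tertile independent of birth weight
# given the adjusting covariates; with confounded = TRUE, age and smoking
# shift the exposure so that adjustment is exercised
gen_null_data <- function(n = 250, two_ethnicities = TRUE, confounded = TRUE) {
  age <- rnorm(n, 27, 5)
  smoking <- factor(sample(c("never", "ever", "current"), n, TRUE,
                           prob = c(0.6, 0.2, 0.2)),
                    levels = c("never", "ever", "current"))
  ethnicity <- if (two_ethnicities) {
    factor(sample(c("white_British", "Pakistani_origin"), n, TRUE))
  } else {
    factor(rep("Pakistani_origin", n))
  }
  x <- if (confounded) {
    rlnorm(n, 0.1 * (smoking == "current") - 0.01 * (age - 27), 0.7)
  } else {
    rlnorm(n, 0, 0.7)
  }
  ga <- pmin(42.5, pmax(37, rnorm(n, 39.8, 1.2)))
  sex <- factor(sample(c("female", "male"), n, TRUE))
  bw <- 3300 + 1.5 * (age - 27) - 150 * (smoking == "current") +
    120 * (sex == "male") + 140 * (ga - 40) - 80 * (ethnicity == "Pakistani_origin") +
    rnorm(n, 0, 450)
  data.frame(birth_weight_g = bw, exp_tert = categorize(x, "tertile"),
             age = age, smoking = smoking, ethnicity = ethnicity,
             gestational_age_wk = ga, sex = sex)
}
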