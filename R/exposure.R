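# Per-pregnancy exposure metrics: time-weighted average (TWA) concentrations
# over gestational windows, ingestion via drinking water, pathway-resolved and
# integrated blood uptake of THMs, and the joint THM-HAA aggregates.

#' Individual water-use profile
#'
#' Questionnaire water-use quantities for one woman. Derived components
#' follow the questionnaire definitions: cold tap = tap + squash, hot tap =
#' tea + coffee, total tap = their sum. Bottled water never contributes to
#' tap-water exposure.
#'
#' @param tap_Lday,bottled_Lday,tea_Lday,coffee_Lday,squash_Lday litres/day.
#' @param filter_home,filter_work logical; tap water filtered at home / work.
#' @param shower_minwk,bath_minwk,swim_minwk minutes per week.
#' @return list of class `"water_use_profile"` with derived components.
#' @export
water_use_profile <- function(tap_Lday = 0, bottled_Lday = 0, tea_Lday = 0,
                              coffee_Lday = 0, squash_Lday = 0,
                              filter_home = FALSE, filter_work = FALSE,
                              shower_minwk = 0, bath_minwk = 0,
                              swim_minwk = 0) {
  q <- c(tap_Lday, bottled_Lday, tea_Lday, coffee_Lday, squash_Lday,
         shower_minwk, bath_minwk, swim_minwk)
  if (any(q < 0, na.rm = TRUE)) stop("water-use quantities must be nonnegative")
  structure(list(
    tap_Lday = tap_Lday, bottled_Lday = bottled_Lday, tea_Lday = tea_Lday,
    coffee_Lday = coffee_Lday, squash_Lday = squash_Lday,
    filter_home = isTRUE(filter_home), filter_work = isTRUE(filter_work),
    shower_minwk = shower_minwk, bath_minwk = bath_minwk,
    swim_minwk = swim_minwk,
    cold_tap_Lday = tap_Lday + squash_Lday,
    hot_tap_Lday = tea_Lday + coffee_Lday,
    total_tap_Lday = tap_Lday + squash_Lday + tea_Lday + coffee_Lday),
    class = "water_use_profile")
}

# work/residence weights: 8 h at work, 5 days/week, of 112 waking hours
WORK_WEIGHT <- 40 / 112
RESIDENCE_WEIGHT <- 72 / 112

#' Time-weighted average concentration over an exposure window
#'
#' Cell concentrations for the residence zone (and, for women with an assigned
#' workplace zone, a 72/112 residence + 40/112 work blend) are averaged with
#' weights proportional to the days of the window falling in each calendar
#' month or quarter. If any overlapped cell is missing from the surface the
#' metric is `NA` (flagged missing, never zero).
#'
#' @param surface a `"conc_surface"` for one analyte.
#' @param window a window from [exposure_window()].
#' @param residence_wsz residence zone label.
#' @param work_wsz workplace zone label or `NA` when not assigned.
#' @return TWA concentration (ug/L), or `NA_real_` if the window extends
#'   outside surface coverage.
#' @export
twa_concentration <- function(surface, window, residence_wsz, work_wsz = NA) {
  w <- compute_time_weights(window, attr(surface, "resolution"))
  c_res <- surface_lookup(surface, residence_wsz, names(w))
  if (anyNA(c_res)) return(NA_real_)
  if (!is.na(work_wsz)) {
    c_work <- surface_lookup(surface, work_wsz, names(w))
    if (anyNA(c_work)) return(NA_real_)
    cc <- RESIDENCE_WEIGHT * c_res + WORK_WEIGHT * c_work
  } else {
    cc <- c_res
  }
  sum(w * cc)
}

# litres/day of tap water reaching the body for a given analyte, after
# filtering (cold tap component only, squash never filtered) and boiling
# (hot beverages) adjustments
effective_tap_volume <- function(profile, analyte, factors) {
  f <- if (profile$filter_home) factors$filter_adjust[[analyte]] else 0
  b <- factors$boil_adjust[[analyte]]
  vol <- profile$tap_Lday * (1 + f) + profile$squash_Lday +
    profile$hot_tap_Lday * (1 + b)
  if (vol < 0) stop("negative adjusted volume; check adjustment factors")
  vol
}

#' Ingestion of DBPs via drinking-water consumption
#'
#' TWA concentration times adjusted daily tap-water consumption, per analyte.
#' The hot-beverage component carries the boiling adjustment, the cold tap
#' component the filtering adjustment when a home filter is used; squash is
#' always unfiltered and bottled water contributes nothing. Aggregates HAA3
#' (DCAA + TCAA + BDCAA) and DBP7 (TTHM + HAA3) are appended when their
#' components are present.
#'
#' @param profile a [water_use_profile()].
#' @param twa named vector of TWA concentrations (ug/L) per analyte.
#' @param factors an [uptake_factor_table()].
#' @return named vector of ingestion metrics (ug/day).
#' @export
ingestion <- function(profile, twa, factors = uptake_factor_table()) {
  out <- vapply(names(twa), function(a) {
    if (is.na(twa[[a]])) return(NA_real_)
    twa[[a]] * effective_tap_volume(profile, a, factors)
  }, numeric(1))
  if (all(HAA_ANALYTES %in% names(out))) {
    out["HAA3"] <- sum(out[HAA_ANALYTES])
    if ("TTHM" %in% names(out)) out["DBP7"] <- out[["TTHM"]] + out[["HAA3"]]
  }
  out
}

#' Integrated blood uptake of THMs across exposure pathways
#'
#' Combines the ingestion, showering, bathing and swimming pathways into a
#' total blood dose per THM analyte (ug/day). Timed activities are converted
#' from minutes/week to minutes/day; swimming uses pool concentrations rather
#' than the tap-water TWA. The shower + bath + swim sum is returned separately
#' (used as the non-ingestion exposure term in joint THM-HAA models).
#'
#' @param profile a [water_use_profile()].
#' @param twa named TWA concentrations per THM analyte (ug/L).
#' @param factors an [uptake_factor_table()].
#' @param analytes THM analytes to compute (default: those in `twa`).
#' @return list with `pathway` (matrix pathway x analyte, ug/day),
#'   `integrated` (named vector, the pathway sums) and `sbs` (shower + bath +
#'   swim sum per analyte).
#' @export
integrated_uptake <- function(profile, twa, factors = uptake_factor_table(),
                              analytes = intersect(names(twa), THM_ANALYTES)) {
  if (!length(analytes)) stop("no THM analytes in `twa`")
  pathway <- sapply(analytes, function(a) {
    if (is.na(twa[[a]])) return(rep(NA_real_, 4))
    c(ingestion = get_uptake_factor(factors, "ingestion", a) * twa[[a]] *
        effective_tap_volume(profile, a, factors),
      shower = get_uptake_factor(factors, "shower", a) * twa[[a]] *
        profile$shower_minwk / 7,
      bath = get_uptake_factor(factors, "bath", a) * twa[[a]] *
        profile$bath_minwk / 7,
      swim = get_uptake_factor(factors, "swim", a) * factors$pool_conc[[a]] *
        profile$swim_minwk / 7)
  })
  pathway <- matrix(pathway, nrow = 4,
                    dimnames = list(c("ingestion", "shower", "bath", "swim"),
                                    analytes))
  list(pathway = pathway,
       integrated = colSums(pathway),
       sbs = colSums(pathway[c("shower", "bath", "swim"), , drop = FALSE]))
}

#' Categorize exposure or water-use values
#'
#' `"tertile"` computes cutpoints at the 1/3 and 2/3 quantiles of the supplied
#' (analysis-population) values, with lower-closed intervals and a closed top
#' tertile; the cutpoints are attached as an attribute. The fixed water-use
#' schemes use the questionnaire bin edges: cold tap 0.0-0.4 / 0.6-1.0 /
#' 1.2-1.4 / >= 1.6 L/day; showering 0 / 1-60 / 61-105 / > 105 min/week;
#' bathing 0 / 1-60 / 61-120 / > 120 min/week; swimming yes vs no. Missing
#' values get missing labels, never a bin.
#'
#' @param values numeric vector.
#' @param scheme one of `"tertile"`, `"cold_tap"`, `"shower"`, `"bath"`,
#'   `"swim"`.
#' @return factor of category labels; tertile factors carry a `cutpoints`
#'   attribute.
#' @export
categorize <- function(values, scheme = c("tertile", "cold_tap", "shower",
                                          "bath", "swim")) {
  scheme <- match.arg(scheme)
  if (scheme == "tertile") {
    cut_lo <- stats::quantile(values, 1 / 3, na.rm = TRUE, names = FALSE)
    cut_hi <- stats::quantile(values, 2 / 3, na.rm = TRUE, names = FALSE)
    lab <- ifelse(is.na(values), NA_character_,
                  ifelse(values < cut_lo, "T1",
                         ifelse(values < cut_hi, "T2", "T3")))
    f <- factor(lab, levels = c("T1", "T2", "T3"))
    attr(f, "cutpoints") <- c(cut_lo, cut_hi)
    return(f)
  }
  lab <- switch(scheme,
    cold_tap = ifelse(values < 0.5, "0.0-0.4",
                ifelse(values < 1.1, "0.6-1.0",
                 ifelse(values < 1.5, "1.2-1.4", ">=1.6"))),
    shower = ifelse(values == 0, "0",
              ifelse(values <= 60, "1-60",
               ifelse(values <= 105, "61-105", ">105"))),
    bath = ifelse(values == 0, "0",
            ifelse(values <= 60, "1-60",
             ifelse(values <= 120, "61-120", ">120"))),
    swim = ifelse(values > 0, "yes", "no"))
  levels <- switch(scheme,
    cold_tap = c("0.0-0.4", "0.6-1.0", "1.2-1.4", ">=1.6"),
    shower = c("0", "1-60", "61-105", ">105"),
    bath = c("0", "1-60", "61-120", ">120"),
    swim = c("no", "yes"))
  factor(lab, levels = levels)
}

#' Spearman rank correlations between exposure metrics
#'
#' Pairwise-complete Spearman correlation matrix; metrics that are constant
#' over their complete pairs yield `NA` entries and a warning.
#'
#' @param profiles data.frame or matrix of exposure metrics (columns).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlate_metrics <- function(profiles) {
  m <- as.matrix(profiles)
  if (ncol(m) < 2) stop("need at least two metrics")
  const <- apply(m, 2, function(x) stats::sd(x, na.rm = TRUE) == 0)
  if (any(const, na.rm = TRUE)) {
    warning("constant metric(s), correlation undefined: ",
            paste(colnames(m)[which(const)], collapse = ", "))
  }
  suppressWarnings(
    rho <- stats::cor(m, method = "spearman", use = "pairwise.complete.obs"))
  diag(rho) <- ifelse(const | is.na(const), NA_real_, 1)
  rho
}

#' Workplace-assignment bookkeeping
#'
#' Counts employed women and those whose workplace zone could be assigned
#' (geocodable and inside the modelled zones), reporting the assignment rate.
#'
#' @param cohort data.frame with logical `employed` and `work_wsz` (`NA` when
#'   no workplace zone was assigned).
#' @return list with `n_employed`, `n_assigned` and the percentage
#'   `rate_pct`.
#' @export
workplace_assignment <- function(cohort) {
  employed <- cohort$employed %in% TRUE
  n_emp <- sum(employed)
  n_asg <- sum(employed & !is.na(cohort$work_wsz))
  list(n_employed = n_emp, n_assigned = n_asg,
       rate_pct = 100 * n_asg / n_emp)
}

#' Compute per-pregnancy, per-window exposure profiles
#'
#' Runs the whole exposure chain for every pregnancy and requested gestational
#' window: TWA concentrations per analyte, ingestion (with HAA3 and DBP7
#' aggregates), pathway-resolved and integrated THM uptake, the shower + bath
#' + swim TTHM term, and the DBP7 concentration aggregate. HAA-dependent
#' metrics are `NA` for pregnancies not covered by the HAA surface.
#'
#' @param cohort data.frame with `pregnancy_id`, `conception_date`,
#'   `delivery_date`, `residence_wsz`, `work_wsz` and the water-use columns of
#'   [water_use_profile()].
#' @param thm_surface monthly `"conc_surface"` rows for one or more THM
#'   analytes (stackable via `rbind`).
#' @param haa_surface quarterly surface rows for the HAAs, or `NULL`.
#' @param factors an [uptake_factor_table()].
#' @param windows subset of `c("whole", "T1", "T2", "T3")`.
#' @return data.frame, one row per pregnancy x window, with `twa_*`, `ing_*`,
#'   `up_*`, `sbs_TTHM` and `conc_DBP7` columns.
#' @export
compute_exposure <- function(cohort, thm_surface, haa_surface = NULL,
                             factors = uptake_factor_table(),
                             windows = c("whole", "T1", "T2", "T3")) {
  thm_analytes <- unique(thm_surface$analyte)
  haa_analytes <- if (!is.null(haa_surface)) unique(haa_surface$analyte) else character()
  split_surface <- function(surface, res) {
    lapply(stats::setNames(nm = unique(surface$analyte)), function(a) {
      s <- surface[surface$analyte == a, , drop = FALSE]
      structure(s, resolution = res, class = c("conc_surface", "data.frame"))
    })
  }
  thm_s <- split_surface(thm_surface, "month")
  haa_s <- if (length(haa_analytes)) split_surface(haa_surface, "quarter")
  rows <- vector("list", nrow(cohort) * length(windows))
  k <- 0
  for (i in seq_len(nrow(cohort))) {
    ci <- cohort[i, ]
    prof <- water_use_profile(
      tap_Lday = ci$tap_Lday, bottled_Lday = ci$bottled_Lday %||% 0,
      tea_Lday = ci$tea_Lday, coffee_Lday = ci$coffee_Lday,
      squash_Lday = ci$squash_Lday, filter_home = isTRUE(ci$filter_home),
      shower_minwk = ci$shower_minwk, bath_minwk = ci$bath_minwk,
      swim_minwk = ci$swim_minwk)
    for (wl in windows) {
      win <- tryCatch(exposure_window(wl, ci$conception_date, ci$delivery_date),
                      error = function(e) NULL)
      k <- k + 1
      if (is.null(win)) {
        rows[[k]] <- data.frame(pregnancy_id = ci$pregnancy_id, window = wl)
        next
      }
      twa <- vapply(thm_analytes, function(a) {
        twa_concentration(thm_s[[a]], win, ci$residence_wsz, ci$work_wsz)
      }, numeric(1))
      if (length(haa_analytes)) {
        twa_h <- vapply(haa_analytes, function(a) {
          twa_concentration(haa_s[[a]], win, ci$residence_wsz, ci$work_wsz)
        }, numeric(1))
        twa <- c(twa, twa_h)
      }
      ing <- ingestion(prof, twa, factors)
      up <- integrated_uptake(prof, twa, factors)
      row <- data.frame(pregnancy_id = ci$pregnancy_id, window = wl)
      for (a in names(twa)) row[[paste0("twa_", a)]] <- twa[[a]]
      for (a in names(ing)) row[[paste0("ing_", a)]] <- ing[[a]]
      for (a in names(up$integrated)) row[[paste0("up_", a)]] <- up$integrated[[a]]
      if ("TTHM" %in% names(up$sbs)) row$sbs_TTHM <- up$sbs[["TTHM"]]
      if (all(c("TTHM", HAA_ANALYTES) %in% names(twa))) {
        row$conc_DBP7 <- sum(twa[c("TTHM", HAA_ANALYTES)])
      }
      rows[[k]] <- row
    }
  }
  out <- do.call(rbind_fill, list(rows))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rbind data.frames with possibly different columns, filling with NA
rbind_fill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cl in setdiff(cols, names(d))) d[[cl]] <- NA
    d[cols]
  }))
}
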