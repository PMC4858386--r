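# Zone- and time-resolved predictive models of disinfection by-product
# concentrations, fitted to sparse routine monitoring data, and the
# concentration surfaces (analyte x WSZ x month/quarter) they emit.

# covariate sets selected per HAA analyte; selection itself is not re-run
HAA_COVARIATES <- list(
  DCAA  = c("conductivity", "temperature"),
  TCAA  = c("conductivity", "temperature", "toc"),
  BDCAA = c("conductivity", "total_chlorine")
)
HAA_TRANSFORM <- c(DCAA = "sqrt", TCAA = "sqrt", BDCAA = "log")

fwd_transform <- function(x, transform) switch(transform, log = log(x), sqrt = sqrt(x))
inv_transform <- function(x, transform) switch(transform, log = exp(x), sqrt = x^2)

# seasonal basis over month-of-year (1..12) or a continuous time index;
# returns a closure usable on new values
make_spline_basis <- function(x, df, cyclic = FALSE, period = 12) {
  if (cyclic) {
    k <- ceiling(df / 2)
    function(newx) {
      cols <- lapply(seq_len(k), function(h) {
        cbind(sin(2 * pi * h * newx / period), cos(2 * pi * h * newx / period))
      })
      do.call(cbind, cols)[, seq_len(df), drop = FALSE]
    }
  } else {
    B <- splines::ns(x, df = df)
    function(newx) stats::predict(B, newx)
  }
}

basis_frame <- function(Bmat) {
  Bd <- as.data.frame(Bmat)
  names(Bd) <- paste0(".b", seq_len(ncol(Bd)))
  Bd
}

#' Fit a seasonal zone-resolved THM concentration model
#'
#' Log-transformed concentrations are modelled by ordinary least squares with
#' a spline in month of year, a factor for calendar year and a factor for
#' water supply zone, yielding predicted monthly zone-specific means.
#' Bromoform is never fitted individually (most observations are censored);
#' model the brominated sum from [derive_thmbr()] instead.
#'
#' @param samples monitoring data.frame; censored values must already be
#'   half-LOD substituted (see [substitute_half_lod()]).
#' @param analyte one of `"chloroform"`, `"BDCM"`, `"DBCM"`, `"TTHM"`,
#'   `"THMBr"`.
#' @param month_df degrees of freedom of the month spline (default 4).
#' @param cyclic if TRUE use a periodic (Fourier) seasonal basis so December
#'   joins January smoothly; default FALSE (natural cubic spline).
#' @return an object of class `"thm_model"` with `coef`, `predict`, `print`
#'   methods.
#' @export
fit_thm_model <- function(samples, analyte, month_df = 4, cyclic = FALSE) {
  if (identical(analyte, "bromoform")) {
    stop("bromoform is not modelled individually; model THMBr instead")
  }
  if (!analyte %in% c("chloroform", "BDCM", "DBCM", "TTHM", "THMBr")) {
    stop("not a modellable THM analyte: ", analyte)
  }
  d <- samples[samples$analyte == analyte, , drop = FALSE]
  if (!nrow(d)) stop("no samples for analyte ", analyte)
  d <- validate_monitoring(d)
  if (any(d$below_lod & d$value != d$lod / 2)) {
    stop("censored samples present; apply substitute_half_lod() first")
  }
  if (any(d$value <= 0)) stop("non-positive concentrations cannot be log-transformed")
  d$year <- as.integer(format(d$sample_date, "%Y"))
  d$month <- as.integer(format(d$sample_date, "%m"))
  zones <- sort(unique(as.character(d$wsz_id)))
  years <- sort(unique(d$year))
  if (length(zones) < 2 || length(years) < 2) {
    stop("need samples from >= 2 zones and >= 2 years")
  }
  n_par <- 1 + month_df + (length(years) - 1) + (length(zones) - 1)
  if (nrow(d) <= n_par || length(unique(d$month)) <= month_df) {
    stop("singular design: ", nrow(d), " samples over ",
         length(unique(d$month)), " distinct months cannot identify ",
         n_par, " coefficients")
  }
  basis <- make_spline_basis(d$month, df = month_df, cyclic = cyclic)
  dat <- cbind(
    data.frame(.y = log(d$value),
               .year = factor(d$year, levels = years),
               .wsz = factor(as.character(d$wsz_id), levels = zones)),
    basis_frame(basis(d$month)))
  fml <- stats::as.formula(paste(
    ".y ~", paste(grep("^\\.b", names(dat), value = TRUE), collapse = " + "),
    "+ .year + .wsz"))
  fit <- stats::lm(fml, data = dat)
  if (anyNA(stats::coef(fit))) {
    stop("singular design; aliased terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  structure(list(
    fit = fit, analyte = analyte, transform = "log",
    basis = basis, month_df = month_df, cyclic = cyclic,
    zones = zones, years = years,
    sigma = summary(fit)$sigma,
    smear_factor = mean(exp(stats::residuals(fit))),
    train_cells = sort(unique(time_cell(d$sample_date, "month"))),
    resolution = "month", n = nrow(d)),
    class = "thm_model")
}

#' @export
print.thm_model <- function(x, ...) {
  cat("THM concentration model:", x$analyte, "\n")
  cat("  log scale; month spline df", x$month_df,
      if (x$cyclic) "(cyclic)" else "(natural)", "\n")
  cat("  ", length(x$zones), "zones,", length(x$years), "years,",
      x$n, "samples; residual sd", signif(x$sigma, 3), "\n")
  invisible(x)
}

#' @export
coef.thm_model <- function(object, ...) stats::coef(object$fit)

# shared prediction machinery: newdata has wsz_id + time_cell
predict_cells <- function(object, newdata, smearing = c("none", "duan")) {
  smearing <- match.arg(smearing)
  if (object$resolution == "month") {
    year <- as.integer(substr(newdata$time_cell, 1, 4))
    month <- as.integer(substr(newdata$time_cell, 6, 7))
    bad_year <- !year %in% object$years
    if (any(bad_year)) {
      stop("cells in years outside the training window: ",
           paste(unique(newdata$time_cell[bad_year]), collapse = ", "))
    }
    nd <- cbind(
      data.frame(.year = factor(year, levels = object$years),
                 .wsz = factor(as.character(newdata$wsz_id), levels = object$zones)),
      basis_frame(object$basis(month)))
  } else {
    qidx <- cell_index(newdata$time_cell)
    nd <- cbind(
      data.frame(.wsz = factor(as.character(newdata$wsz_id), levels = object$zones)),
      basis_frame(object$basis(qidx)))
    for (cv in object$covariates) {
      v <- object$cell_covariates[[cv]][paste(newdata$wsz_id, newdata$time_cell)]
      v[is.na(v)] <- object$covariate_means[[cv]]
      nd[[cv]] <- as.numeric(v)
    }
  }
  if (anyNA(nd$.wsz)) stop("zones outside the training set requested")
  pr <- stats::predict(object$fit, newdata = nd, se.fit = TRUE)
  eta <- as.numeric(pr$fit)
  value <- inv_transform(eta, object$transform)
  if (smearing == "duan" && object$transform == "log") {
    value <- value * object$smear_factor
  }
  # delta-method sd on the concentration scale
  se <- as.numeric(pr$se.fit)
  sd <- if (object$transform == "log") value * se else 2 * abs(eta) * se
  list(pred = value, sd = sd)
}

#' Predict monthly zone means from a THM model
#'
#' @param object a `"thm_model"`.
#' @param newdata data.frame with `wsz_id` and `time_cell` (`"YYYY-MM"`).
#' @param smearing `"none"` (naive back-transform, default) or `"duan"`
#'   (nonparametric smearing correction for the log-scale retransformation).
#' @param ... unused.
#' @return numeric vector of predicted mean concentrations (ug/L).
#' @export
predict.thm_model <- function(object, newdata, smearing = "none", ...) {
  predict_cells(object, newdata, smearing)$pred
}

#' Fit a quarterly HAA concentration model
#'
#' Square-root-transformed DCAA and TCAA and log-transformed BDCAA are
#' modelled with a water-supply-zone factor, a natural spline over continuous
#' quarter index, and analyte-specific water-chemistry covariates:
#' conductivity (all three), temperature (DCAA, TCAA), TOC (TCAA) and total
#' chlorine (BDCAA). These covariate sets are fixed, not re-selected.
#'
#' In `"frequentist"` mode missing covariates are mean-imputed and an OLS fit
#' is returned. In `"bayesian"` mode the same linear structure is sampled with
#' JAGS under weakly informative priors (normal(0, 100 sd) coefficients,
#' half-normal(5) residual scale); missing covariate entries are given normal
#' population submodels and imputed inside the sampler, and the posterior mean
#' surface is computed for every requested (zone, quarter) cell, including
#' cells with no samples at all. Convergence is checked with the
#' Gelman-Rubin diagnostic (two chains).
#'
#' @param samples monitoring data.frame restricted/filterable to one analyte.
#' @param analyte `"DCAA"`, `"TCAA"` or `"BDCAA"`.
#' @param mode `"frequentist"` or `"bayesian"`.
#' @param time_df spline degrees of freedom over quarter index (default 3).
#' @param grid_cells quarter cells for which a Bayesian posterior surface is
#'   required (defaults to the training quarters); ignored in frequentist mode.
#' @param zones zones of the surface (default: zones present in the data).
#' @param n_iter,n_burn MCMC iterations kept / discarded per chain.
#' @param rhat_max convergence threshold on the potential scale reduction
#'   factor (default 1.05).
#' @param seed integer seed for the MCMC.
#' @return an object of class `"haa_model"`.
#' @export
fit_haa_model <- function(samples, analyte, mode = c("frequentist", "bayesian"),
                          time_df = 3, grid_cells = NULL, zones = NULL,
                          n_iter = 2000, n_burn = 1000, rhat_max = 1.05,
                          seed = 1L) {
  mode <- match.arg(mode)
  if (!analyte %in% HAA_ANALYTES) {
    stop("not an HAA analyte: ", analyte, " (expected DCAA, TCAA or BDCAA)")
  }
  d <- samples[samples$analyte == analyte, , drop = FALSE]
  if (!nrow(d)) stop("no samples for analyte ", analyte)
  d <- validate_monitoring(d)
  d$sample_date <- as.Date(d$sample_date)
  if (any(d$below_lod & d$value != d$lod / 2)) {
    stop("censored samples present; apply substitute_half_lod() first")
  }
  transform <- HAA_TRANSFORM[[analyte]]
  covs <- HAA_COVARIATES[[analyte]]
  for (cv in covs) if (!cv %in% names(d)) d[[cv]] <- NA_real_
  d$cell <- time_cell(d$sample_date, "quarter")
  d$qidx <- cell_index(d$cell)
  if (is.null(zones)) zones <- sort(unique(as.character(d$wsz_id)))
  train_cells <- sort(unique(d$cell))
  basis <- make_spline_basis(d$qidx, df = time_df)

  # per-(zone, quarter) covariate means used when predicting cells that have
  # samples; cells without samples fall back to imputation
  cell_key <- paste(d$wsz_id, d$cell)
  cell_cov <- lapply(covs, function(cv) {
    tapply(d[[cv]], cell_key, mean, na.rm = TRUE)
  })
  names(cell_cov) <- covs
  cov_means <- lapply(covs, function(cv) mean(d[[cv]], na.rm = TRUE))
  names(cov_means) <- covs

  obj <- list(analyte = analyte, mode = mode, transform = transform,
              covariates = covs, basis = basis, time_df = time_df,
              zones = zones, train_cells = train_cells,
              cell_covariates = cell_cov, covariate_means = cov_means,
              resolution = "quarter", n = nrow(d))

  if (mode == "frequentist") {
    dat <- cbind(
      data.frame(.y = fwd_transform(d$value, transform),
                 .wsz = factor(as.character(d$wsz_id), levels = zones)),
      basis_frame(basis(d$qidx)))
    for (cv in covs) {
      v <- d[[cv]]
      v[is.na(v)] <- cov_means[[cv]]
      dat[[cv]] <- v
    }
    fml <- stats::as.formula(paste(
      ".y ~", paste(c(grep("^\\.b", names(dat), value = TRUE), ".wsz", covs),
                    collapse = " + ")))
    fit <- stats::lm(fml, data = dat)
    if (anyNA(stats::coef(fit))) {
      stop("singular design; aliased terms: ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
    }
    obj$fit <- fit
    obj$sigma <- summary(fit)$sigma
    obj$smear_factor <- if (transform == "log") mean(exp(stats::residuals(fit))) else NA_real_
  } else {
    if (is.null(grid_cells)) grid_cells <- train_cells
    obj <- c(obj, fit_haa_bayes(d, obj, grid_cells, n_iter, n_burn, rhat_max, seed))
    class(obj) <- "haa_model"
    if (!obj$converged) {
      warning("Bayesian HAA model for ", analyte,
              " did not reach R-hat < ", rhat_max,
              " (max R-hat ", signif(obj$rhat, 3), ")")
    }
    return(obj)
  }
  class(obj) <- "haa_model"
  obj
}

# JAGS backend: linear model on the transform scale with normal covariate
# submodels so missing covariate entries (training rows and empty prediction
# cells alike) are imputed as part of the posterior.
fit_haa_bayes <- function(d, obj, grid_cells, n_iter, n_burn, rhat_max, seed) {
  covs <- obj$covariates
  pred_grid <- expand.grid(wsz_id = obj$zones, time_cell = grid_cells,
                           stringsAsFactors = FALSE)
  # design rows: training first, prediction cells after
  all_wsz <- c(as.character(d$wsz_id), pred_grid$wsz_id)
  all_qidx <- c(d$qidx, cell_index(pred_grid$time_cell))
  B <- cbind(1, obj$basis(all_qidx),
             stats::model.matrix(~ 0 + f, data.frame(
               f = factor(all_wsz, levels = obj$zones)))[, -1, drop = FALSE])
  scale_tab <- t(vapply(covs, function(cv) {
    m <- mean(d[[cv]], na.rm = TRUE)
    s <- stats::sd(d[[cv]], na.rm = TRUE)
    if (!is.finite(m)) m <- 0
    if (!is.finite(s) || s == 0) s <- 1
    c(center = m, scale = s)
  }, numeric(2)))
  pred_key <- paste(pred_grid$wsz_id, pred_grid$time_cell)
  Z <- sapply(seq_along(covs), function(j) {
    cv <- covs[j]
    v <- c(d[[cv]], as.numeric(obj$cell_covariates[[cv]][pred_key]))
    (v - scale_tab[j, "center"]) / scale_tab[j, "scale"]
  })
  Z <- matrix(Z, ncol = length(covs))
  Z[is.nan(Z)] <- NA
  N <- nrow(d); M <- nrow(B); K <- ncol(B); P <- ncol(Z)
  y <- fwd_transform(d$value, obj$transform)

  model_str <- "
  model {
    for (i in 1:M) {
      mu[i] <- inprod(B[i, ], beta[]) + inprod(Z[i, ], gamma[])
      for (j in 1:P) { Z[i, j] ~ dnorm(muz[j], tauz[j]) }
    }
    for (i in 1:N) { y[i] ~ dnorm(mu[i], tau) }
    for (k in 1:K) { beta[k] ~ dnorm(0, 1.0E-4) }
    for (j in 1:P) {
      gamma[j] ~ dnorm(0, 1.0E-4)
      muz[j] ~ dnorm(0, 1.0E-4)
      sz[j] ~ dnorm(0, 0.04) T(0, )
      tauz[j] <- pow(sz[j], -2)
    }
    sigma ~ dnorm(0, 0.04) T(0, )
    tau <- pow(sigma, -2)
  }"
  inits <- lapply(1:2, function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + ch)
  })
  jm <- rjags::jags.model(textConnection(model_str),
                          data = list(y = y, B = B, Z = Z, N = N, M = M,
                                      K = K, P = P),
                          inits = inits, n.chains = 2, n.adapt = 500,
                          quiet = TRUE)
  stats::update(jm, n_burn, progress.bar = "none")
  samp <- rjags::coda.samples(
    jm, variable.names = c("beta", "gamma", "sigma", "mu"),
    n.iter = n_iter, progress.bar = "none")

  scalar_vars <- grep("^(beta|gamma|sigma)", coda::varnames(samp), value = TRUE)
  gd <- coda::gelman.diag(samp[, scalar_vars, drop = FALSE],
                          autoburnin = FALSE, multivariate = FALSE)
  rhat <- max(gd$psrf[, 1], na.rm = TRUE)

  draws <- do.call(rbind, lapply(samp, as.matrix))
  mu_pred <- draws[, paste0("mu[", N + seq_len(nrow(pred_grid)), "]"), drop = FALSE]
  conc <- inv_transform(mu_pred, obj$transform)  # back-transform per draw
  pred_grid$pred_ugL <- colMeans(conc)
  pred_grid$sd <- apply(conc, 2, stats::sd)

  gamma_cols <- grep("^gamma", colnames(draws), value = TRUE)
  g_mean <- colMeans(draws[, gamma_cols, drop = FALSE])
  g_sd <- apply(draws[, gamma_cols, drop = FALSE], 2, stats::sd)
  # sampled on the standardized covariate scale; report raw scale too
  gamma_summary <- data.frame(
    covariate = covs, mean = g_mean, sd = g_sd,
    mean_raw = g_mean / scale_tab[, "scale"],
    sd_raw = g_sd / scale_tab[, "scale"],
    row.names = NULL)
  list(posterior_surface = pred_grid, grid_cells = grid_cells,
       gamma = gamma_summary, covariate_scale = scale_tab,
       rhat = rhat, converged = rhat < rhat_max,
       sigma = mean(draws[, "sigma"]))
}

#' @export
print.haa_model <- function(x, ...) {
  cat("HAA concentration model:", x$analyte, sprintf("(%s mode)\n", x$mode))
  cat("  ", x$transform, "scale; quarter spline df", x$time_df,
      "; covariates:", paste(x$covariates, collapse = ", "), "\n")
  cat("  ", length(x$zones), "zones,", x$n, "samples\n")
  if (x$mode == "bayesian") {
    cat("   max R-hat", signif(x$rhat, 4),
        if (x$converged) "(converged)" else "(NOT converged)", "\n")
  }
  invisible(x)
}

#' @export
coef.haa_model <- function(object, ...) {
  if (object$mode == "frequentist") stats::coef(object$fit) else object$gamma
}

#' Predict quarterly zone means from a frequentist HAA model
#'
#' @param object a frequentist `"haa_model"`.
#' @param newdata data.frame with `wsz_id` and `time_cell` (`"YYYYQn"`).
#' @param smearing back-transform correction; `"duan"` applies only to the
#'   log-scale (BDCAA) model.
#' @param ... unused.
#' @return predicted mean concentrations (ug/L).
#' @export
predict.haa_model <- function(object, newdata, smearing = "none", ...) {
  if (object$mode == "bayesian") {
    key <- paste(newdata$wsz_id, newdata$time_cell)
    ps <- object$posterior_surface
    idx <- match(key, paste(ps$wsz_id, ps$time_cell))
    if (anyNA(idx)) {
      stop("cells not in the fitted posterior grid; refit with `grid_cells`")
    }
    return(ps$pred_ugL[idx])
  }
  predict_cells(object, newdata, smearing)$pred
}

#' Assemble a concentration surface from a fitted model
#'
#' Produces one predicted mean concentration per (zone, time cell) over the
#' requested grid plus any excluded (gap-filled) and extrapolated cells, with
#' a provenance flag per cell. Excluded cells must not have contributed to the
#' fit; extrapolation is refused beyond one grid step outside the training
#' window.
#'
#' @param model a `"thm_model"` or `"haa_model"`.
#' @param cells character vector of grid cells (defaults to the model's
#'   training cells, completed to a contiguous run).
#' @param exclusions cells whose data were withheld from training and which
#'   the model must gap-fill.
#' @param extrapolation cells at most one step beyond the training window.
#' @param zones zones to cover (default: model zones).
#' @param smearing back-transform correction, see [predict.thm_model()].
#' @return data.frame of class `"conc_surface"` with columns `analyte`,
#'   `wsz_id`, `time_cell`, `pred_ugL`, `sd`, `provenance`.
#' @export
build_surface <- function(model, cells = NULL, exclusions = character(),
                          extrapolation = character(), zones = model$zones,
                          smearing = "none") {
  if (is.null(cells)) {
    cells <- cell_seq(min(model$train_cells), max(model$train_cells))
  }
  if (length(exclusions) && any(exclusions %in% model$train_cells)) {
    stop("excluded cells are present in the training data; ",
         "remove them before fitting")
  }
  tr <- cell_index(model$train_cells)
  if (length(extrapolation)) {
    ex <- cell_index(extrapolation)
    if (any(ex < min(tr) - 1L | ex > max(tr) + 1L)) {
      stop("extrapolation beyond one grid step outside the training window refused")
    }
  }
  all_cells <- sort(unique(c(cells, exclusions, extrapolation)))
  grid <- expand.grid(wsz_id = zones, time_cell = all_cells,
                      stringsAsFactors = FALSE)
  if (inherits(model, "haa_model") && model$mode == "bayesian") {
    ps <- model$posterior_surface
    idx <- match(paste(grid$wsz_id, grid$time_cell),
                 paste(ps$wsz_id, ps$time_cell))
    if (anyNA(idx)) {
      stop("Bayesian surface grid does not cover all requested cells; ",
           "refit with `grid_cells` including them")
    }
    grid$pred_ugL <- ps$pred_ugL[idx]
    grid$sd <- ps$sd[idx]
  } else {
    pr <- predict_cells(model, grid, smearing)
    grid$pred_ugL <- pr$pred
    grid$sd <- pr$sd
  }
  grid$provenance <- "fitted"
  grid$provenance[grid$time_cell %in% exclusions] <- "gap_filled"
  grid$provenance[grid$time_cell %in% extrapolation] <- "extrapolated"
  out <- data.frame(analyte = model$analyte, grid, stringsAsFactors = FALSE)
  if (any(out$pred_ugL <= 0)) stop("non-positive prediction produced")
  structure(out, resolution = model$resolution,
            class = c("conc_surface", "data.frame"))
}

#' Fit a model and build its surface in one step
#'
#' Convenience wrapper: half-LOD substitutes, withholds excluded cells from
#' training, fits the analyte-appropriate model and returns the surface over
#' the full grid including gap-filled and extrapolated cells.
#'
#' @inheritParams fit_thm_model
#' @inheritParams fit_haa_model
#' @param resolution `"month"` (THMs) or `"quarter"` (HAAs).
#' @param grid_cells cells of the output grid; default spans the training data.
#' @param exclude_cells cells dropped from training and gap-filled.
#' @param extrapolate_cells cells predicted one step beyond the data.
#' @param ... passed to the model-fitting function.
#' @return list with `model` and `surface`.
#' @export
fit_concentration_surface <- function(samples, analyte,
                                      resolution = c("month", "quarter"),
                                      grid_cells = NULL,
                                      exclude_cells = character(),
                                      extrapolate_cells = character(),
                                      mode = "frequentist", ...) {
  resolution <- match.arg(resolution)
  samples <- substitute_half_lod(samples)
  d <- samples[samples$analyte == analyte, , drop = FALSE]
  d <- d[!time_cell(d$sample_date, resolution) %in% exclude_cells, , drop = FALSE]
  if (resolution == "month") {
    model <- fit_thm_model(d, analyte, ...)
  } else {
    if (is.null(grid_cells)) {
      cs <- time_cell(d$sample_date, "quarter")
      grid_cells <- cell_seq(min(cs), max(cs))
    }
    bayes_grid <- sort(unique(c(grid_cells, exclude_cells, extrapolate_cells)))
    model <- fit_haa_model(d, analyte, mode = mode, grid_cells = bayes_grid, ...)
  }
  surface <- build_surface(model, cells = grid_cells,
                           exclusions = exclude_cells,
                           extrapolation = extrapolate_cells)
  list(model = model, surface = surface)
}

#' Look up surface concentrations for one zone
#'
#' @param surface a `"conc_surface"`.
#' @param wsz_id one zone label.
#' @param cells cell labels; cells not covered return `NA`.
#' @return named numeric vector of concentrations over `cells`.
#' @export
surface_lookup <- function(surface, wsz_id, cells) {
  idx <- match(paste(wsz_id, cells), paste(surface$wsz_id, surface$time_cell))
  stats::setNames(surface$pred_ugL[idx], cells)
}

#' Write / read a concentration surface as CSV
#' @param surface a `"conc_surface"`. @param path file path.
#' @export
write_surface <- function(surface, path) {
  utils::write.csv(as.data.frame(surface), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(x, resolution = cell_resolution(x$time_cell),
            class = c("conc_surface", "data.frame"))
}
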