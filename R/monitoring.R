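# Water-quality monitoring records: one row per sample of one analyte in one
# water supply zone (WSZ) on one date.

THM_ANALYTES <- c("chloroform", "BDCM", "DBCM", "bromoform", "TTHM", "THMBr")
HAA_ANALYTES <- c("DCAA", "TCAA", "BDCAA")
ALL_ANALYTES <- c(THM_ANALYTES, HAA_ANALYTES)

#' Validate a monitoring-sample table
#'
#' Checks the column contract for monitoring data: `wsz_id`, `sample_date`,
#' `analyte`, `value` (ug/L), `below_lod` (logical) and `lod` (required and
#' positive where `below_lod` is TRUE). Optional water-chemistry covariate
#' columns (`conductivity`, `temperature`, `toc`, `total_chlorine`) may hold
#' missing values.
#'
#' @param samples data.frame of monitoring samples.
#' @return the input, invisibly, with `sample_date` coerced to `Date`.
#' @export
validate_monitoring <- function(samples) {
  required <- c("wsz_id", "sample_date", "analyte", "value", "below_lod")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("monitoring table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  samples$sample_date <- as.Date(samples$sample_date)
  bad <- !samples$analyte %in% ALL_ANALYTES
  if (any(bad)) stop("unknown analyte(s): ", paste(unique(samples$analyte[bad]), collapse = ", "))
  if (any(samples$value < 0, na.rm = TRUE)) stop("negative concentrations present")
  cens <- which(samples$below_lod)
  if (length(cens)) {
    if (!"lod" %in% names(samples) || anyNA(samples$lod[cens]) ||
        any(samples$lod[cens] <= 0)) {
      stop("below-LOD samples must carry a positive `lod`")
    }
  }
  invisible(samples)
}

#' Substitute half the detection limit for censored samples
#'
#' Samples flagged below the limit of detection are assigned a value equal to
#' half their LOD; detected samples pass through unchanged and row order is
#' preserved.
#'
#' @param samples monitoring data.frame (see [validate_monitoring()]).
#' @return the table with censored values replaced by `lod / 2`.
#' @export
substitute_half_lod <- function(samples) {
  samples <- validate_monitoring(samples)
  cens <- which(samples$below_lod)
  if (length(cens)) samples$value[cens] <- samples$lod[cens] / 2
  samples
}

#' Derive total brominated THMs at the sample level
#'
#' Sums BDCM, DBCM and bromoform values sharing a zone and date into THMBr
#' rows. Bromoform is heavily left-censored in routine monitoring and is never
#' modelled individually; the brominated sum is modelled instead. Censored
#' components should be half-LOD substituted before summation.
#'
#' @param samples monitoring data.frame containing the three brominated THMs.
#' @return data.frame of THMBr rows (columns as the input, `below_lod` FALSE).
#' @export
derive_thmbr <- function(samples) {
  comp <- samples[samples$analyte %in% c("BDCM", "DBCM", "bromoform"), , drop = FALSE]
  if (!nrow(comp)) stop("no brominated THM component rows present")
  if (any(comp$below_lod & comp$value != comp$lod / 2)) {
    stop("apply substitute_half_lod() before deriving THMBr")
  }
  key <- interaction(comp$wsz_id, comp$sample_date, drop = TRUE)
  agg <- stats::aggregate(comp$value, by = list(key = key), FUN = sum)
  first <- comp[!duplicated(key), c("wsz_id", "sample_date"), drop = FALSE]
  first <- first[match(agg$key, unique(key)), , drop = FALSE]
  out <- data.frame(wsz_id = first$wsz_id, sample_date = first$sample_date,
                    analyte = "THMBr", value = agg$x, below_lod = FALSE,
                    lod = NA_real_, stringsAsFactors = FALSE)
  for (cv in intersect(c("conductivity", "temperature", "toc", "total_chlorine"),
                       names(samples))) {
    out[[cv]] <- comp[[cv]][!duplicated(key)][match(agg$key, unique(key))]
  }
  rownames(out) <- NULL
  out
}

#' Read monitoring samples from CSV
#'
#' @param path CSV with columns `wsz_id, date, analyte, value, below_lod, lod`
#'   and optional covariates; `date` is ISO-8601.
#' @return validated monitoring data.frame with a `sample_date` column.
#' @export
read_monitoring <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("date" %in% names(x) && !"sample_date" %in% names(x)) {
    names(x)[names(x) == "date"] <- "sample_date"
  }
  x$below_lod <- as.logical(x$below_lod)
  validate_monitoring(x)
  x$sample_date <- as.Date(x$sample_date)
  x
}
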