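# Study-population assembly: the eligibility cascade and complete-case
# restriction for model fitting.

#' Apply the eligibility cascade
#'
#' Restricts a table of pregnancy records to the analysis population in a
#' fixed stage order: singleton births; one pregnancy per mother (a seeded
#' uniform random choice among her pregnancies); water-use data present; THM
#' exposure computable for all trimesters; birth weight present; term delivery
#' (>= 37 completed weeks). Each stage's exclusions are logged.
#'
#' @param records data.frame with columns `mother_id`, `pregnancy_id`,
#'   `singleton` (logical), `gestational_age_wk`, `birth_weight_g`; water-use
#'   availability is read from `water_use_missing` if present, otherwise from
#'   missingness of `tap_Lday`; THM computability from a logical
#'   `thm_computable` column (assumed TRUE when absent).
#' @param seed integer seed controlling the repeated-pregnancy choice; the
#'   same seed reproduces the same selection exactly.
#' @return list with `records` (eligible rows) and `log` (a `"cascade_log"`
#'   data.frame of stage, n_excluded, n_remaining).
#' @export
apply_exclusions <- function(records, seed = 1L) {
  log <- data.frame(stage = "input", n_excluded = 0L,
                    n_remaining = nrow(records), stringsAsFactors = FALSE)
  note <- function(stage, keep) {
    log <<- rbind(log, data.frame(
      stage = stage, n_excluded = sum(!keep), n_remaining = sum(keep),
      stringsAsFactors = FALSE))
    keep
  }
  if (nrow(records) == 0) {
    return(list(records = records,
                log = structure(log, class = c("cascade_log", "data.frame"))))
  }

  records <- records[note("singleton", records$singleton %in% TRUE), , drop = FALSE]

  # one pregnancy per mother, chosen uniformly at random under the seed
  keep <- rep(TRUE, nrow(records))
  dup_mothers <- unique(records$mother_id[duplicated(records$mother_id)])
  if (length(dup_mothers)) {
    rng <- local({ set.seed(seed); function(n) sample.int(n, 1L) })
    for (m in dup_mothers) {
      idx <- which(records$mother_id == m)
      keep[idx[-rng(length(idx))]] <- FALSE
    }
  }
  records <- records[note("one_pregnancy_per_mother", keep), , drop = FALSE]

  wu_missing <- if ("water_use_missing" %in% names(records)) {
    records$water_use_missing %in% TRUE
  } else {
    is.na(records$tap_Lday)
  }
  records <- records[note("water_use_present", !wu_missing), , drop = FALSE]

  thm_ok <- if ("thm_computable" %in% names(records)) {
    records$thm_computable %in% TRUE
  } else {
    rep(TRUE, nrow(records))
  }
  records <- records[note("thm_computable_all_trimesters", thm_ok), , drop = FALSE]

  records <- records[note("birth_weight_present",
                          !is.na(records$birth_weight_g)), , drop = FALSE]
  records <- records[note("term_birth",
                          records$gestational_age_wk >= 37), , drop = FALSE]

  rownames(records) <- NULL
  list(records = records,
       log = structure(log, class = c("cascade_log", "data.frame")))
}

#' @export
print.cascade_log <- function(x, ...) {
  cat("Eligibility cascade:\n")
  for (i in seq_len(nrow(x))) {
    if (x$stage[i] == "input") {
      cat(sprintf("  %-32s n = %d\n", "input", x$n_remaining[i]))
    } else {
      cat(sprintf("  %-32s -%-6d n = %d\n", x$stage[i], x$n_excluded[i],
                  x$n_remaining[i]))
    }
  }
  invisible(x)
}

#' Complete-case restriction for a covariate set
#'
#' Drops records missing any of the listed covariates (model fitting is
#' complete-case; no imputation) and reports per-covariate missingness.
#'
#' @param records data.frame of pregnancy records.
#' @param covariates character vector of covariate column names.
#' @return the retained rows, with a `missingness` attribute giving the
#'   per-covariate count of missing values in the input.
#' @export
complete_case <- function(records, covariates) {
  unknown <- setdiff(covariates, names(records))
  if (length(unknown)) {
    stop("unknown covariate(s): ", paste(unknown, collapse = ", "))
  }
  miss <- vapply(covariates, function(v) sum(is.na(records[[v]])), integer(1))
  keep <- stats::complete.cases(records[covariates])
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missingness") <- miss
  out
}
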