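# Calendar grid used by concentration surfaces and time weighting.
# Month cells are "YYYY-MM"; quarter cells are "YYYYQn".

#' Time cell containing a date
#'
#' @param date a `Date` vector.
#' @param resolution `"month"` or `"quarter"`.
#' @return character vector of cell labels (`"2008-03"` or `"2008Q1"`).
#' @export
time_cell <- function(date, resolution = c("month", "quarter")) {
  resolution <- match.arg(resolution)
  date <- as.Date(date)
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  if (resolution == "month") {
    sprintf("%04d-%02d", y, m)
  } else {
    sprintf("%04dQ%d", y, (m - 1L) %/% 3L + 1L)
  }
}

cell_resolution <- function(cell) {
  if (all(grepl("^\\d{4}-\\d{2}$", cell))) "month"
  else if (all(grepl("^\\d{4}Q[1-4]$", cell))) "quarter"
  else stop("unrecognised time cell format: ", paste(utils::head(cell), collapse = ", "))
}

# cell -> integer index on a common axis (months since 0 AD, or quarters)
cell_index <- function(cell) {
  res <- cell_resolution(cell)
  if (res == "month") {
    y <- as.integer(substr(cell, 1, 4)); m <- as.integer(substr(cell, 6, 7))
    y * 12L + (m - 1L)
  } else {
    y <- as.integer(substr(cell, 1, 4)); q <- as.integer(substr(cell, 6, 6))
    y * 4L + (q - 1L)
  }
}

index_to_cell <- function(idx, resolution) {
  if (resolution == "month") {
    sprintf("%04d-%02d", idx %/% 12L, idx %% 12L + 1L)
  } else {
    sprintf("%04dQ%d", idx %/% 4L, idx %% 4L + 1L)
  }
}

#' First and last calendar day of a time cell
#'
#' @param cell character vector of cell labels.
#' @return data.frame with `start` and `end` Date columns.
#' @export
cell_bounds <- function(cell) {
  res <- cell_resolution(cell)
  if (res == "month") {
    start <- as.Date(paste0(cell, "-01"))
    end <- seq_months(start, 1L) - 1L
  } else {
    y <- substr(cell, 1, 4); q <- as.integer(substr(cell, 6, 6))
    start <- as.Date(sprintf("%s-%02d-01", y, (q - 1L) * 3L + 1L))
    end <- seq_months(start, 3L) - 1L
  }
  data.frame(cell = cell, start = start, end = end, stringsAsFactors = FALSE)
}

# vectorised "first day of the month k months later"
seq_months <- function(start, k) {
  y <- as.integer(format(start, "%Y"))
  m <- as.integer(format(start, "%m")) + k
  y <- y + (m - 1L) %/% 12L
  m <- (m - 1L) %% 12L + 1L
  as.Date(sprintf("%04d-%02d-01", y, m))
}

#' Sequence of consecutive time cells
#'
#' @param from,to cell labels of the same resolution (inclusive).
#' @return character vector of consecutive cells.
#' @export
cell_seq <- function(from, to) {
  res <- cell_resolution(c(from, to))
  i0 <- cell_index(from); i1 <- cell_index(to)
  if (i1 < i0) stop("`to` precedes `from`")
  index_to_cell(seq.int(i0, i1), res)
}

#' Shift a cell by a number of grid steps
#' @param cell cell label. @param k integer steps (may be negative).
#' @export
cell_shift <- function(cell, k) {
  index_to_cell(cell_index(cell) + as.integer(k), cell_resolution(cell))
}

#' Gestational exposure windows
#'
#' Trimesters use fixed gestational-day cuts: first trimester days 1-93,
#' second days 94-186, third from day 187 to the day preceding delivery; the
#' whole-pregnancy window runs from day 1 to the day preceding delivery.
#'
#' @param label one of `"whole"`, `"T1"`, `"T2"`, `"T3"`.
#' @param conception_date,delivery_date `Date`s; day 1 is the conception date.
#' @return list with `label`, `start_day`, `end_day`, `start_date`, `end_date`.
#' @export
exposure_window <- function(label = c("whole", "T1", "T2", "T3"),
                            conception_date, delivery_date) {
  label <- match.arg(label)
  conception_date <- as.Date(conception_date)
  delivery_date <- as.Date(delivery_date)
  if (delivery_date <= conception_date) stop("delivery must follow conception")
  last_day <- as.integer(delivery_date - conception_date)  # day before delivery
  bounds <- switch(label,
    whole = c(1L, last_day),
    T1 = c(1L, 93L),
    T2 = c(94L, 186L),
    T3 = c(187L, last_day))
  if (bounds[2] < bounds[1]) {
    stop("empty window: pregnancy ends before gestational day ", bounds[1])
  }
  list(label = label, start_day = bounds[1], end_day = bounds[2],
       start_date = conception_date + bounds[1] - 1L,
       end_date = conception_date + bounds[2] - 1L)
}

#' Time weights of an exposure window over a calendar grid
#'
#' Weight of a cell is the fraction of the window's days falling inside that
#' calendar month or quarter; weights are nonnegative and sum to one.
#'
#' @param window a window from [exposure_window()].
#' @param resolution `"month"` or `"quarter"`.
#' @return named numeric vector, names are cell labels.
#' @export
compute_time_weights <- function(window, resolution = c("month", "quarter")) {
  resolution <- match.arg(resolution)
  cells <- cell_seq(time_cell(window$start_date, resolution),
                    time_cell(window$end_date, resolution))
  b <- cell_bounds(cells)
  overlap <- as.integer(pmin(b$end, window$end_date) -
                        pmax(b$start, window$start_date)) + 1L
  n_days <- as.integer(window$end_date - window$start_date) + 1L
  stats::setNames(overlap / n_days, cells)
}
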