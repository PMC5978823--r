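#' Day-indexed multivariate rating series
#'
#' A `rating_matrix` holds one person's daily ratings on a set of symptom
#' items as a calendar-complete day-by-item matrix. Every calendar day from
#' the first to the last observed date is materialized, with `NA` marking
#' cells that were not rated, so downstream lag-1 logic can distinguish a
#' skipped day from a consecutive pair unambiguously.
#'
#' @param values Numeric matrix, days in rows and items in columns. `NA`
#'   marks unobserved cells.
#' @param dates `Date` vector, one per row of `values`, strictly increasing
#'   and consecutive (one entry per calendar day).
#' @param items Character vector of item labels, one per column.
#' @param scales Optional character vector assigning each item to a scale
#'   (e.g. Depression, Anxiety); purely descriptive.
#'
#' @return An object of class `rating_matrix` with elements `values`,
#'   `dates`, `items`, `scales` and the logical mask `observed`.
#' @export
rating_matrix <- function(values, dates, items = colnames(values),
                          scales = NULL) {
  values <- as.matrix(values)
  if (is.null(items)) items <- paste0("item", seq_len(ncol(values)))
  dates <- as.Date(dates)
  if (length(dates) != nrow(values))
    stop("length(dates) must equal nrow(values)")
  if (anyNA(dates)) stop("dates contain NA")
  if (any(duplicated(dates))) stop("duplicate dates: ",
                                   paste(dates[duplicated(dates)], collapse = ", "))
  if (is.unsorted(dates, strictly = TRUE)) {
    ord <- order(dates)
    dates <- dates[ord]
    values <- values[ord, , drop = FALSE]
  }
  # pad to a calendar-complete span
  full <- seq(min(dates), max(dates), by = "day")
  if (length(full) != length(dates)) {
    padded <- matrix(NA_real_, length(full), ncol(values))
    padded[match(dates, full), ] <- values
    values <- padded
    dates <- full
  }
  storage.mode(values) <- "double"
  if (any(is.infinite(values), na.rm = TRUE))
    stop("observed values must be finite")
  observed <- !is.na(values)
  if (sum(rowSums(observed) > 0) < 2)
    stop("need at least 2 observed days")
  if (ncol(values) < 1) stop("need at least 1 item")
  if (!is.null(scales) && length(scales) != length(items))
    stop("scales must have one entry per item")
  dimnames(values) <- list(as.character(dates), items)
  structure(list(values = values, dates = dates, items = items,
                 scales = scales, observed = observed),
            class = "rating_matrix")
}

#' @param x A `rating_matrix`.
#' @param ... Unused.
#' @rdname rating_matrix
#' @export
print.rating_matrix <- function(x, ...) {
  cs <- coverage_summary(x)
  cat(sprintf("<rating_matrix> %d items, %d-day span (%s to %s), %d observed days\n",
              length(x$items), cs$span_days, min(x$dates), max(x$dates),
              cs$observed_days))
  invisible(x)
}

#' @export
dim.rating_matrix <- function(x) dim(x$values)

#' Read daily ratings from CSV
#'
#' Reads a wide (`date,<item1>,<item2>,...`) or long (`date,item,value`) CSV
#' of daily ratings into a [rating_matrix()]. Dates are ISO-8601. Days absent
#' from the file (or rows/cells left empty) are treated as unobserved; the
#' returned object always spans every calendar day from the first to the
#' last observed date.
#'
#' @param path Path to a CSV file.
#' @param layout `"wide"` or `"long"`.
#' @return A [rating_matrix()].
#' @export
read_ratings <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 colClasses = "character")
  names(df)[tolower(names(df)) == "date"] <- "date"
  if (!"date" %in% names(df))
    stop("CSV must contain a 'date' column")
  dates <- as.Date(df$date)
  if (anyNA(dates)) stop("unparseable date: ",
                         df$date[which(is.na(dates))[1]])
  if (layout == "wide") {
    item_cols <- setdiff(names(df), "date")
    if (length(item_cols) < 1) stop("wide CSV has no item columns")
    if (any(duplicated(dates)))
      stop(sprintf("duplicate cell (%s, %s)",
                   dates[duplicated(dates)][1], item_cols[1]))
    vals <- sapply(item_cols, function(cn) parse_numeric(df[[cn]], dates, cn))
    vals <- matrix(vals, nrow = length(dates),
                   dimnames = list(NULL, item_cols))
    keep <- rowSums(!is.na(vals)) > 0
    rating_matrix(vals[keep, , drop = FALSE], dates[keep], item_cols)
  } else {
    need <- c("date", "item", "value")
    names(df)[tolower(names(df)) == "item"] <- "item"
    names(df)[tolower(names(df)) == "value"] <- "value"
    if (!all(need %in% names(df)))
      stop("long CSV must have columns date,item,value")
    dup <- duplicated(paste(dates, df$item))
    if (any(dup))
      stop(sprintf("duplicate cell (%s, %s)", dates[dup][1], df$item[dup][1]))
    items <- unique(df$item)
    full_dates <- sort(unique(dates))
    vals <- matrix(NA_real_, length(full_dates), length(items),
                   dimnames = list(NULL, items))
    v <- parse_numeric(df$value, dates, df$item)
    vals[cbind(match(dates, full_dates), match(df$item, items))] <- v
    rating_matrix(vals, full_dates, items)
  }
}

# strict numeric parse; empty/NA strings become NA, anything else must parse
parse_numeric <- function(x, dates, label) {
  x <- trimws(x)
  blank <- is.na(x) | x == "" | toupper(x) == "NA"
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!blank & is.na(out))
  if (length(bad)) {
    lab <- if (length(label) == length(x)) label[bad[1]] else label[1]
    stop(sprintf("non-numeric value '%s' at (%s, %s)", x[bad[1]],
                 dates[bad[1]], lab))
  }
  out[blank] <- NA_real_
  out
}

#' Write daily ratings to CSV
#'
#' Inverse of [read_ratings()]: the observed cells round-trip bit-exactly
#' through either layout. Fully unobserved days are omitted from the file.
#'
#' @param rm A [rating_matrix()].
#' @param path Output CSV path.
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(rm, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  if (layout == "wide") {
    keep <- rowSums(rm$observed) > 0
    out <- data.frame(date = as.character(rm$dates[keep]),
                      apply(rm$values[keep, , drop = FALSE], 2, fmt),
                      check.names = FALSE, stringsAsFactors = FALSE)
    colnames(out) <- c("date", rm$items)
  } else {
    idx <- which(rm$observed, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    out <- data.frame(date = as.character(rm$dates[idx[, 1]]),
                      item = rm$items[idx[, 2]],
                      value = fmt(rm$values[idx]),
                      stringsAsFactors = FALSE)
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize observation coverage
#'
#' Counts observed days overall and per item, the calendar span, and the
#' longest run of consecutive unobserved days — the quantities that matter
#' when judging how many valid day-to-day lag pairs a series can support.
#'
#' @param rm A [rating_matrix()].
#' @return A list with `observed_days` (days with at least one observed
#'   item), `span_days`, `longest_gap`, and a per-item data frame `items`.
#' @export
coverage_summary <- function(rm) {
  stopifnot(inherits(rm, "rating_matrix"))
  day_obs <- rowSums(rm$observed) > 0
  longest_run <- function(missing) {
    if (!any(missing)) return(0L)
    r <- rle(missing)
    max(c(0L, r$lengths[r$values]))
  }
  per_item <- data.frame(
    item = rm$items,
    observed_days = colSums(rm$observed),
    longest_gap = vapply(seq_along(rm$items),
                         function(j) longest_run(!rm$observed[, j]), integer(1)),
    stringsAsFactors = FALSE)
  list(observed_days = sum(day_obs),
       span_days = length(rm$dates),
       longest_gap = longest_run(!day_obs),
       items = per_item)
}

#' Coerce a wide data frame to a rating matrix
#'
#' @param data A data frame with a date column and one numeric column per
#'   item, or an existing [rating_matrix()] (returned unchanged).
#' @param date_col Name of the date column.
#' @return A [rating_matrix()].
#' @export
as_rating_matrix <- function(data, date_col = "date") {
  if (inherits(data, "rating_matrix")) return(data)
  stopifnot(is.data.frame(data), date_col %in% names(data))
  items <- setdiff(names(data), date_col)
  vals <- as.matrix(data[items])
  keep <- rowSums(!is.na(vals)) > 0
  rating_matrix(vals[keep, , drop = FALSE], as.Date(data[[date_col]])[keep],
                items)
}
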