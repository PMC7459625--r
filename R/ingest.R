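#' @include AllClasses.R
NULL

#' Read raw movement counts from CSV
#'
#' Expects one row per sensor interval with an animal identifier, an
#' ISO 8601 timestamp and a non-negative integer movement count.
#' Validation failures name the offending row.
#'
#' @param path CSV file path.
#' @param idCol,timeCol,countCol column names (defaults \code{animal_id},
#'   \code{timestamp}, \code{count}).
#' @param tz timezone for timestamp parsing (default UTC).
#' @param sep,dec field and decimal separators.
#' @return named list of \linkS4class{MovementCountSeries}, one per
#'   animal.
#' @export
readMovementCounts <- function(path, idCol = "animal_id",
                               timeCol = "timestamp", countCol = "count",
                               tz = "UTC", sep = ",", dec = ".") {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, sep = sep, dec = dec)
  need <- c(idCol, timeCol, countCol)
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  ts <- as.POSIXct(d[[timeCol]], tz = tz,
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  if (any(is.na(ts)))
    stop("unparseable timestamp at row ", which(is.na(ts))[1])
  cnt <- d[[countCol]]
  bad <- which(is.na(cnt) | cnt < 0 | cnt != round(cnt))
  if (length(bad))
    stop("invalid count (must be a non-negative integer) at row ", bad[1],
         ": ", cnt[bad[1]])
  out <- lapply(split(seq_len(nrow(d)), d[[idCol]]), function(i) {
    i <- i[order(ts[i])]
    dup <- which(duplicated(as.numeric(ts[i])))
    if (length(dup))
      stop("duplicated timestamp for animal ", d[[idCol]][i[1]],
           " at row ", i[dup[1]])
    movementCountSeries(d[[idCol]][i[1]], ts[i], as.integer(cnt[i]))
  })
  out[order(names(out))]
}

#' Write movement-count series to CSV
#'
#' Inverse of \code{\link{readMovementCounts}}; round-trips exactly at
#' minute resolution.
#'
#' @param series list of \linkS4class{MovementCountSeries}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeMovementCounts <- function(series, path) {
  rows <- do.call(rbind, lapply(series, function(s)
    data.frame(animal_id = s@animalId,
               timestamp = format(s@timestamps, "%Y-%m-%dT%H:%M:%S",
                                  tz = "UTC"),
               count = s@counts)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.parseClock <- function(x) {
  parts <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
  parts[1] * 3600 + parts[2] * 60
}

#' Nightly cumulative activity
#'
#' Sums movement counts over the nocturnal window (default 18:00 to
#' 06:00, half-open, spanning midnight). Each night is labelled by the
#' calendar date on which it starts. Nights whose expected number of
#' sensor intervals is not fully observed are flagged incomplete.
#'
#' @param series a \linkS4class{MovementCountSeries}.
#' @param nightStart,nightEnd clock times "HH:MM"; the window runs from
#'   nightStart through midnight to nightEnd (exclusive).
#' @return data.frame with columns \code{night} (Date), \code{total}
#'   (integer), \code{n_intervals} and \code{complete}. Empty (with a
#'   warning) when the series covers no night interval.
#' @export
nightlyActivity <- function(series, nightStart = "18:00", nightEnd = "06:00") {
  stopifnot(is(series, "MovementCountSeries"))
  startSec <- .parseClock(nightStart)
  endSec <- .parseClock(nightEnd)
  if (endSec >= startSec)
    stop("night window must span midnight (nightStart after nightEnd)")
  ts <- series@timestamps
  tod <- as.numeric(ts) %% 86400
  date <- as.Date(ts, tz = "UTC")
  inEvening <- tod >= startSec
  inMorning <- tod < endSec
  keep <- inEvening | inMorning
  if (!any(keep)) {
    warning("series contains no observations in the night window")
    return(data.frame(night = as.Date(character()), total = integer(),
                      n_intervals = integer(), complete = logical()))
  }
  night <- date
  night[inMorning] <- night[inMorning] - 1L
  night <- night[keep]
  cnt <- series@counts[keep]
  spacing <- if (length(ts) >= 2) diff(as.numeric(ts))[1] else 60
  expected <- round((86400 - startSec + endSec) / spacing)
  agg <- tapply(cnt, night, sum)
  nInt <- tapply(cnt, night, length)
  data.frame(night = as.Date(names(agg)),
             total = as.integer(agg),
             n_intervals = as.integer(nInt),
             complete = as.integer(nInt) == expected,
             row.names = NULL)
}

#' Log-transform nightly totals
#'
#' @param totals positive counts.
#' @param base logarithm base (default 10; a nightly total of 10000
#'   movements maps to 4.0).
#' @return numeric log activities.
#' @export
toLogActivity <- function(totals, base = 10) {
  if (any(totals <= 0))
    stop("non-positive nightly total at position ", which(totals <= 0)[1],
         "; exclude or impute degenerate nights explicitly")
  log(totals, base = base)
}

#' Assemble the analysis panel
#'
#' Joins per-animal nightly log activities with the dose map and converts
#' calendar nights to day indices relative to the irradiation date
#' (day 0 = the night starting on the irradiation date). Incomplete
#' nights are excluded.
#'
#' @param nightly named list (by animal id) of data.frames as returned by
#'   \code{\link{nightlyActivity}}.
#' @param doseMap named numeric vector: dose in Gy per animal id.
#' @param irradiationDate Date of irradiation.
#' @param base log base passed to \code{\link{toLogActivity}}.
#' @return An \linkS4class{ActivityPanel}.
#' @export
assemblePanel <- function(nightly, doseMap, irradiationDate, base = 10) {
  irradiationDate <- as.Date(irradiationDate)
  miss <- setdiff(names(nightly), names(doseMap))
  if (length(miss))
    stop("no dose assigned for animal(s): ", paste(miss, collapse = ", "))
  rows <- do.call(rbind, lapply(names(nightly), function(a) {
    nt <- nightly[[a]]
    nt <- nt[nt$complete & nt$total > 0, ]
    if (!nrow(nt)) return(NULL)
    data.frame(animal_id = a,
               dose_gy = unname(doseMap[[a]]),
               day = as.integer(nt$night - irradiationDate),
               log_activity = toLogActivity(nt$total, base = base))
  }))
  if (is.null(rows) || !nrow(rows))
    stop("no complete, positive nights to assemble")
  activityPanel(rows)
}

#' Read an activity panel from CSV
#'
#' Tidy-panel dialect: columns \code{animal_id}, \code{dose_gy},
#' \code{day}, \code{log_activity}.
#'
#' @param path CSV file path.
#' @param sep,dec field and decimal separators.
#' @return An \linkS4class{ActivityPanel}.
#' @export
readActivityPanel <- function(path, sep = ",", dec = ".") {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, sep = sep, dec = dec)
  need <- c("animal_id", "dose_gy", "day", "log_activity")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(d$log_activity))
  if (length(bad))
    stop("non-finite log_activity at row ", bad[1])
  activityPanel(d)
}

#' Write an activity panel to CSV
#'
#' @param panel an \linkS4class{ActivityPanel}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeActivityPanel <- function(panel, path) {
  stopifnot(is(panel, "ActivityPanel"))
  utils::write.csv(panel@data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
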