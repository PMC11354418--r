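#' Read an individual-level rearing log
#'
#' A rearing log is a wide CSV with one row per reared individual: the diet
#' and generation labels, one entry date per developmental stage reached
#' (`date_EG` is the oviposition date, the biofix), the death date and stage,
#' the adult sex, and the fecundity counts for females. Dates are ISO-8601.
#'
#' Validation is collect-all: every problem in the file is reported in a
#' single error, naming the offending `individual_id`, because hand-entered
#' logs typically carry more than one mistake.
#'
#' @param path path to a CSV file with columns `individual_id`, `diet`,
#'   `generation`, `date_EG` ... `date_AD`, `death_date`, `death_stage`,
#'   `sex`, `eggs_laid`, `eggs_hatched`.
#' @return A `rearing_log` data frame (one row per individual, dates as
#'   `Date`).
#' @export
read_rearing_log <- function(path) {
  if (!file.exists(path)) stop("rearing log not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = c("", "NA"))
  as_rearing_log(df)
}

#' Coerce and validate a data frame as a rearing log
#'
#' @param df data frame with the rearing-log columns (dates either `Date` or
#'   ISO-8601 strings).
#' @return validated `rearing_log` data frame.
#' @export
as_rearing_log <- function(df) {
  required <- c("individual_id", "diet", "generation", stage_date_cols(),
                "death_date", "death_stage", "sex", "eggs_laid", "eggs_hatched")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("rearing log is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[required]
  for (col in c(stage_date_cols(), "death_date")) {
    df[[col]] <- as.Date(df[[col]])
  }
  df$generation <- as.integer(df$generation)
  df$eggs_laid <- as.integer(df$eggs_laid)
  df$eggs_hatched <- as.integer(df$eggs_hatched)
  df$individual_id <- as.character(df$individual_id)
  df$diet <- as.character(df$diet)
  df$death_stage <- as.character(df$death_stage)
  df$sex <- as.character(df$sex)
  issues <- validate_rearing_log(df)
  if (length(issues)) {
    stop("invalid rearing log:\n", paste0("  - ", issues, collapse = "\n"))
  }
  class(df) <- c("rearing_log", "data.frame")
  df
}

#' Validate rearing-log invariants
#'
#' Checks, per individual: stage entry dates are present only in an
#' uninterrupted prefix of the stage order and are nondecreasing; the death
#' stage equals the last stage with an entry date; sex is only assigned to
#' individuals that reached adulthood; fecundity fields appear only for
#' females and satisfy `eggs_hatched <= eggs_laid`.
#'
#' @param df rearing-log data frame (already type-coerced).
#' @return character vector of human-readable issues (empty when valid).
#' @export
validate_rearing_log <- function(df) {
  issues <- character()
  add <- function(...) issues[[length(issues) + 1L]] <<- paste0(...)
  if (anyDuplicated(df$individual_id)) {
    add("duplicated individual_id: ",
        paste(unique(df$individual_id[duplicated(df$individual_id)]), collapse = ", "))
  }
  stages <- stage_codes()
  for (r in seq_len(nrow(df))) {
    id <- df$individual_id[r]
    dates <- as.Date(unlist(df[r, stage_date_cols()]), origin = "1970-01-01")
    have <- !is.na(dates)
    if (!have[1]) {
      add(id, ": missing date_EG (the biofix)")
      next
    }
    if (any(have) && !all(have[seq_len(max(which(have)))])) {
      gap <- stages[!have & seq_along(have) < max(which(have))]
      add(id, ": stage(s) ", paste(gap, collapse = ", "),
          " lack entry dates although a later stage has one")
    }
    d <- dates[have]
    if (is.unsorted(d)) {
      add(id, ": stage entry dates are not nondecreasing")
    }
    last_stage <- stages[max(which(have))]
    if (!is.na(df$death_stage[r]) && df$death_stage[r] != last_stage) {
      add(id, ": death_stage (", df$death_stage[r],
          ") is not the last stage with an entry date (", last_stage, ")")
    }
    if (!is.na(df$death_date[r]) && df$death_date[r] < max(d)) {
      add(id, ": death_date precedes the last stage entry date")
    }
    sex <- df$sex[r]
    if (!is.na(sex) && !sex %in% c("male", "female", "undetermined")) {
      add(id, ": sex must be male, female or undetermined")
    }
    if (!is.na(sex) && sex %in% c("male", "female") && !have[length(have)]) {
      add(id, ": sex assigned although the adult stage was not reached")
    }
    if (!is.na(df$eggs_laid[r]) && (is.na(sex) || sex != "female")) {
      add(id, ": eggs_laid present for a non-female individual")
    }
    if (!is.na(df$eggs_laid[r]) && df$eggs_laid[r] < 0) {
      add(id, ": eggs_laid is negative")
    }
    if (!is.na(df$eggs_hatched[r])) {
      if (is.na(df$eggs_laid[r])) {
        add(id, ": eggs_hatched present without eggs_laid")
      } else if (df$eggs_hatched[r] > df$eggs_laid[r]) {
        add(id, ": eggs_hatched exceeds eggs_laid")
      }
    }
  }
  issues
}

#' Write a rearing log to CSV
#'
#' @param log `rearing_log` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rearing_log <- function(log, path) {
  out <- as.data.frame(log)
  for (col in c(stage_date_cols(), "death_date")) {
    out[[col]] <- format(out[[col]], "%Y-%m-%d")
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Convert an event-long log to the wide rearing-log layout
#'
#' Some laboratories record one row per event (`individual_id`, `event`,
#' `date`), where `event` is a stage code (entry into that stage) or
#' `"death"`. This reshapes such a log into the wide one-row-per-individual
#' layout; static fields (diet, generation, sex, fecundity) are supplied in a
#' companion data frame.
#'
#' @param events data frame with columns `individual_id`, `event`, `date`.
#' @param individuals data frame with columns `individual_id`, `diet`,
#'   `generation`, `sex`, `eggs_laid`, `eggs_hatched`.
#' @return validated `rearing_log` data frame.
#' @export
pivot_event_log <- function(events, individuals) {
  stopifnot(all(c("individual_id", "event", "date") %in% names(events)))
  events$date <- as.Date(events$date)
  ids <- individuals$individual_id
  wide <- individuals
  for (s in stage_codes()) {
    m <- events[events$event == s, ]
    wide[[paste0("date_", s)]] <- m$date[match(ids, m$individual_id)]
  }
  dth <- events[events$event == "death", ]
  wide$death_date <- dth$date[match(ids, dth$individual_id)]
  has_stage <- !is.na(as.matrix(wide[stage_date_cols()]))
  last <- apply(has_stage, 1, function(x) if (any(x)) max(which(x)) else NA_integer_)
  wide$death_stage <- ifelse(is.na(wide$death_date), NA_character_,
                             stage_codes()[last])
  as_rearing_log(wide)
}

#' Read a daily temperature series
#'
#' @param path CSV with columns `date` (ISO-8601), `tmin`, `tmax` in degrees
#'   Celsius. Dates must be strictly increasing with no gaps, and
#'   `tmin <= tmax` on every day.
#' @return a `temperature_series` data frame.
#' @export
read_temperature <- function(path) {
  if (!file.exists(path)) stop("temperature file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("date", "tmin", "tmax"), names(df))
  if (length(missing_cols)) {
    stop("temperature series is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(df$tmin) || !is.numeric(df$tmax)) {
    stop("non-numeric temperature values in ", path)
  }
  as_temperature_series(df)
}

#' Coerce and validate a daily temperature series
#'
#' @param df data frame with columns `date`, `tmin`, `tmax`.
#' @return validated `temperature_series` data frame.
#' @export
as_temperature_series <- function(df) {
  df <- df[c("date", "tmin", "tmax")]
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("unparseable date(s) in temperature series")
  if (anyNA(df$tmin) || anyNA(df$tmax)) stop("missing temperature value(s)")
  if (nrow(df) > 1) {
    step <- diff(as.integer(df$date))
    if (any(step <= 0)) stop("temperature dates are not strictly increasing")
    if (any(step > 1)) {
      first_gap <- which(step > 1)[1]
      stop("temperature series has a gap: missing ",
           format(df$date[first_gap] + 1, "%Y-%m-%d"))
    }
  }
  bad <- df$tmin > df$tmax
  if (any(bad)) {
    stop("tmin > tmax on ", format(df$date[which(bad)[1]], "%Y-%m-%d"))
  }
  class(df) <- c("temperature_series", "data.frame")
  df
}

#' Write a temperature series to CSV
#'
#' @param series `temperature_series` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_temperature <- function(series, path) {
  out <- as.data.frame(series)
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
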