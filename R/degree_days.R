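#' Degree-day accumulation parameters
#'
#' The developmental clock uses the simple-average degree-day method: each
#' day contributes `(tmax + tmin)/2 - tbase` heat units, clipped at zero so
#' that days below the developmental threshold contribute nothing rather
#' than subtracting accumulated heat. The base temperature defaults to the
#' 15 degC lower developmental threshold of *Zelus renardii*.
#'
#' @param tbase lower developmental threshold, degrees Celsius.
#' @param clip clip negative daily contributions to zero?
#' @return a `dd_params` list.
#' @export
dd_params <- function(tbase = 15, clip = TRUE) {
  stopifnot(is.finite(tbase), is.logical(clip), length(clip) == 1)
  structure(list(tbase = tbase, clip = clip), class = "dd_params")
}

#' Daily degree-day contribution
#'
#' @param tmax,tmin daily maximum and minimum temperature, degrees Celsius
#'   (vectorised; `tmin <= tmax` required).
#' @param params a [dd_params()] object.
#' @return degree-days (degC day) contributed by each day.
#' @export
daily_dd <- function(tmax, tmin, params = dd_params()) {
  if (any(tmin > tmax)) stop("tmin exceeds tmax")
  dd <- (tmax + tmin) / 2 - params$tbase
  if (params$clip) dd <- pmax(dd, 0)
  dd
}

# day index of a calendar date within a series (1-based), NA outside coverage
.day_index <- function(series, date) {
  i <- as.integer(as.Date(date) - series$date[1]) + 1L
  i[i < 1L | i > nrow(series)] <- NA_integer_
  i
}

# cumulative degree-days: cdd0[k+1] = heat of days 1..k, cdd0[1] = 0,
# so the half-open date-index interval [a, b) accumulates cdd0[b] - cdd0[a]
.cum_dd <- function(series, params) {
  c(0, cumsum(daily_dd(series$tmax, series$tmin, params)))
}

#' Accumulate degree-days over a date interval
#'
#' Sums daily contributions over the half-open interval `[start, end)`:
#' the day an event happens belongs to the period being entered, so
#' `accumulate_dd(s, d, d)` is zero and adjacent intervals add without
#' double counting.
#'
#' @param series a `temperature_series`.
#' @param start,end calendar dates, `start <= end`; `[start, end)` must lie
#'   within the series coverage.
#' @param params a [dd_params()] object.
#' @return accumulated degree-days (degC day).
#' @export
accumulate_dd <- function(series, start, end, params = dd_params()) {
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop("end date precedes start date")
  if (start == end) return(0)
  a <- .day_index(series, start)
  b <- .day_index(series, end - 1)
  if (is.na(a) || is.na(b)) {
    stop("temperature series does not cover ", format(start), " to ",
         format(end - 1), " (coverage ", format(series$date[1]), " to ",
         format(series$date[nrow(series)]), ")")
  }
  cdd0 <- .cum_dd(series, params)
  cdd0[b + 1] - cdd0[a]
}

#' Per-individual, per-stage degree-day ledger
#'
#' For every individual and every stage it entered, accumulates the
#' degree-days between entry into that stage and entry into the next stage
#' (or the death date for the last stage occupied). The egg entry date is
#' the biofix: all accumulation starts there.
#'
#' @param log a `rearing_log`.
#' @param series a `temperature_series` covering every individual's life.
#' @param params a [dd_params()] object.
#' @return a data frame with columns `individual_id`, `stage`, `n_days`,
#'   `add` (degree-days in the stage); one row per occupied stage, in stage
#'   order within individual.
#' @export
add_ledger <- function(log, series, params = dd_params()) {
  cdd0 <- .cum_dd(series, params)
  stages <- stage_codes()
  res <- vector("list", nrow(log))
  for (r in seq_len(nrow(log))) {
    dates <- as.Date(unlist(log[r, stage_date_cols()]), origin = "1970-01-01")
    have <- which(!is.na(dates))
    ends <- c(dates[have][-1], log$death_date[r])
    starts <- dates[have]
    if (anyNA(ends)) {  # alive at censoring: last stage has no exit
      keep <- !is.na(ends)
      starts <- starts[keep]; ends <- ends[keep]; have <- have[keep]
    }
    a <- .day_index(series, starts)
    b <- .day_index(series, ends - 1)
    b[ends == starts] <- a[ends == starts] - 1L  # empty interval
    if (anyNA(a) || anyNA(b)) {
      stop("temperature series does not cover individual ",
           log$individual_id[r])
    }
    res[[r]] <- data.frame(
      individual_id = log$individual_id[r],
      stage = stages[have],
      n_days = as.integer(ends - starts),
      add = cdd0[b + 1] - cdd0[a],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cumulative egg-to-adult degree-days per individual
#'
#' Sums the per-stage ledger entries from the biofix (or from first-instar
#' entry, for the reading that excludes the egg stage) up to adult entry,
#' for individuals that reached adulthood. Both readings are offered because
#' a cumulative stage total "up to the adult" can be counted with or without
#' the egg stage; the default includes it.
#'
#' @param ledger output of [add_ledger()].
#' @param log the `rearing_log` the ledger was built from.
#' @param from `"EG"` (biofix, default) or `"N1"`.
#' @return data frame `individual_id`, `cumulative_add` (adults only).
#' @export
cumulative_add <- function(ledger, log, from = c("EG", "N1")) {
  from <- match.arg(from)
  adults <- log$individual_id[!is.na(log$date_AD)]
  pre_adult <- setdiff(stage_codes(), "AD")
  if (from == "N1") pre_adult <- setdiff(pre_adult, "EG")
  keep <- ledger$individual_id %in% adults & ledger$stage %in% pre_adult
  sums <- tapply(ledger$add[keep], ledger$individual_id[keep], sum)
  data.frame(individual_id = names(sums),
             cumulative_add = as.numeric(sums),
             stringsAsFactors = FALSE)
}

#' Degree-days remaining from each stage entry to death
#'
#' Used for the life-table expectation-of-life column: for each individual
#' and each stage it entered, the degree-days accumulated between that entry
#' and death (the tail sum of the per-stage ledger).
#'
#' @inheritParams cumulative_add
#' @return data frame `individual_id`, `stage`, `add_to_death`.
#' @export
add_to_death <- function(ledger) {
  parts <- split(ledger, ledger$individual_id)
  out <- lapply(parts, function(d) {
    d <- d[order(stage_index(d$stage)), ]
    data.frame(individual_id = d$individual_id,
               stage = d$stage,
               add_to_death = rev(cumsum(rev(d$add))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Potential generations per year at a constant temperature
#'
#' At a constant mean daily temperature the annual heat budget above the
#' developmental threshold is `365 * (mean_daily_t - tbase)` degree-days;
#' dividing by the egg-to-adult requirement gives the number of generations
#' the budget can sustain. The ceiling is the companion integer upper bound.
#'
#' @param mean_daily_t mean daily temperature, degrees Celsius.
#' @param egg_to_adult_add egg-to-adult degree-day requirement (> 0).
#' @param params a [dd_params()] object.
#' @return list with `rate` (real generations/year; 0 at or below the
#'   threshold) and `ceiling`.
#' @export
generations_per_year <- function(mean_daily_t, egg_to_adult_add,
                                 params = dd_params()) {
  stopifnot(egg_to_adult_add > 0)
  if (mean_daily_t <= params$tbase) {
    return(list(rate = 0, ceiling = 0L))
  }
  rate <- 365 * (mean_daily_t - params$tbase) / egg_to_adult_add
  list(rate = rate, ceiling = as.integer(ceiling(rate)))
}
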