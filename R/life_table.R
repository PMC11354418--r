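#' Stage-entry counts of a cohort
#'
#' The "number living" column of a cohort life table: for each stage, the
#' number of individuals whose record carries an entry date for that stage.
#' Counts are necessarily nonincreasing along the stage order.
#'
#' @param log a `rearing_log` whose rows all share one diet and generation.
#' @return named integer vector over the seven stages.
#' @export
stage_counts <- function(log) {
  if (length(unique(log$diet)) > 1 || length(unique(log$generation)) > 1) {
    stop("stage_counts expects a single diet x generation cohort")
  }
  n <- vapply(stage_date_cols(), function(col) sum(!is.na(log[[col]])), 0L)
  names(n) <- stage_codes()
  n
}

#' Build a cohort life table from stage counts
#'
#' All ratios are computed from the raw integer counts; rounding happens
#' only at render time. For stage `x` with `N` individuals entering:
#' `lx = N(x)/N(EG)` (fraction surviving from cohort start),
#' `px = N(next)/N(x)` (period survival; 0 for the terminal adult stage),
#' `qx = 1 - px`, and `dx = lx(x) - lx(next)` (`dx(AD) = lx(AD)`), so that
#' `dx` sums to one over the table.
#'
#' @param counts named integer vector over the seven stages (nonincreasing).
#' @param eggs_next total eggs of the subsequent brood laid by the cohort's
#'   females; the population trend is `eggs_next / N(EG)`.
#' @param diet,generation cohort labels carried on the table.
#' @return a `life_table` data frame (columns `stage`, `n`, `lx`, `px`,
#'   `qx`, `dx`, `ex`) with attributes `diet`, `generation`, `eggs_next`,
#'   `trend`.
#' @export
life_table_from_counts <- function(counts, eggs_next,
                                   diet = NA_character_,
                                   generation = NA_integer_) {
  stopifnot(length(counts) == 7, eggs_next >= 0)
  counts <- as.integer(counts)
  if (counts[1] == 0) stop("empty cohort: no individuals entered the egg stage")
  if (any(diff(counts) > 0)) stop("stage counts must be nonincreasing")
  lx <- counts / counts[1]
  px <- c(ifelse(counts[-7] > 0, counts[-1] / counts[-7], NA_real_), 0)
  qx <- 1 - px
  dx <- c(lx[-7] - lx[-1], lx[7])
  tab <- data.frame(stage = stage_codes(), n = counts,
                    lx = lx, px = px, qx = qx, dx = dx, ex = NA_real_,
                    stringsAsFactors = FALSE)
  structure(tab,
            diet = diet, generation = generation,
            eggs_next = as.integer(eggs_next),
            trend = eggs_next / counts[1],
            class = c("life_table", "data.frame"))
}

#' Build a cohort life table from records and degree-day ledgers
#'
#' In addition to the count-based columns of [life_table_from_counts()],
#' fills the expectation-of-life column `ex`: for each stage, the mean
#' degree-days accumulated between entry into that stage and death, over
#' the individuals that entered it. `ex` is therefore denominated in
#' degree-days, not calendar days, and shrinks stage by stage as the
#' remaining heat budget is spent. Stages nobody entered have `ex = NA`.
#'
#' @param log a single-cohort `rearing_log`.
#' @param series a `temperature_series` covering the cohort.
#' @param eggs_next total eggs of the subsequent brood (default: the sum of
#'   `eggs_laid` over the cohort's females, i.e. the brood they produced).
#' @param params a [dd_params()] object.
#' @return a `life_table` data frame.
#' @export
build_life_table <- function(log, series,
                             eggs_next = sum(log$eggs_laid, na.rm = TRUE),
                             params = dd_params()) {
  counts <- stage_counts(log)
  tab <- life_table_from_counts(counts, eggs_next,
                                diet = unique(log$diet),
                                generation = unique(log$generation))
  ledger <- add_ledger(log, series, params)
  tail_sums <- add_to_death(ledger)
  ex <- tapply(tail_sums$add_to_death, tail_sums$stage, mean)
  tab$ex <- as.numeric(ex[tab$stage])
  tab
}

#' Population trend between successive broods
#'
#' The ratio of the number of eggs in the subsequent brood to the number in
#' the previous one. The population grows when the trend exceeds one,
#' declines below one, and is at equilibrium at exactly one.
#'
#' @param eggs_prev egg count of the previous brood (> 0).
#' @param eggs_next egg count of the subsequent brood.
#' @return the trend, with attribute `status` in
#'   `"growing"/"declining"/"equilibrium"`.
#' @export
population_trend <- function(eggs_prev, eggs_next) {
  if (eggs_prev <= 0) stop("population trend undefined: previous brood empty")
  t <- eggs_next / eggs_prev
  structure(t, status = if (t > 1) "growing" else if (t < 1) "declining"
                        else "equilibrium")
}

#' Mean population trend over generations
#'
#' Averages per-generation trends into a per-treatment trend. Published
#' rearing tables round each generation's trend to two decimals before
#' averaging; `rounded = TRUE` reproduces that convention, while
#' `rounded = FALSE` averages the raw ratios.
#'
#' @param trends numeric vector of per-generation trends (nonempty).
#' @param rounded average the half-up 2-decimal roundings of the trends?
#' @param digits rounding digits used when `rounded = TRUE`.
#' @return the mean trend.
#' @export
mean_trend <- function(trends, rounded = FALSE, digits = 2) {
  trends <- as.numeric(trends)
  if (!length(trends)) stop("no trends supplied")
  if (rounded) trends <- round_half_up(trends, digits)
  mean(trends)
}
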