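#' Published stage counts of the rearing trial
#'
#' The "number living" columns of the published two-generation *Zelus
#' renardii* rearing trial: cohorts of 33 on live prey (`Dm`) and five
#' artificial diets. `D2` collapsed in the first generation (no adults) and
#' was not reared again; its per-stage death allocation was not published,
#' so the counts carried here for `D2` are a synthetic allocation of its 33
#' deaths across the nymphal instars (flagged by the `synthetic` column) —
#' only its start count and zero adult survivors are reported values.
#'
#' @return data frame `diet`, `generation`, `stage`, `n`, `synthetic`.
#' @export
zelus_counts <- function() {
  counts <- list(
    Dm = list(`1` = c(33, 33, 33, 33, 32, 31, 29),
              `2` = c(33, 33, 32, 31, 30, 30, 30)),
    D0 = list(`1` = c(33, 33, 32, 32, 31, 29, 27),
              `2` = c(33, 32, 32, 31, 29, 27, 27)),
    D1 = list(`1` = c(33, 33, 31, 31, 29, 28, 28),
              `2` = c(33, 33, 32, 31, 30, 29, 28)),
    D2 = list(`1` = c(33, 33, 25, 17, 10, 4, 0)),
    D3 = list(`1` = c(33, 33, 32, 31, 29, 27, 27),
              `2` = c(33, 33, 29, 27, 27, 27, 26)),
    D4 = list(`1` = c(33, 33, 31, 29, 28, 27, 27),
              `2` = c(33, 33, 32, 30, 29, 29, 28))
  )
  out <- do.call(rbind, lapply(names(counts), function(d) {
    do.call(rbind, lapply(names(counts[[d]]), function(g) {
      data.frame(diet = d, generation = as.integer(g),
                 stage = stage_codes(), n = as.integer(counts[[d]][[g]]),
                 synthetic = d == "D2" & stage_codes() != "EG" &
                   stage_codes() != "AD",
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Published next-brood egg totals
#'
#' The egg counts of the subsequent brood reported under each cohort table,
#' the numerators of the published population trends. `D2` produced no
#' adults and hence no brood.
#'
#' @return data frame `diet`, `generation`, `eggs_next`.
#' @export
zelus_egg_totals <- function() {
  data.frame(
    diet = rep(c("Dm", "D0", "D1", "D2", "D3", "D4"), each = 2)[-8],
    generation = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 1L, 2L, 1L, 2L),
    eggs_next = c(338L, 416L, 624L, 378L, 364L, 432L, 0L,
                  468L, 324L, 338L, 390L),
    stringsAsFactors = FALSE
  )
}

#' Published life-table survival cells
#'
#' The printed `lx`, `px`, `qx`, `dx` cells of the five published cohort
#' tables (two generations each), kept as the reference surface the
#' count-based reconstruction is compared against. Five printed cells are
#' internally inconsistent with the same table's own counts column and are
#' flagged as errata: the generation-2 `Dm` N1 row prints `dx = 0` though
#' `lx` drops by 0.03; the generation-2 `D0` egg row prints
#' `px/qx/dx = 1/0/0` though only 32 of 33 eggs hatched; and the
#' generation-2 `D4` egg row prints `px = 0` though all 33 survive.
#'
#' @return data frame `diet`, `generation`, `stage`, `lx`, `px`, `qx`,
#'   `dx`, `erratum` (character vector of column names whose printed value
#'   contradicts the table's counts, comma-separated, `""` if none).
#' @export
zelus_reference_cells <- function() {
  rows <- function(diet, gen, m, errata = rep("", 7)) {
    data.frame(diet = diet, generation = gen, stage = stage_codes(),
               lx = m[, 1], px = m[, 2], qx = m[, 3], dx = m[, 4],
               erratum = errata, stringsAsFactors = FALSE)
  }
  out <- rbind(
    rows("Dm", 1L, matrix(c(
      1, 1, 0, 0,   1, 1, 0, 0,   1, 1, 0, 0,   1, .97, .03, .03,
      .97, .97, .03, .03,   .94, .94, .06, .06,   .88, 0, 1, .88),
      ncol = 4, byrow = TRUE)),
    rows("Dm", 2L, matrix(c(
      1, 1, 0, 0,   1, .97, .03, 0,   .97, .97, .03, .03,
      .94, .97, .03, .03,   .91, 1, 0, 0,   .91, 1, 0, 0,   .91, 0, 1, .91),
      ncol = 4, byrow = TRUE),
      errata = c("", "dx", "", "", "", "", "")),
    rows("D0", 1L, matrix(c(
      1, 1, 0, 0,   1, .97, .03, .03,   .97, 1, 0, 0,   .97, .97, .03, .03,
      .94, .94, .06, .06,   .88, .93, .07, .06,   .82, 0, 1, .82),
      ncol = 4, byrow = TRUE)),
    rows("D0", 2L, matrix(c(
      1, 1, 0, 0,   .97, 1, 0, 0,   .97, .97, .03, .03,
      .94, .94, .06, .06,   .88, .93, .07, .06,   .82, 1, 0, 0,
      .82, 0, 1, .82),
      ncol = 4, byrow = TRUE),
      errata = c("px,qx,dx", "", "", "", "", "", "")),
    rows("D1", 1L, matrix(c(
      1, 1, 0, 0,   1, .94, .06, .06,   .94, 1, 0, 0,   .94, .94, .06, .06,
      .88, .97, .03, .03,   .85, 1, 0, 0,   .85, 0, 1, .85),
      ncol = 4, byrow = TRUE)),
    rows("D1", 2L, matrix(c(
      1, 1, 0, 0,   1, .97, .03, .03,   .97, .97, .03, .03,
      .94, .97, .03, .03,   .91, .97, .03, .03,   .88, .97, .03, .03,
      .85, 0, 1, .85),
      ncol = 4, byrow = TRUE)),
    rows("D3", 1L, matrix(c(
      1, 1, 0, 0,   1, .97, .03, .03,   .97, .97, .03, .03,
      .94, .94, .06, .06,   .88, .93, .07, .06,   .82, 1, 0, 0,
      .82, 0, 1, .82),
      ncol = 4, byrow = TRUE)),
    rows("D3", 2L, matrix(c(
      1, 1, 0, 0,   1, .88, .12, .12,   .88, .93, .07, .06,
      .82, 1, 0, 0,   .82, 1, 0, 0,   .82, .96, .04, .03,   .79, 0, 1, .79),
      ncol = 4, byrow = TRUE)),
    rows("D4", 1L, matrix(c(
      1, 1, 0, 0,   1, .94, .06, .06,   .94, .94, .06, .06,
      .88, .97, .03, .03,   .85, .96, .04, .03,   .82, 1, 0, 0,
      .82, 0, 1, .82),
      ncol = 4, byrow = TRUE)),
    rows("D4", 2L, matrix(c(
      1, 0, 0, 0,   1, .97, .03, .03,   .97, .94, .06, .06,
      .91, .97, .03, .03,   .88, 1, 0, 0,   .88, .97, .03, .03,
      .85, 0, 1, .85),
      ncol = 4, byrow = TRUE),
      errata = c("px", "", "", "", "", "", ""))
  )
  rownames(out) <- NULL
  out
}

#' Published per-diet cumulative degree-day summaries
#'
#' Mean and standard deviation of cumulative egg-to-adult degree-days per
#' diet as reported for each generation (not every diet x generation mean
#' was printed; missing ones are `NA`). These are calibration anchors for
#' the generator and sanity envelopes for simulations — the raw individual
#' values behind them were not published.
#'
#' @return data frame `diet`, `generation`, `mean_add`, `sd_add`.
#' @export
zelus_cumulative_add_summaries <- function() {
  data.frame(
    diet = rep(c("Dm", "D0", "D1", "D3", "D4"), times = 2),
    generation = rep(1:2, each = 5),
    mean_add = c(1923.96, NA, 1931.89, 2131.81, 2191.98,
                 1513, 2332, 1810, 2203, NA),
    sd_add = c(466.98, NA, 255.40, 321.27, 448.72,
               175.99, 361.10, 243.49, 419.54, NA),
    stringsAsFactors = FALSE
  )
}

# stage durations (days) used to lay out the deterministic fixture calendar
.fixture_durations <- c(EG = 13, N1 = 12, N2 = 14, N3 = 15, N4 = 17, N5 = 20)

#' Deterministic reference rearing log
#'
#' A non-random rearing log whose stage-entry counts, next-brood egg totals
#' and D2 collapse exactly match the published trial, built by assigning
#' each cohort's deaths to stages according to the published counts.
#' Calendar dates follow a fixed per-stage schedule under a constant
#' laboratory temperature series (18-25 degC); they make the log a valid,
#' fully analyzable dataset but are synthetic — the trial's raw dates and
#' temperatures were not published, so degree-day columns derived from this
#' fixture (e.g. `ex`) are not reference values.
#'
#' Sexes are assigned to adults to echo the reported first-generation sex
#' compositions (notably the female-skewed `D0`), and each cohort's total
#' eggs laid equals the published next-brood egg count, spread as evenly as
#' possible over its females.
#'
#' @return list with `log` (a `rearing_log`) and `temps` (a constant
#'   `temperature_series` covering it).
#' @export
zelus_fixture <- function() {
  counts <- zelus_counts()
  eggs <- zelus_egg_totals()
  female_frac <- list(
    Dm = c(0.38, 0.5), D0 = c(0.83, 0.5), D1 = c(0.5, 0.5),
    D2 = c(0.5), D3 = c(0.59, 0.5), D4 = c(0.37, 0.5)
  )
  start0 <- as.Date("2021-05-01")
  dur <- .fixture_durations
  adult_days <- 60L
  rows <- list(); k <- 0L
  for (key in unique(paste(counts$diet, counts$generation))) {
    parts <- strsplit(key, " ")[[1]]
    d <- parts[1]; g <- as.integer(parts[2])
    n <- counts$n[counts$diet == d & counts$generation == g]
    egg_total <- eggs$eggs_next[eggs$diet == d & eggs$generation == g]
    start <- start0 + (g - 1L) * 180L
    entries <- start + cumsum(c(0, unname(dur)))  # entry date per stage
    deaths_per_stage <- c(-diff(n), 0)            # deaths during stage s
    n_adults <- n[7]
    nf <- if (n_adults > 0) {
      max(1L, as.integer(round(n_adults * female_frac[[d]][g])))
    } else 0L
    egg_share <- if (nf > 0) {
      base <- egg_total %/% nf
      share <- rep(base, nf)
      extra <- egg_total - base * nf
      if (extra > 0) share[seq_len(extra)] <- share[seq_len(extra)] + 1L
      share
    } else integer()
    # individuals 1..n_adults survive; the rest die, grouped by stage
    death_stage_of <- rep(NA_character_, n[1])
    idx <- n_adults
    for (s in seq_len(6)) {
      if (deaths_per_stage[s] > 0) {
        death_stage_of[idx + seq_len(deaths_per_stage[s])] <- stage_codes()[s]
        idx <- idx + deaths_per_stage[s]
      }
    }
    for (i in seq_len(n[1])) {
      k <- k + 1L
      ds <- death_stage_of[i]
      if (is.na(ds)) {  # adult
        ent <- entries
        death <- entries[7] + adult_days
        ds_out <- "AD"
        sex <- if (i <= nf) "female" else "male"
        laid <- if (i <= nf) egg_share[i] else NA_integer_
        hatched <- if (i <= nf) as.integer(floor(0.97 * laid)) else NA_integer_
      } else {
        si <- stage_index(ds)
        ent <- c(entries[seq_len(si)], rep(as.Date(NA), 7 - si))
        death <- entries[si] + floor(dur[si] / 2)
        ds_out <- ds
        sex <- NA_character_
        laid <- NA_integer_; hatched <- NA_integer_
      }
      rows[[k]] <- data.frame(
        individual_id = sprintf("%s-G%d-%03d", d, g, i),
        diet = d, generation = g,
        date_EG = ent[1], date_N1 = ent[2], date_N2 = ent[3],
        date_N3 = ent[4], date_N4 = ent[5], date_N5 = ent[6],
        date_AD = ent[7],
        death_date = death, death_stage = ds_out,
        sex = sex, eggs_laid = laid, eggs_hatched = hatched,
        stringsAsFactors = FALSE
      )
    }
  }
  log <- as_rearing_log(do.call(rbind, rows))
  span <- as.integer(max(log$death_date) - start0) + 10L
  temps <- as_temperature_series(data.frame(
    date = start0 + seq_len(span) - 1, tmin = 18, tmax = 25))
  list(log = log, temps = temps)
}
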