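#' Split a multi-cohort rearing log
#'
#' @param log a `rearing_log` spanning several diets and generations.
#' @return named list of single-cohort logs, names `"<diet>.<generation>"`.
#' @export
split_cohorts <- function(log) {
  parts <- split(as.data.frame(log),
                 list(log$diet, log$generation), drop = TRUE)
  lapply(parts, function(d) {
    class(d) <- c("rearing_log", "data.frame")
    d
  })
}

#' Build all cohort life tables of an experiment
#'
#' One life table per diet x generation, with the next-brood egg count
#' taken as the total eggs laid by the cohort's females (that total is the
#' subsequent brood).
#'
#' @param log a multi-cohort `rearing_log`.
#' @param series a `temperature_series` covering it.
#' @param params a [dd_params()] object.
#' @return named list of `life_table` objects.
#' @export
demography_tables <- function(log, series, params = dd_params()) {
  lapply(split_cohorts(log), build_life_table, series = series,
         params = params)
}

#' Per-diet population-trend summary
#'
#' Per-generation trends (subsequent brood eggs over the cohort's initial
#' egg number) and their per-diet mean. The per-diet mean follows the
#' published-table convention of averaging the 2-decimal rounded
#' per-generation trends (see [mean_trend()]).
#'
#' @param tables output of [demography_tables()].
#' @return data frame `diet`, `t1`, `t2`, `t_mean`.
#' @export
trend_summary <- function(tables) {
  diets <- unique(vapply(tables, attr, "", "diet"))
  out <- lapply(diets, function(d) {
    gens <- sort(vapply(Filter(function(t) attr(t, "diet") == d, tables),
                        attr, 0L, "generation"))
    tr <- vapply(gens, function(g) {
      tab <- tables[[paste(d, g, sep = ".")]]
      as.numeric(attr(tab, "trend"))
    }, 0)
    data.frame(diet = d,
               t1 = if (1 %in% gens) tr[match(1, gens)] else NA_real_,
               t2 = if (2 %in% gens) tr[match(2, gens)] else NA_real_,
               t_mean = mean_trend(tr, rounded = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Run the full demographic analysis of a rearing experiment
#'
#' The whole pipeline over a rearing log and temperature series: per-cohort
#' life tables, per-diet population trends, and the per-generation
#' comparison battery (sex-ratio chi-square with residual post hoc, exact
#' mortality tests, Welch ANOVA and Games-Howell on cumulative
#' degree-days, per-instar Kruskal-Wallis) plus the two-way fecundity and
#' hatch ANOVA across generations.
#'
#' @param log a multi-cohort `rearing_log`.
#' @param series a `temperature_series` covering it.
#' @param params a [dd_params()] object.
#' @return a `demography_report` list: `tables`, `trends`, `stats` (one
#'   element per generation), `fecundity`.
#' @export
demography_report <- function(log, series, params = dd_params()) {
  tables <- demography_tables(log, series, params)
  ledger <- add_ledger(log, series, params)
  diet_of <- log$diet[match(ledger$individual_id, log$individual_id)]
  gen_of <- log$generation[match(ledger$individual_id, log$individual_id)]
  stats_by_gen <- list()
  for (g in sort(unique(log$generation))) {
    sub <- log[log$generation == g, ]
    class(sub) <- c("rearing_log", "data.frame")
    cum <- cumulative_add(ledger[gen_of == g, ], sub)
    cum$diet <- sub$diet[match(cum$individual_id, sub$individual_id)]
    groups <- split(cum$cumulative_add, cum$diet)
    groups <- groups[vapply(groups, length, 0L) >= 2]
    per_instar <- data.frame(stage = ledger$stage[gen_of == g],
                             diet = diet_of[gen_of == g],
                             add = ledger$add[gen_of == g],
                             stringsAsFactors = FALSE)
    stats_by_gen[[as.character(g)]] <- list(
      sex_ratio = tryCatch(sex_ratio_test(sex_table(sub)),
                           error = function(e) NULL),
      mortality = mortality_test(mortality_table(sub)),
      welch = if (length(groups) >= 2) {
        tryCatch(welch_anova(groups), error = function(e) NULL)
      },
      games_howell = if (length(groups) >= 2) {
        tryCatch(games_howell(groups), error = function(e) NULL)
      },
      kruskal = kruskal_wallis_per_instar(per_instar)
    )
  }
  females <- as.data.frame(log[!is.na(log$eggs_laid), ])
  fec <- if (length(unique(females$diet)) >= 2 &&
             length(unique(females$generation)) >= 2) {
    tryCatch(fecundity_anova(females), error = function(e) NULL)
  }
  structure(list(tables = tables, trends = trend_summary(tables),
                 stats = stats_by_gen, fecundity = fec),
            class = "demography_report")
}

.jsonable_test <- function(t) {
  if (is.null(t)) return(NULL)
  list(statistic_name = t$statistic_name, statistic = t$statistic,
       df = unname(unlist(t$df)), p_value = t$p_value,
       posthoc = t$posthoc)
}

#' Write a demography report as JSON
#'
#' @param report a [demography_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_demography_json <- function(report, path) {
  out <- list(
    trends = report$trends,
    life_tables = lapply(report$tables, tidy_life_table),
    stats = lapply(report$stats, function(gs) {
      list(sex_ratio = .jsonable_test(gs$sex_ratio),
           mortality = .jsonable_test(gs$mortality),
           welch = .jsonable_test(gs$welch),
           games_howell = gs$games_howell,
           kruskal = lapply(gs$kruskal, .jsonable_test))
    }),
    fecundity = if (!is.null(report$fecundity)) list(
      eggs = lapply(report$fecundity$eggs, .jsonable_test),
      hatch = lapply(report$fecundity$hatch, .jsonable_test),
      normality = .jsonable_test(report$fecundity$normality),
      levene = .jsonable_test(report$fecundity$levene)
    )
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
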