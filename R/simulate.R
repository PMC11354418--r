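#' Evaluate an expression under a local random seed
#'
#' Seeds are explicit everywhere in the generator: this helper sets the
#' given seed (Mersenne-Twister, the fixed generator the package is
#' versioned against), runs the expression, and restores the caller's
#' random state, so simulations are bit-reproducible and never leak hidden
#' global state.
#'
#' @param seed integer seed, or NULL to use the current state.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Diet profile for the cohort generator
#'
#' All generative parameters of one diet treatment. The egg-to-adult
#' degree-day requirement is split into a fixed egg share (128 degree-days,
#' the constant gap between the egg and first-instar expectation-of-life
#' columns across all published cohort tables) and nymphal shares that rise
#' toward the late instars, where observed heat requirements and their
#' dispersion are largest. Per-stage requirements are drawn lognormal
#' (positive, right-skewed) around these means.
#'
#' @param label diet label (e.g. "Dm", "D0").
#' @param total_add mean egg-to-adult degree-day requirement.
#' @param adult_add_mean mean adult degree-day budget after the final molt
#'   (sets the adult expectation of life).
#' @param stage_mortality named probability vector over EG..N5: probability
#'   of dying during each pre-adult stage.
#' @param male_prob probability a surviving adult is male.
#' @param fecundity_mean,fecundity_sd eggs per female (normal, truncated at
#'   zero, rounded).
#' @param hatch_prob per-egg hatch probability.
#' @param stage_add_cv coefficient of variation of each stage's requirement.
#' @param egg_add egg-stage degree-day requirement.
#' @param nymph_weights shares of `total_add - egg_add` across N1..N5.
#' @return a `diet_profile` list with the derived `stage_add_mean` vector.
#' @export
diet_profile <- function(label, total_add, adult_add_mean,
                         stage_mortality, male_prob,
                         fecundity_mean, fecundity_sd = 4.83,
                         hatch_prob = 0.969,
                         stage_add_cv = 0.30, egg_add = 128,
                         nymph_weights = c(N1 = 0.10, N2 = 0.13, N3 = 0.17,
                                           N4 = 0.25, N5 = 0.35)) {
  stopifnot(total_add > egg_add, adult_add_mean > 0,
            abs(sum(nymph_weights) - 1) < 1e-8,
            all(stage_mortality >= 0 & stage_mortality <= 1),
            male_prob >= 0, male_prob <= 1,
            hatch_prob >= 0, hatch_prob <= 1)
  pre <- setdiff(stage_codes(), "AD")
  if (is.null(names(stage_mortality))) names(stage_mortality) <- pre
  stopifnot(setequal(names(stage_mortality), pre))
  stage_add_mean <- c(EG = egg_add, nymph_weights * (total_add - egg_add))
  names(stage_add_mean) <- pre
  structure(list(label = label, total_add = total_add,
                 stage_add_mean = stage_add_mean,
                 adult_add_mean = adult_add_mean,
                 stage_add_cv = stage_add_cv,
                 stage_mortality = stage_mortality[pre],
                 male_prob = male_prob,
                 fecundity_mean = fecundity_mean,
                 fecundity_sd = fecundity_sd,
                 hatch_prob = hatch_prob),
            class = "diet_profile")
}

#' Default diet profiles of the rearing trial
#'
#' One profile per diet that completed two generations (live prey `Dm` and
#' the artificial formulations `D0`, `D1`, `D3`, `D4`), calibrated to the
#' published trial: egg-to-adult requirements to the per-diet cumulative
#' degree-day means, adult budgets to the adult expectation-of-life column,
#' per-stage mortalities to the first-generation life-table mortalities,
#' sex ratios to the first-generation sex compositions (strongly
#' female-skewed `D0`), and fecundity/hatch to the reported per-diet means.
#'
#' @return named list of [diet_profile()] objects.
#' @export
default_diet_profiles <- function() {
  list(
    Dm = diet_profile("Dm", total_add = 1923.96, adult_add_mean = 489,
                      stage_mortality = c(EG = 0, N1 = 0, N2 = 0,
                                          N3 = 1 / 33, N4 = 1 / 32, N5 = 2 / 31),
                      male_prob = 0.62, fecundity_mean = 26.92,
                      fecundity_sd = 6.52, hatch_prob = 0.969),
    D0 = diet_profile("D0", total_add = 2332, adult_add_mean = 1266,
                      stage_mortality = c(EG = 0, N1 = 1 / 33, N2 = 0,
                                          N3 = 1 / 32, N4 = 2 / 31, N5 = 2 / 29),
                      male_prob = 0.17, fecundity_mean = 25.45,
                      fecundity_sd = 5.05, hatch_prob = 0.9752),
    D1 = diet_profile("D1", total_add = 1931.89, adult_add_mean = 594,
                      stage_mortality = c(EG = 0, N1 = 2 / 33, N2 = 0,
                                          N3 = 2 / 31, N4 = 1 / 29, N5 = 0),
                      male_prob = 0.50, fecundity_mean = 26.04,
                      hatch_prob = 0.969),
    D3 = diet_profile("D3", total_add = 2131.81, adult_add_mean = 843,
                      stage_mortality = c(EG = 0, N1 = 1 / 33, N2 = 1 / 32,
                                          N3 = 2 / 31, N4 = 2 / 29, N5 = 0),
                      male_prob = 0.41, fecundity_mean = 26.5,
                      hatch_prob = 0.969),
    D4 = diet_profile("D4", total_add = 2191.98, adult_add_mean = 492,
                      stage_mortality = c(EG = 0, N1 = 2 / 33, N2 = 2 / 31,
                                          N3 = 1 / 29, N4 = 1 / 28, N5 = 0),
                      male_prob = 0.62, fecundity_mean = 26.04,
                      fecundity_sd = 3.59, hatch_prob = 0.9615)
  )
}

#' Profile of the failed oligidic diet
#'
#' The trial's `D2` formulation did not sustain development: the whole
#' first-generation cohort died before adulthood, and the diet was dropped.
#' This profile emulates that collapse with severe per-stage mortality; it
#' is not part of [default_diet_profiles()] because no adult-stage
#' calibration data exist for it.
#'
#' @return a [diet_profile()].
#' @export
d2_profile <- function() {
  diet_profile("D2", total_add = 2100, adult_add_mean = 500,
               stage_mortality = c(EG = 0, N1 = 0.55, N2 = 0.55,
                                   N3 = 0.55, N4 = 0.55, N5 = 0.55),
               male_prob = 0.5, fecundity_mean = 26.04, hatch_prob = 0.969)
}

#' Simulation configuration
#'
#' All generative parameters of the synthetic rearing experiment: cohort
#' design (33 individuals per diet per generation, two generations), diet
#' profiles, the seasonal laboratory temperature model (air-conditioned
#' between 18 and 25 degrees Celsius), and reproductive shifts.
#'
#' @param cohort_size individuals per diet per generation.
#' @param diets named list of [diet_profile()] objects.
#' @param generations number of successive generations.
#' @param start_date oviposition date of the first generation's eggs.
#' @param gen_lag_days calendar lag between successive generations' broods.
#' @param oviposition_spread eggs of a cohort are laid over this many days.
#' @param tmin_winter,tmax_summer seasonal extremes of the laboratory
#'   regime, degrees Celsius.
#' @param seasonal_amplitude seasonal excursion (degC) applied to both
#'   daily bounds.
#' @param jitter_sd standard deviation of the day-to-day jitter, degC.
#' @param peak_doy day of year at which the laboratory is warmest.
#' @param fecundity_gen2_shift additive shift of mean eggs/female in the
#'   second generation (the trial's second brood laid slightly more).
#' @param dd a [dd_params()] object.
#' @return a `sim_config` list.
#' @export
sim_config <- function(cohort_size = 33, diets = default_diet_profiles(),
                       generations = 2,
                       start_date = as.Date("2021-05-01"),
                       gen_lag_days = 180, oviposition_spread = 7,
                       tmin_winter = 18, tmax_summer = 25,
                       seasonal_amplitude = 2, jitter_sd = 0.5,
                       peak_doy = 196, fecundity_gen2_shift = 1.67,
                       dd = dd_params()) {
  stopifnot(cohort_size >= 1, generations >= 1, tmin_winter <= tmax_summer,
            seasonal_amplitude >= 0, jitter_sd >= 0)
  structure(list(cohort_size = cohort_size, diets = diets,
                 generations = generations, start_date = as.Date(start_date),
                 gen_lag_days = gen_lag_days,
                 oviposition_spread = oviposition_spread,
                 tmin_winter = tmin_winter, tmax_summer = tmax_summer,
                 seasonal_amplitude = seasonal_amplitude,
                 jitter_sd = jitter_sd, peak_doy = peak_doy,
                 fecundity_gen2_shift = fecundity_gen2_shift,
                 dd = dd),
            class = "sim_config")
}

#' Configured annual mean temperature of the laboratory model
#'
#' The seasonal component is symmetric, so the long-run mean of the daily
#' midpoint is the midpoint of the configured seasonal extremes.
#'
#' @param config a [sim_config()].
#' @return degrees Celsius.
#' @export
annual_mean_temperature <- function(config) {
  (config$tmin_winter + config$tmax_summer) / 2
}

#' Simulate the seasonal laboratory temperature regime
#'
#' Daily minimum and maximum temperatures follow a sinusoidal annual cycle
#' between the configured winter minimum and summer maximum, with Gaussian
#' day-to-day jitter, truncated so the minimum stays above the
#' developmental threshold and never exceeds the maximum.
#'
#' @param config a [sim_config()].
#' @param start_date first day of the series.
#' @param n_days series length.
#' @param seed integer seed (NULL to use the current random state).
#' @return a `temperature_series`.
#' @export
simulate_temperatures <- function(config, start_date = config$start_date,
                                  n_days, seed = NULL) {
  stopifnot(n_days >= 1)
  with_seed(seed, {
    dates <- as.Date(start_date) + seq_len(n_days) - 1
    doy <- as.integer(format(dates, "%j"))
    s <- (1 + cos(2 * pi * (doy - config$peak_doy) / 365.25)) / 2
    tmin <- config$tmin_winter + config$seasonal_amplitude * s +
      stats::rnorm(n_days, 0, config$jitter_sd)
    tmax <- config$tmax_summer - config$seasonal_amplitude * (1 - s) +
      stats::rnorm(n_days, 0, config$jitter_sd)
    tmin <- pmax(tmin, config$dd$tbase + 0.5)
    tmax <- pmax(tmax, tmin)
    as_temperature_series(data.frame(date = dates, tmin = tmin, tmax = tmax))
  })
}

# day index b > a at which a degree-day requirement is recorded as met:
# the threshold is continuous but events are logged daily, so the event is
# placed on whichever adjacent day's accumulated heat is nearest the
# requirement (unbiased day-quantization). NA if the series is exhausted.
.advance <- function(cdd0, a, req) {
  b <- findInterval(cdd0[a] + req - 1e-9, cdd0) + 1L
  if (b > length(cdd0)) return(NA_integer_)
  if (b - 1L > a) {
    overshoot <- (cdd0[b] - cdd0[a]) - req
    undershoot <- req - (cdd0[b - 1L] - cdd0[a])
    if (undershoot < overshoot) b <- b - 1L
  }
  b
}

#' Simulate one rearing cohort
#'
#' Each individual draws lognormal per-stage degree-day requirements around
#' the diet's stage means, converts them to calendar dates by accumulating
#' daily degree-days over the temperature series (the molt day belongs to
#' the stage being entered), suffers an independent mortality draw at entry
#' into each pre-adult stage (death falls uniformly within the stage),
#' and, on reaching adulthood, is sexed, lives out a lognormal adult
#' degree-day budget, and (if female) lays a truncated-normal egg count of
#' which a binomial share hatches.
#'
#' @param config a [sim_config()].
#' @param diet a [diet_profile()].
#' @param generation generation number (the second brood gets the
#'   configured fecundity shift).
#' @param series a `temperature_series` long enough for every individual to
#'   finish or die; exhaustion raises a simulation-horizon error.
#' @param start_date oviposition date of the cohort's first egg.
#' @param seed integer seed (NULL to use the current random state).
#' @return a `rearing_log` of `config$cohort_size` individuals.
#' @export
simulate_cohort <- function(config, diet, generation, series,
                            start_date = config$start_date, seed = NULL) {
  with_seed(seed, {
    n <- config$cohort_size
    cdd0 <- .cum_dd(series, config$dd)
    pre <- setdiff(stage_codes(), "AD")
    cv <- diet$stage_add_cv
    sdlog <- sqrt(log(1 + cv^2))
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      id <- sprintf("%s-G%d-%03d", diet$label, generation, i)
      lay_offset <- sample.int(config$oviposition_spread + 1L, 1L) - 1L
      a <- .day_index(series, as.Date(start_date) + lay_offset)
      if (is.na(a)) stop("temperature series does not cover the cohort start")
      entry <- stats::setNames(rep(as.Date(NA), 7), stage_codes())
      entry["EG"] <- series$date[a]
      death_date <- as.Date(NA); death_stage <- NA_character_
      sex <- NA_character_
      eggs <- NA_integer_; hatched <- NA_integer_
      reached_ad <- TRUE
      for (s in pre) {
        req <- stats::rlnorm(1, log(diet$stage_add_mean[[s]]) - sdlog^2 / 2,
                             sdlog)
        b <- .advance(cdd0, a, req)
        if (is.na(b)) stop("simulation horizon exceeded for ", id)
        if (stats::runif(1) < diet$stage_mortality[[s]]) {
          death_day <- a + floor(stats::runif(1) * (b - a))
          death_date <- series$date[min(death_day, nrow(series))]
          death_stage <- s
          reached_ad <- FALSE
          break
        }
        a <- b
        nxt <- stage_codes()[stage_index(s) + 1L]
        entry[nxt] <- series$date[a]
      }
      if (reached_ad) {
        budget <- stats::rlnorm(1, log(diet$adult_add_mean) - sdlog^2 / 2,
                                sdlog)
        b <- .advance(cdd0, a, budget)
        if (is.na(b)) stop("simulation horizon exceeded for ", id)
        death_date <- series$date[b]
        death_stage <- "AD"
        sex <- if (stats::runif(1) < diet$male_prob) "male" else "female"
        if (sex == "female") {
          shift <- if (generation >= 2) config$fecundity_gen2_shift else 0
          eggs <- max(0L, as.integer(round(stats::rnorm(
            1, diet$fecundity_mean + shift, diet$fecundity_sd))))
          hatched <- stats::rbinom(1, eggs, diet$hatch_prob)
        }
      }
      rows[[i]] <- data.frame(
        individual_id = id, diet = diet$label, generation = generation,
        date_EG = entry[["EG"]], date_N1 = entry[["N1"]],
        date_N2 = entry[["N2"]], date_N3 = entry[["N3"]],
        date_N4 = entry[["N4"]], date_N5 = entry[["N5"]],
        date_AD = entry[["AD"]],
        death_date = death_date, death_stage = death_stage,
        sex = sex, eggs_laid = eggs, eggs_hatched = hatched,
        stringsAsFactors = FALSE
      )
    }
    as_rearing_log(do.call(rbind, rows))
  })
}

#' Simulate a full rearing experiment
#'
#' Generates the laboratory temperature series and one cohort per diet per
#' generation, successive generations starting `gen_lag_days` apart. Cohort
#' seeds are derived deterministically from the experiment seed, so the
#' whole dataset is bit-reproducible.
#'
#' @param config a [sim_config()].
#' @param seed integer experiment seed.
#' @param n_days temperature-series length (must outlast the slowest
#'   individual).
#' @return list with elements `log` (a `rearing_log` over all cohorts) and
#'   `temps` (the `temperature_series`).
#' @export
simulate_experiment <- function(config, seed, n_days = 1500) {
  series <- simulate_temperatures(config, config$start_date, n_days,
                                  seed = seed)
  logs <- list(); k <- 0L
  for (gen in seq_len(config$generations)) {
    start <- config$start_date + (gen - 1L) * config$gen_lag_days
    for (diet in config$diets) {
      k <- k + 1L
      logs[[k]] <- simulate_cohort(config, diet, gen, series,
                                   start_date = start,
                                   seed = (seed + 1000L * k) %% .Machine$integer.max)
    }
  }
  log <- do.call(rbind, lapply(logs, as.data.frame))
  list(log = as_rearing_log(log), temps = series)
}
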