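# shared builders for test fixtures; everything is generated in code

const_series <- function(tmin, tmax, start = as.Date("2021-01-01"), n = 400) {
  as_temperature_series(data.frame(date = start + seq_len(n) - 1,
                                   tmin = tmin, tmax = tmax))
}

rand_series <- function(seed, n = 60, start = as.Date("2021-03-01")) {
  with_seed(seed, {
    mid <- 21.5 + 2 * sin(seq_len(n) / 30) + rnorm(n, 0, 1)
    half <- runif(n, 1, 4)
    as_temperature_series(data.frame(date = start + seq_len(n) - 1,
                                     tmin = mid - half, tmax = mid + half))
  })
}

# minimal single-individual record; stage_dates is a named vector of entry
# dates over a prefix of the stage order
make_record <- function(id, stage_dates, death_date = NA, sex = NA,
                        eggs_laid = NA, eggs_hatched = NA,
                        diet = "Dm", generation = 1L) {
  row <- data.frame(individual_id = id, diet = diet, generation = generation,
                    date_EG = as.Date(NA), date_N1 = as.Date(NA),
                    date_N2 = as.Date(NA), date_N3 = as.Date(NA),
                    date_N4 = as.Date(NA), date_N5 = as.Date(NA),
                    date_AD = as.Date(NA),
                    death_date = as.Date(death_date),
                    death_stage = NA_character_,
                    sex = as.character(sex),
                    eggs_laid = as.integer(eggs_laid),
                    eggs_hatched = as.integer(eggs_hatched),
                    stringsAsFactors = FALSE)
  for (s in names(stage_dates)) row[[paste0("date_", s)]] <- as.Date(stage_dates[[s]])
  last <- stage_codes()[max(stage_index(names(stage_dates)))]
  if (!is.na(row$death_date)) row$death_stage <- last
  row
}

make_log <- function(...) as_rearing_log(do.call(rbind, list(...)))

# a small fast generator config used across tests
test_config <- function(...) {
  sim_config(jitter_sd = 0.2, ...)
}
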