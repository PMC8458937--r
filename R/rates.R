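#' Age-indexed annual event rate table
#'
#' A rate table maps contiguous single years of age to annual event
#' probabilities (breast-cancer incidence or all-cause death). Ages must be
#' strictly increasing with step 1 and all probabilities must lie in `[0, 1]`.
#'
#' @param ages Integer vector of contiguous ages (step 1).
#' @param rates Annual event probabilities, same length as `ages`.
#' @return An object of class `rate_table` (a data frame with columns `age`
#'   and `annual_probability`).
#' @seealso [load_fixture_rates()], [generate_rate_tables()], [rate_lookup()]
#' @export
rate_table <- function(ages, rates) {
  ages <- as.integer(ages)
  if (length(ages) == 0L || length(ages) != length(rates)) {
    stop("ages and rates must be non-empty vectors of equal length")
  }
  if (length(ages) > 1L && any(diff(ages) != 1L)) {
    stop("ages must be strictly increasing with step 1")
  }
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1)) {
    stop("all rates must lie in [0, 1]")
  }
  out <- data.frame(age = ages, annual_probability = as.numeric(rates))
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Look up the annual probability at an age
#'
#' Ages outside the table's coverage raise an error rather than extrapolate,
#' so coverage bugs cannot pass silently.
#'
#' @param table A [rate_table()].
#' @param age Integer age(s) to look up.
#' @return Annual event probability at each requested age.
#' @export
rate_lookup <- function(table, age) {
  idx <- match(as.integer(age), table$age)
  if (anyNA(idx)) {
    stop(sprintf("age %s outside rate-table coverage [%d, %d]",
                 paste(age[is.na(idx)], collapse = ", "),
                 min(table$age), max(table$age)))
  }
  table$annual_probability[idx]
}

# coverage check used by the cohort engine
.check_coverage <- function(table, start_age, horizon, what) {
  needed <- start_age + c(0, horizon)
  if (min(table$age) > needed[1] || max(table$age) < needed[2]) {
    stop(sprintf("%s rate table must cover ages [%d, %d]; got [%d, %d]",
                 what, needed[1], needed[2], min(table$age), max(table$age)))
  }
  invisible(TRUE)
}

#' Load a packaged age-indexed rate fixture
#'
#' Two fixtures ship with the package, covering ages 55-75:
#' `breast_incidence_2017_like` (annual breast-cancer incidence probability,
#' emulating SEER-style age-specific rates) and `female_mortality_2017_like`
#' (annual all-cause death probability for women, emulating a US period life
#' table). Both are synthetic emulations of the public reference tables; see
#' the header comments of the CSV files for provenance notes.
#'
#' @param name One of `"breast_incidence_2017_like"`,
#'   `"female_mortality_2017_like"`.
#' @return A [rate_table()].
#' @export
#' @examples
#' mort <- load_fixture_rates("female_mortality_2017_like")
#' rate_lookup(mort, 55)
load_fixture_rates <- function(name = c("breast_incidence_2017_like",
                                        "female_mortality_2017_like")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "mrmcea",
                      mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#")
  rate_table(df$age, df$annual_probability)
}

#' Default incidence/mortality rate pair
#'
#' Convenience loader returning both packaged fixtures as a named list, the
#' form every model-running function accepts via its `rates` argument.
#'
#' @return A list with elements `incidence` and `mortality`, each a
#'   [rate_table()].
#' @export
default_rates <- function() {
  list(incidence = load_fixture_rates("breast_incidence_2017_like"),
       mortality = load_fixture_rates("female_mortality_2017_like"))
}

#' Profile for synthetic rate-table generation
#'
#' Describes the structural shape of a plausible incidence/mortality pair:
#' incidence follows a linear age trend, mortality an exponential-in-age
#' (Gompertz-like) curve, optionally perturbed by multiplicative noise.
#'
#' @param age_min,age_max Age span (contiguous integer years).
#' @param incidence_base Incidence probability at `age_min`.
#' @param incidence_trend Additive incidence change per year of age.
#' @param mortality_base Mortality probability at `age_min`.
#' @param mortality_slope Exponential age slope of mortality (> 0 gives the
#'   strictly increasing curve characteristic of adult life tables).
#' @param noise_sd Standard deviation of multiplicative log-normal noise
#'   (0 = deterministic curves).
#' @return An object of class `rate_profile`.
#' @export
rate_profile <- function(age_min = 55, age_max = 75,
                         incidence_base = 0.0023, incidence_trend = 0.00012,
                         mortality_base = 0.005, mortality_slope = 0.08,
                         noise_sd = 0.02) {
  stopifnot(age_max > age_min, incidence_base >= 0, mortality_base > 0,
            noise_sd >= 0)
  out <- list(age_min = as.integer(age_min), age_max = as.integer(age_max),
              incidence_base = incidence_base,
              incidence_trend = incidence_trend,
              mortality_base = mortality_base,
              mortality_slope = mortality_slope,
              noise_sd = noise_sd)
  class(out) <- "rate_profile"
  out
}

#' Generate a synthetic incidence/mortality rate-table pair
#'
#' Deterministic given `seed`. Mortality follows
#' `mortality_base * exp(mortality_slope * (age - age_min))` with optional
#' multiplicative log-normal noise, clipped to `[0, 1]`; incidence follows the
#' linear trend `incidence_base + incidence_trend * (age - age_min)`, floored
#' at 0. A profile whose noise-free curves leave `[0, 1]` is rejected.
#'
#' @param profile A [rate_profile()].
#' @param seed Integer RNG seed.
#' @return A list with elements `incidence` and `mortality`, each a
#'   [rate_table()].
#' @export
#' @examples
#' r <- generate_rate_tables(rate_profile(noise_sd = 0), seed = 1)
#' all(diff(r$mortality$annual_probability) > 0)
generate_rate_tables <- function(profile, seed) {
  stopifnot(inherits(profile, "rate_profile"))
  ages <- profile$age_min:profile$age_max
  rel <- ages - profile$age_min
  inc <- profile$incidence_base + profile$incidence_trend * rel
  mort <- profile$mortality_base * exp(profile$mortality_slope * rel)
  if (any(inc < 0) || any(inc > 1) || any(mort > 1)) {
    stop("profile produces probabilities outside [0, 1]")
  }
  if (profile$noise_sd > 0) {
    old_seed <- .save_rng()
    on.exit(.restore_rng(old_seed))
    set.seed(as.integer(seed))
    inc <- pmin(1, pmax(0, inc * exp(stats::rnorm(length(inc), 0,
                                                  profile$noise_sd))))
    mort <- pmin(1, pmax(0, mort * exp(stats::rnorm(length(mort), 0,
                                                    profile$noise_sd))))
  }
  list(incidence = rate_table(ages, inc), mortality = rate_table(ages, mort))
}

#' Write a rate table in the fixture CSV format
#'
#' @param table A [rate_table()].
#' @param path Output path.
#' @param comment Optional provenance comment lines (without leading `#`).
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(table, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines("age,annual_probability", con)
  writeLines(sprintf("%d,%.10g", table$age, table$annual_probability), con)
  invisible(path)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}
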