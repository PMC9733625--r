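#' Read a life table from CSV
#'
#' Expected header: `age,q_male,q_female`, one row per integer age, annual
#' all-cause death probabilities as decimals. Ages must be contiguous.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble of class `life_table`.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Life table file not found: %s", path),
          class = "tremorcea_config_error")
  }
  lt <- as_tibble(read.csv(path))
  validate_life_table(lt)
}

#' Validate a life table
#'
#' @param lt Data frame with columns `age`, `q_male`, `q_female`.
#' @return `lt` as a tibble with class `life_table`; errors of class
#'   `tremorcea_validation_error` otherwise.
#' @export
validate_life_table <- function(lt) {
  need <- c("age", "q_male", "q_female")
  if (!all(need %in% names(lt))) {
    abort("Life table must have columns age, q_male, q_female.",
          class = "tremorcea_validation_error")
  }
  lt <- as_tibble(lt)[need]
  if (any(diff(lt$age) != 1)) {
    abort("Life table ages must be contiguous integers.",
          class = "tremorcea_validation_error")
  }
  q <- c(lt$q_male, lt$q_female)
  if (any(is.na(q)) || any(q < 0) || any(q > 1)) {
    abort("Life table probabilities must lie in [0, 1].",
          class = "tremorcea_validation_error")
  }
  class(lt) <- c("life_table", class(lt))
  lt
}

#' Bundled synthetic England-style life table
#'
#' A smooth Gompertz--Makeham schedule for ages 40--85 calibrated to the
#' level of recent (2017--2019 era) national life tables for England. It is
#' a synthetic stand-in, not a transcription of official rates, shipped so
#' the model runs with no download; substitute your own CSV via
#' [read_life_table()] for production estimates.
#'
#' @return A `life_table` tibble, ages 40--85.
#' @export
#' @examples
#' lt <- england_life_table()
#' blended_mortality(lt, 70, 0.46)
england_life_table <- function() {
  read_life_table(system.file("extdata", "life_table_england_synthetic.csv",
                              package = "tremorcea", mustWork = TRUE))
}

#' Sex-blended annual death probability
#'
#' @param lt A `life_table`.
#' @param age Integer age; must be covered by the table.
#' @param male_fraction Male proportion of the cohort.
#' @return `male_fraction * q_male(age) + (1 - male_fraction) * q_female(age)`.
#' @export
blended_mortality <- function(lt, age, male_fraction) {
  i <- match(age, lt$age)
  if (is.na(i)) {
    abort(sprintf("Age %s outside the life table range [%d, %d].",
                  age, min(lt$age), max(lt$age)),
          class = "tremorcea_range_error")
  }
  male_fraction * lt$q_male[i] + (1 - male_fraction) * lt$q_female[i]
}
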