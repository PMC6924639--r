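#' Age-indexed rate table
#'
#' The life table's substrate: per-age hazards of prostate-cancer incidence,
#' prostate-cancer death and death from other causes (events per person-year,
#' 1-year age bands, attained age), plus population weights giving the number
#' of men entering the cohort at each age between `entry_min` and `entry_max`.
#'
#' @param age Integer attained ages, contiguous (typically 45--90).
#' @param pc_incidence Prostate-cancer incidence per person-year.
#' @param pc_mortality Prostate-cancer deaths per person-year.
#' @param other_mortality Other-cause deaths per person-year.
#' @param population_weight Men entering the cohort at each age; zero outside
#'   the entry window. Their sum is the cohort size.
#' @return A `data.frame` of class `rate_table`.
#' @seealso [generate_rates()] for a synthetic table, [read_rate_table()].
#' @export
rate_table <- function(age, pc_incidence, pc_mortality, other_mortality,
                       population_weight = rep(0, length(age))) {
  x <- data.frame(
    age = as.integer(age),
    pc_incidence = as.numeric(pc_incidence),
    pc_mortality = as.numeric(pc_mortality),
    other_mortality = as.numeric(other_mortality),
    population_weight = as.numeric(population_weight)
  )
  class(x) <- c("rate_table", "data.frame")
  validate_rate_table(x)
  x
}

validate_rate_table <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("age", "pc_incidence", "pc_mortality", "other_mortality",
            "population_weight")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("rate table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) < 2L || any(diff(x$age) != 1L)) {
    stop("rate table ages must be contiguous 1-year bands", call. = FALSE)
  }
  rates <- as.matrix(x[c("pc_incidence", "pc_mortality", "other_mortality")])
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates >= 1)) {
    stop("all rates must lie in [0, 1) per person-year", call. = FALSE)
  }
  if (any(x$population_weight < 0)) {
    stop("population weights must be non-negative", call. = FALSE)
  }
  invisible(x)
}

#' Read / write a rate table as CSV
#'
#' The on-disk dialect is a plain CSV with header
#' `age,pc_incidence,pc_mortality,other_mortality,population_weight`;
#' rates are events per person-year in 1-year attained-age bands.
#'
#' @param path Path to a CSV file.
#' @return `read_rate_table()` returns a validated [rate_table()];
#'   `write_rate_table()` returns `path` invisibly.
#' @export
read_rate_table <- function(path) {
  x <- utils::read.csv(path, check.names = TRUE)
  if (!"population_weight" %in% names(x)) x$population_weight <- 0
  rate_table(x$age, x$pc_incidence, x$pc_mortality, x$other_mortality,
             x$population_weight)
}

#' @rdname read_rate_table
#' @param x A [rate_table()].
#' @export
write_rate_table <- function(x, path) {
  validate_rate_table(x)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.rate_table <- function(x, ...) {
  cohort <- sum(x$population_weight)
  cat(sprintf("Rate table: ages %d-%d, cohort size %s\n",
              min(x$age), max(x$age), format(round(cohort), big.mark = ",")))
  NextMethod()
}

rate_at <- function(rates, age, col) {
  i <- match(age, rates$age)
  if (anyNA(i)) {
    stop("age ", paste(age[is.na(i)], collapse = ", "),
         " outside the rate table range", call. = FALSE)
  }
  rates[[col]][i]
}

#' Background 10-year absolute risk of diagnosis
#'
#' Competing-risk cumulative incidence of a prostate-cancer diagnosis within
#' 10 years for a man of the given age, in the absence of screening:
#' `sum_{t=0..9} h_inc(a+t) * S(a,t)` where `S` is the probability of
#' remaining alive and diagnosis-free to the start of year `t` (each year
#' survivors escape diagnosis with probability `1 - h_inc` and then other-cause
#' death with probability `1 - h_oth`). This is the "baseline risk" that the
#' polygenic distribution multiplies in [eligible_fraction()].
#'
#' @param rates A [rate_table()].
#' @param age Attained age(s); `age + 9` must be within the table.
#' @param horizon Years of follow-up (default 10).
#' @return Probability of diagnosis within the horizon, in (0, 1).
#' @export
ten_year_absolute_risk <- function(rates, age, horizon = 10L) {
  validate_rate_table(rates)
  vapply(age, function(a) {
    if (a < min(rates$age) || (a + horizon - 1L) > max(rates$age)) {
      stop("10-year window for age ", a, " exceeds the rate table",
           call. = FALSE)
    }
    S <- 1
    risk <- 0
    for (t in seq_len(horizon) - 1L) {
      hi <- rate_at(rates, a + t, "pc_incidence")
      ho <- rate_at(rates, a + t, "other_mortality")
      risk <- risk + S * hi
      S <- S * (1 - hi) * (1 - ho)
    }
    risk
  }, numeric(1))
}
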