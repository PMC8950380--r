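# Cohort and life-table domain types, validation, readers and writers.
#
# A cohort is a data.frame with one row per patient:
#   id        character, opaque
#   age_dx    integer, age at diagnosis in 26..74
#   age_group factor {<=49, 50-59, 60-74}, derived from age_dx
#   stage     factor {I, II, III}
#   her2      factor {pos, neg}
#   adherence factor {yes, no}, NA = missing
#   followup  integer follow-up years in 1..10
#   exitus    factor {died, survived}; survived => censored at followup
#   year_dx   integer calendar year of diagnosis
#
# The life table carries one annual mortality hazard per (age, year) cell
# for the female general population; no sex column (the cohort is all
# women).

AGE_GROUP_LEVELS <- c("<=49", "50-59", "60-74")
STAGE_LEVELS     <- c("I", "II", "III")
HER2_LEVELS      <- c("pos", "neg")
ADHERENCE_LEVELS <- c("yes", "no")
EXITUS_LEVELS    <- c("died", "survived")
AGE_MIN <- 26L
AGE_MAX <- 74L
FOLLOWUP_MAX <- 10L

#' Age group of an age at diagnosis
#'
#' Maps exact age to the three-level grouping used throughout
#' (`<=49`, `50-59`, `60-74`).
#'
#' @param age_dx integer vector of ages.
#' @return factor with levels `<=49`, `50-59`, `60-74`.
#' @export
age_group_of <- function(age_dx) {
  cut(age_dx, breaks = c(-Inf, 49, 59, Inf), labels = AGE_GROUP_LEVELS)
}

# Validate a cohort data.frame in place; stops with the offending row id.
validate_cohort <- function(cohort, require_adherence = FALSE) {
  need <- c("id", "age_dx", "stage", "her2", "adherence",
            "followup", "exitus", "year_dx")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0L)
    stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  bad <- function(which, what) {
    if (any(which))
      stop("invalid ", what, " in row id(s): ",
           paste(utils::head(cohort$id[which], 5L), collapse = ", "))
  }
  bad(is.na(cohort$age_dx) | cohort$age_dx < AGE_MIN | cohort$age_dx > AGE_MAX,
      sprintf("age_dx (must be %d..%d)", AGE_MIN, AGE_MAX))
  bad(is.na(cohort$followup) | cohort$followup < 1L |
        cohort$followup > FOLLOWUP_MAX,
      sprintf("followup (must be 1..%d)", FOLLOWUP_MAX))
  bad(!(cohort$stage %in% STAGE_LEVELS), "stage code")
  bad(!(cohort$her2 %in% HER2_LEVELS), "her2 code")
  bad(!(cohort$exitus %in% EXITUS_LEVELS), "exitus code")
  bad(!is.na(cohort$adherence) & !(cohort$adherence %in% ADHERENCE_LEVELS),
      "adherence code")
  if (require_adherence) bad(is.na(cohort$adherence), "missing adherence")
  invisible(cohort)
}

# Canonicalize column types and ordering; derives age_group.
as_cohort <- function(df) {
  df$id        <- as.character(df$id)
  df$age_dx    <- as.integer(df$age_dx)
  df$stage     <- factor(as.character(df$stage), levels = STAGE_LEVELS)
  df$her2      <- factor(as.character(df$her2), levels = HER2_LEVELS)
  df$adherence <- factor(as.character(df$adherence),
                         levels = ADHERENCE_LEVELS)
  df$followup  <- as.integer(df$followup)
  df$exitus    <- factor(as.character(df$exitus), levels = EXITUS_LEVELS)
  df$year_dx   <- as.integer(df$year_dx)
  df$age_group <- age_group_of(df$age_dx)
  df[c("id", "age_dx", "age_group", "stage", "her2", "adherence",
       "followup", "exitus", "year_dx")]
}

#' Read a patient-level cohort file
#'
#' Reads the canonical cohort CSV (columns `id, age_dx, stage, her2,
#' adherence, followup, exitus, year_dx`), applies the registry exclusion
#' rules in order, and validates every surviving record. The exclusion
#' rules mirror a registry intake: (1) missing hormone-receptor/HER2
#' status, (2) missing stage or stage IV, (3) unretrievable follow-up. A
#' record failing several rules is counted once, under the first matching
#' rule. The position of the follow-up rule is configurable because
#' registries differ on where it sits in the intake order.
#'
#' @param path path to a CSV file with header.
#' @param followup_rule_position integer 1..3; where the
#'   missing-follow-up rule sits in the exclusion order (default 3, last).
#' @return the cohort data.frame, with the exclusion tally attached as
#'   attribute `filter_report` (class `cohort_filter_report`): counts
#'   dropped per rule plus `kept` and `input_n`.
#' @export
read_cohort <- function(path, followup_rule_position = 3L) {
  if (!file.exists(path)) stop("cannot read cohort file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  if (!"id" %in% names(raw)) stop("cohort file has no 'id' column")
  n_in <- nrow(raw)

  rules <- list(
    receptor = function(d) is.na(d$her2) | !(d$her2 %in% HER2_LEVELS),
    stage    = function(d) is.na(d$stage) | d$stage == "IV" |
                           !(d$stage %in% c(STAGE_LEVELS, "IV")),
    followup = function(d) is.na(d$followup)
  )
  stopifnot(followup_rule_position %in% 1:3)
  ord <- append(c("receptor", "stage"), "followup",
                after = followup_rule_position - 1L)
  rules <- rules[ord]

  dropped <- stats::setNames(integer(length(rules)), names(rules))
  excluded <- rep(FALSE, n_in)
  for (rn in names(rules)) {
    hit <- rules[[rn]](raw) & !excluded
    dropped[rn] <- sum(hit)
    excluded <- excluded | hit
  }
  kept <- raw[!excluded, , drop = FALSE]
  cohort <- validate_cohort(as_cohort(kept))

  report <- structure(
    list(dropped = as.list(dropped), kept = nrow(cohort), input_n = n_in),
    class = "cohort_filter_report")
  attr(cohort, "filter_report") <- report
  cohort
}

#' @export
print.cohort_filter_report <- function(x, ...) {
  cat("Cohort intake:", x$input_n, "records read,", x$kept, "kept\n")
  for (rn in names(x$dropped))
    cat(sprintf("  dropped (%s): %d (%.1f%%)\n", rn, x$dropped[[rn]],
                percentage(x$dropped[[rn]], x$input_n)))
  invisible(x)
}

#' Write a cohort to the canonical CSV
#'
#' Inverse of [read_cohort()]: writes the eight canonical columns
#' (dropping the derived `age_group`), with missing adherence as `NA`.
#'
#' @param cohort cohort data.frame.
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort[c("id", "age_dx", "stage", "her2", "adherence",
                  "followup", "exitus", "year_dx")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Reported percentage
#'
#' `100 * numerator / denominator`, rounded to one decimal with halves
#' away from zero — the convention of every percentage printed in
#' registry reports.
#'
#' @param numerator,denominator counts; `denominator` must be positive.
#' @return percentage rounded to one decimal.
#' @examples
#' percentage(352, 4053)  # 8.7
#' @export
percentage <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  round_half_away(100 * numerator / denominator, 1L)
}

#' Read a general-population life table
#'
#' Reads a CSV with columns `age, year, rate` (annual mortality hazard
#' per person-year) and optionally validates complete coverage of a
#' stated age and calendar-year range. Age lookups beyond the covered
#' range clamp to the nearest covered age (applied at lookup, not load);
#' a missing calendar year is an error.
#'
#' @param path path to the CSV.
#' @param ages optional integer range (e.g. `25:85`) that must be fully
#'   covered for every year.
#' @param years optional integer vector of calendar years that must be
#'   fully covered.
#' @return an object of class `life_table`.
#' @export
read_lifetable <- function(path, ages = NULL, years = NULL) {
  if (!file.exists(path)) stop("cannot read life table: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "year", "rate")
  if (!all(need %in% names(df)))
    stop("life table must have columns age, year, rate")
  if (anyDuplicated(df[c("age", "year")]) > 0L)
    stop("duplicate (age, year) keys in life table")
  if (any(df$rate < 0)) stop("negative mortality rate in life table")
  lt <- new_lifetable(df$age, df$year, df$rate)
  if (!is.null(ages) || !is.null(years)) {
    ages  <- ages  %||% lt$ages
    years <- years %||% lt$years
    want <- expand.grid(age = ages, year = years)
    have <- !is.na(lt$rate[cbind(match(want$age, lt$ages),
                                 match(want$year, lt$years))])
    if (any(!have)) {
      first <- want[which(!have)[1L], ]
      stop(sprintf("life table missing (age=%d, year=%d)",
                   first$age, first$year))
    }
  }
  lt
}

# Construct a life_table from parallel vectors.
new_lifetable <- function(age, year, rate) {
  ages  <- sort(unique(age))
  years <- sort(unique(year))
  m <- matrix(NA_real_, length(ages), length(years),
              dimnames = list(ages, years))
  m[cbind(match(age, ages), match(year, years))] <- rate
  structure(list(rate = m, ages = ages, years = years),
            class = "life_table")
}

#' Population mortality rate lookup
#'
#' Annual hazard for given attained ages and calendar years. Ages beyond
#' the table's range clamp to the nearest covered age (the standard
#' convention for open-ended terminal age groups); calendar years must be
#' covered.
#'
#' @param lt a `life_table`.
#' @param age,year integer vectors (recycled to common length).
#' @return numeric vector of annual hazards.
#' @export
lifetable_rate <- function(lt, age, year) {
  stopifnot(inherits(lt, "life_table"))
  n <- max(length(age), length(year))
  age  <- rep_len(pmin(pmax(age, min(lt$ages)), max(lt$ages)), n)
  year <- rep_len(year, n)
  iy <- match(year, lt$years)
  if (anyNA(iy))
    stop("life table does not cover calendar year(s): ",
         paste(unique(year[is.na(iy)]), collapse = ", "))
  r <- lt$rate[cbind(match(age, lt$ages), iy)]
  if (anyNA(r))
    stop("life table has gaps at the requested (age, year) cells")
  r
}

#' Write a life table to CSV
#'
#' @param lt a `life_table`.
#' @param path output path.
#' @export
write_lifetable <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  df <- expand.grid(age = lt$ages, year = lt$years)
  df$rate <- lt$rate[cbind(match(df$age, lt$ages),
                           match(df$year, lt$years))]
  df <- df[!is.na(df$rate), ]
  df <- df[order(df$age, df$year), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.life_table <- function(x, ...) {
  cat("Life table:", length(x$ages), "ages (", min(x$ages), "-",
      max(x$ages), "),", length(x$years), "years (", min(x$years), "-",
      max(x$years), ")\n")
  invisible(x)
}
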