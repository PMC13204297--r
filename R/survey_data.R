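#' @keywords internal
SEX_LEVELS <- c("total", "men", "women")

#' Default survey waves retained for trend fitting
#'
#' The four post-structural-break triennial waves. Earlier waves (2007, 2010)
#' precede a policy-driven discontinuity in screening trends and are excluded
#' from model training by default.
#' @export
DEFAULT_WAVES <- c(2013L, 2016L, 2019L, 2022L)

#' Construct a coverage series
#'
#' One unit's observed screening coverage over survey years for a single sex
#' group. Coverage is stored as a proportion in the open interval (0, 1);
#' percent is used only at I/O boundaries.
#'
#' @param unit Unit identifier (prefecture name or `"nationwide"`).
#' @param sex One of `"total"`, `"men"`, `"women"`.
#' @param years Integer vector of survey years, strictly increasing.
#' @param coverage Numeric vector of proportions in (0, 1), same length.
#' @return An object of class `coverage_series`.
#' @examples
#' coverage_series("nationwide", "total", c(2013, 2016, 2019, 2022),
#'                 c(0.423, 0.45, 0.47, 0.497))
#' @export
coverage_series <- function(unit, sex, years, coverage) {
  stopifnot(is.character(unit), length(unit) == 1L)
  sex <- match.arg(sex, SEX_LEVELS)
  years <- as.integer(years)
  coverage <- as.numeric(coverage)
  if (length(years) != length(coverage))
    stop("years and coverage must have equal length")
  if (length(years) && any(diff(years) <= 0))
    stop("years must be strictly increasing")
  if (any(!is.finite(coverage)) || any(coverage <= 0) || any(coverage >= 1))
    stop("coverage must lie strictly inside (0, 1)")
  structure(list(unit = unit, sex = sex, years = years, coverage = coverage),
            class = "coverage_series")
}

#' @export
print.coverage_series <- function(x, ...) {
  cat(sprintf("<coverage_series> %s / %s: %d waves\n", x$unit, x$sex,
              length(x$years)))
  print(data.frame(year = x$years, coverage_pct = round(100 * x$coverage, 1)),
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.coverage_series <- function(x, ...) {
  data.frame(unit = x$unit, sex = x$sex, year = x$years,
             coverage_pct = 100 * x$coverage, stringsAsFactors = FALSE)
}

#' Read a coverage table from CSV
#'
#' Reads a long-format CSV with columns `unit,sex,year,coverage_pct` and
#' returns one [coverage_series] per (unit, sex) pair. Rows whose year is not
#' in `wave_whitelist` are dropped: this implements the structural-break
#' filter that removes pre-2013 waves from training.
#'
#' @param path Path to the CSV file (UTF-8, comma separated, header required,
#'   `#` comment lines ignored).
#' @param wave_whitelist Integer vector of years to retain.
#'   Defaults to [DEFAULT_WAVES].
#' @return List of `coverage_series`, in first-appearance order of
#'   (unit, sex) in the file.
#' @export
read_coverage_csv <- function(path, wave_whitelist = DEFAULT_WAVES) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("unit", "sex", "year", "coverage_pct")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(df$coverage_pct) |
                 df$coverage_pct <= 0 | df$coverage_pct >= 100)
  if (length(bad))
    stop("coverage_pct outside (0, 100) at data row(s): ",
         paste(bad, collapse = ", "))
  if (!all(df$sex %in% SEX_LEVELS))
    stop("sex must be one of: ", paste(SEX_LEVELS, collapse = ", "))
  key <- paste(df$unit, df$sex, df$year, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (unit, sex, year) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  df <- df[df$year %in% as.integer(wave_whitelist), , drop = FALSE]
  pair <- paste(df$unit, df$sex, sep = "\r")
  out <- lapply(unique(pair), function(p) {
    sub <- df[pair == p, , drop = FALSE]
    sub <- sub[order(sub$year), , drop = FALSE]
    coverage_series(sub$unit[1L], sub$sex[1L], sub$year,
                    sub$coverage_pct / 100)
  })
  out
}

#' Write coverage series to CSV
#'
#' Inverse of [read_coverage_csv()]: writes a long-format
#' `unit,sex,year,coverage_pct` table, percentages rounded to 1 decimal
#' (the survey's printed resolution).
#'
#' @param series_list List of [coverage_series].
#' @param path Output path.
#' @param digits Decimal places for percent values.
#' @param header_comment Optional comment line (written prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_coverage_csv <- function(series_list, path, digits = 1,
                               header_comment = NULL) {
  df <- do.call(rbind, lapply(series_list, as.data.frame))
  df$coverage_pct <- round(df$coverage_pct, digits)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load the packaged reference tables
#'
#' Returns the published prefecture-level results shipped with the package:
#' observed coverage for the 2013 and 2022 survey waves, projected 2028
#' coverage with 95% credible intervals, the annual percentage change (APC)
#' with 95% CrI, the posterior probability of reaching the 60% benchmark by
#' 2028 (credible interval available for the nationwide unit only), the first
#' year attainment probability reaches 0.80 (`"never"` if not by 2100), and
#' the published on-track marker (target year at or before 2030).
#'
#' All values are percent (coverage, APC in percentage points per year)
#' except `prob_target`/`prob_lo`/`prob_hi`, which are probabilities in
#' \[0, 1\].
#'
#' @return A `data.frame` of 144 rows (48 units x 3 sex groups) with class
#'   `fixture_table`.
#' @examples
#' fix <- load_fixture_tables()
#' fix[fix$unit == "Yamagata" & fix$sex == "total", "coverage_2013"]  # 60.0
#' @export
load_fixture_tables <- function() {
  p1 <- system.file("extdata", "table1_coverage.csv", package = "screentrend",
                    mustWork = TRUE)
  p2 <- system.file("extdata", "table2_attainment.csv",
                    package = "screentrend", mustWork = TRUE)
  t1 <- read.csv(p1, stringsAsFactors = FALSE)
  t2 <- read.csv(p2, stringsAsFactors = FALSE,
                 colClasses = c(target_year = "character"))
  stopifnot(nrow(t1) == 144L, nrow(t2) == 144L,
            identical(t1$unit, t2$unit), identical(t1$sex, t2$sex))
  out <- cbind(t1, t2[, setdiff(names(t2), c("unit", "sex"))])
  class(out) <- c("fixture_table", "data.frame")
  out
}

#' Extract one column of a fixture table as a named vector
#'
#' Convenience accessor used by the derived-indicator functions: selects one
#' sex group and one variable, named by unit, preserving table order.
#'
#' @param fixture A [load_fixture_tables()] result.
#' @param sex One of `"total"`, `"men"`, `"women"`.
#' @param column Column name, e.g. `"coverage_2022"` or `"prob_target"`.
#' @param include_nationwide Keep the nationwide row? Default `FALSE`
#'   because the published counts and ranges are over prefectures only.
#' @return Named numeric (or character, for `target_year`) vector.
#' @export
fixture_column <- function(fixture, sex = "total", column,
                           include_nationwide = FALSE) {
  sex <- match.arg(sex, SEX_LEVELS)
  stopifnot(column %in% names(fixture))
  sub <- fixture[fixture$sex == sex, , drop = FALSE]
  if (!include_nationwide)
    sub <- sub[sub$unit != "Nationwide", , drop = FALSE]
  setNames(sub[[column]], sub$unit)
}
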