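#' Derived-indicator summary of the packaged reference tables
#'
#' Recomputes, from the packaged tables alone, the headline monitoring
#' indicators: national sex gaps at baseline, the latest wave and the
#' projection horizon; national improvement by sex; prefectures at or above
#' the 60% benchmark in each wave; coverage ranges; the largest prefectural
#' sex gaps; the count of prefectures with a large (>= 15 pp) male-female
#' gap in attainment probability; and on-track counts under both the
#' probability rule and the target-year rule.
#'
#' @param fixture A fixture table, by default [load_fixture_tables()].
#' @param threshold Benchmark in percent (default 60).
#' @param disparity_cutoff Large-disparity cutoff in pp (default 15).
#' @param prob_level On-track probability level (default 0.80).
#' @param on_track_by Latest on-track target year (default 2030).
#' @return Nested list of indicators (see examples in the package README).
#' @export
report_indicators <- function(fixture = load_fixture_tables(),
                              threshold = 60, disparity_cutoff = 15,
                              prob_level = 0.80, on_track_by = 2030) {
  nat <- function(sex, col)
    fixture[[col]][fixture$unit == "Nationwide" & fixture$sex == sex]
  col <- function(sex, name) fixture_column(fixture, sex, name)

  gap13 <- col("men", "coverage_2013") - col("women", "coverage_2013")
  gap22 <- col("men", "coverage_2022") - col("women", "coverage_2022")

  on_track_year_count <- function(sex) {
    ty <- col(sex, "target_year")
    yrs <- suppressWarnings(as.integer(ty))
    hit <- !is.na(yrs) & yrs <= on_track_by
    list(count = sum(hit), units = names(ty)[hit])
  }
  on_track_prob_count <- function(sex)
    count_meeting_threshold(100 * col(sex, "prob_target"), 100 * prob_level)

  list(
    national = list(
      gap_2013 = sex_gap(nat("men", "coverage_2013"),
                         nat("women", "coverage_2013")),
      gap_2022 = sex_gap(nat("men", "coverage_2022"),
                         nat("women", "coverage_2022")),
      gap_2028_projected = sex_gap(nat("men", "proj_2028_mean"),
                                   nat("women", "proj_2028_mean")),
      improvement = c(
        total = nat("total", "coverage_2022") - nat("total", "coverage_2013"),
        men = nat("men", "coverage_2022") - nat("men", "coverage_2013"),
        women = nat("women", "coverage_2022") - nat("women", "coverage_2013"))
    ),
    reached_threshold = list(
      y2013 = count_meeting_threshold(col("total", "coverage_2013"),
                                      threshold),
      y2022 = count_meeting_threshold(col("total", "coverage_2022"),
                                      threshold)),
    coverage_range = list(
      total_2013 = range_summary(col("total", "coverage_2013")),
      total_2022 = range_summary(col("total", "coverage_2022")),
      men_2022 = range_summary(col("men", "coverage_2022")),
      women_2022 = range_summary(col("women", "coverage_2022"))),
    largest_sex_gap = list(
      y2013 = range_summary(gap13)[c("max_unit", "max_value")],
      y2022 = range_summary(gap22)[c("max_unit", "max_value")]),
    large_disparity = count_large_disparity(col("men", "prob_target"),
                                            col("women", "prob_target"),
                                            disparity_cutoff)[
                                              c("count", "units")],
    on_track = list(
      year_rule = lapply(setNames(SEX_LEVELS, SEX_LEVELS),
                         on_track_year_count),
      prob_rule = lapply(setNames(SEX_LEVELS, SEX_LEVELS),
                         on_track_prob_count))
  )
}
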