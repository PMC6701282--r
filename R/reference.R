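#' Published summary statistics of the motivating post-stroke cohort
#'
#' Group-level summaries of the two-group (38 low- vs 25 high-symptom)
#' post-stroke depression cohort this package's defaults emulate: per
#' group n, age, MADRS-SIGMA and NIHSS means/SDs, depression-history and
#' antidepressant counts, and the within-high-group history subgroup
#' summary.  These are inputs for summary-level re-analysis with
#' [welch_t()] and [chisq_2x2()]; they are not computed by this package.
#'
#' @return Nested list: `age`, `madrs`, `nihss` (each with `low` and
#'   `high` = `c(n, mean, sd)`), `history_subgroup` (`with` / `without`
#'   within the high group), and 2x2 count matrices `history_counts`,
#'   `antidepressant_counts` (rows low/high, columns yes/no).
#' @export
reference_cohort_summary <- function() {
  list(
    age = list(low = c(n = 38, mean = 64.68, sd = 13.56),
               high = c(n = 25, mean = 59.28, sd = 12.26)),
    madrs = list(low = c(n = 38, mean = 2.29, sd = 2.31),
                 high = c(n = 25, mean = 14.88, sd = 6.67)),
    nihss = list(low = c(n = 38, mean = 0.58, sd = 1.20),
                 high = c(n = 25, mean = 0.84, sd = 1.28)),
    history_subgroup = list(with = c(n = 6, mean = 20.00, sd = 8.53),
                            without = c(n = 19, mean = 13.26, sd = 5.25)),
    history_counts = matrix(c(0, 38, 6, 19), 2, byrow = TRUE,
                            dimnames = list(c("low", "high"),
                                            c("yes", "no"))),
    antidepressant_counts = matrix(c(1, 37, 3, 22), 2, byrow = TRUE,
                                   dimnames = list(c("low", "high"),
                                                   c("yes", "no"))))
}

#' Published peak statistics of the motivating interaction analysis
#'
#' The five significant group-by-score interaction clusters reported for
#' the motivating cohort (n = 63, four-column design, residual df = 59):
#' band, peak region, cluster extent and peak t.  Used as worked-example
#' inputs for [r_squared()] and [t_to_z()].
#'
#' @return Data frame with columns `band`, `region`, `k`, `t`.
#' @export
reference_cluster_peaks <- function() {
  data.frame(
    band = c("broadband", "broadband", "slow4", "slow4", "slow5"),
    region = c("left superior temporal", "left insula", "left thalamus",
               "right caudate", "left cerebellum posterior"),
    k = c(72L, 49L, 44L, 59L, 45L),
    t = c(5.06, 4.82, 4.60, 4.48, 4.28))
}
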