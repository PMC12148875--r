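# Bundled summary statistics of the Qatar Biobank chronic-pain sample
# (n = 2,400; 50/50 gender split; age strata 40.9/50.6/8.5%). These printed
# marginal counts and pairwise conditional percentages are the calibration
# targets of the synthetic-cohort generator and the worked examples of the
# odds-ratio module. Only aggregate statistics are bundled; the underlying
# participant-level data are not public.

#' Published marginal pain prevalences (counts per body region)
#'
#' @return Data frame with columns `variable`, `yes`, `no`, `prevalence`
#'   (percent, 1 decimal place), one row per pain indicator.
#' @export
reference_prevalence <- function() {
  df <- data.frame(
    variable = c("headache", "all_body", "face", "neck", "back",
                 "stomach", "hip", "knee", "hand", "foot"),
    yes = c(747L, 146L, 69L, 824L, 836L, 523L, 160L, 597L, 214L, 301L),
    stringsAsFactors = FALSE
  )
  df$no <- 2400L - df$yes
  df$prevalence <- round(100 * df$yes / 2400, 1L)
  df
}

#' Published pairwise association table
#'
#' One row per (evidence, event) relationship of the reference network:
#' conditional percentages of the event given evidence present vs absent,
#' the odds ratio, and its 95% confidence bounds. Demographic evidence is
#' dichotomized level-vs-rest, so the three age levels appear as separate
#' rows. These rows drive CPT calibration in
#' [build_default_truth_network()] and serve as worked-example inputs for
#' the odds-ratio functions.
#'
#' @return Data frame with columns `parent`, `parent_level` (`"yes"` for
#'   binary pain evidence), `child`, `yes_pct`, `no_pct`, `or`, `ci_low`,
#'   `ci_high`.
#' @export
reference_associations <- function() {
  rows <- list(
    list("age", "young",  "headache", 39.450, 25.370,  1.917, 1.609,  2.284),
    list("age", "middle", "headache", 27.737, 34.599,  0.726, 0.610,  0.863),
    list("age", "senior", "headache", 11.275, 32.969,  0.258, 0.166,  0.402),
    list("age", "young",  "knee",     17.839, 29.739,  0.513, 0.420,  0.626),
    list("age", "middle", "knee",     27.901, 21.772,  1.390, 1.154,  1.675),
    list("age", "senior", "knee",     40.686, 23.406,  2.245, 1.669,  3.019),
    list("gender", "female", "headache", 37.833, 24.417, 1.884, 1.580, 2.246),
    list("gender", "female", "hand",     12.500,  5.333, 2.536, 1.870, 3.438),
    list("gender", "female", "neck",     41.667, 27.000, 1.931, 1.627, 2.293),
    list("headache", "yes", "neck",    51.138, 26.739,  2.867, 2.395,  3.433),
    list("headache", "yes", "hip",     10.442,  4.961,  2.234, 1.617,  3.085),
    list("headache", "yes", "stomach", 35.475, 15.608,  2.973, 2.433,  3.632),
    list("headache", "yes", "face",     7.631,  0.726, 11.297, 6.024, 21.186),
    list("headache", "yes", "back",    50.067, 27.949,  2.585, 2.161,  3.092),
    list("hip",  "yes", "hand",     38.750,  6.786,  8.691, 6.074, 12.434),
    list("hand", "yes", "face",     13.551,  1.830,  8.410, 5.096, 13.880),
    list("hand", "yes", "foot",     45.794,  9.286,  8.253, 6.082, 11.199),
    list("hand", "yes", "all_body", 25.234,  4.209,  7.682, 5.293, 11.149),
    list("hand", "yes", "back",     65.421, 31.839,  4.050, 3.013,  5.444),
    list("hand", "yes", "neck",     66.822, 31.153,  4.451, 3.302,  6.000),
    list("neck", "yes", "back",     56.675, 23.414,  4.279, 3.572,  5.125),
    list("neck", "yes", "foot",     23.301,  6.916,  4.089, 3.175,  5.265),
    list("neck", "yes", "stomach",  34.830, 14.975,  3.035, 2.486,  3.704),
    list("back", "yes", "stomach",  33.493, 15.537,  2.738, 2.245,  3.338),
    list("back", "yes", "knee",     40.311, 16.624,  3.387, 2.796,  4.104),
    list("back", "yes", "all_body", 11.842,  3.005,  4.336, 3.030,  6.203),
    list("foot", "yes", "knee",     55.150, 20.534,  4.759, 3.704,  6.114)
  )
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(parent = r[[1L]], parent_level = r[[2L]], child = r[[3L]],
               yes_pct = r[[4L]], no_pct = r[[5L]], or = r[[6L]],
               ci_low = r[[7L]], ci_high = r[[8L]],
               stringsAsFactors = FALSE)
  }))
  df
}

#' Cohort margins of the reference sample
#'
#' @return List with `n` (2400), `gender_split` (proportion female) and
#'   `age_mix` (named proportions young/middle/senior).
#' @export
reference_margins <- function() {
  list(n = 2400L, gender_split = 0.50,
       age_mix = c(young = 0.409, middle = 0.506, senior = 0.085))
}
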