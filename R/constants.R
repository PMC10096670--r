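#' Default p-value threshold grid for multi-threshold polygenic scoring
#'
#' The eleven inclusion thresholds at which component polygenic scores are
#' built before PRS-PCA aggregation.
#'
#' @return Numeric vector of length 11, increasing.
#' @export
default_prs_thresholds <- function() {
  c(5e-8, 1e-7, 1e-6, 1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5, 1)
}

#' Bonferroni-adjusted significance level for the interaction battery
#'
#' Four diet models are fitted in step 2a and four lifestyle models in step
#' 2b; within each step the nominal 0.05 level is divided by the number of
#' models, giving 0.05 / 4 = 0.0125.
#'
#' @return A single number, 0.0125.
#' @export
bonferroni_alpha <- function() 0.05 / 4

#' Generating coefficient sets for the synthetic cohort
#'
#' Named coefficient vectors used as ground truth by
#' [simulate_cohort_table()]. The `"basic"` set holds the polygenic-score
#' main effect and the full covariate block at effect sizes typical of large
#' adult population-cohort analyses of ADHD polygenic risk and impulsivity;
#' the moderator sets add the corresponding main-effect and product terms
#' (diet tertiles, sleep/smoking/alcohol classes, physical-activity
#' quintile score).
#'
#' Term names match the design columns the generator builds: `prs`, raw
#' covariates (`age`, `sex_female`, `bmi`, `neighborhood_ses`, `income`,
#' `edu_middle`, `edu_high`, `occupation`, `disease`, `life_events`,
#' `long_term_difficulties`, `depression`, `anxiety`), moderator dummies
#' (`kcal_q2`, `llds_i_q3`, `sleep_short`, ...) and products
#' (`prs_x_kcal_q3`, ...).
#'
#' @param block One of `"basic"`, `"llds_i"`, `"kcal"`, `"fat"`, `"sugar"`,
#'   `"sleep"`, `"smoking"`, `"alcohol"`, `"mvpa"`, or `"null"` (all zero,
#'   for calibration checks).
#' @return Named numeric vector of generating coefficients.
#' @export
generating_coefficients <- function(block = c("basic", "llds_i", "kcal", "fat",
                                              "sugar", "sleep", "smoking",
                                              "alcohol", "mvpa", "null")) {
  block <- match.arg(block)
  covs <- c(
    age = -0.021, sex_female = 0.036, bmi = 0.03,
    neighborhood_ses = -0.011, edu_middle = -0.086, edu_high = -0.185,
    income = 2.25e-5, occupation = -0.002, disease = -0.016,
    life_events = 0.021, long_term_difficulties = 0.091,
    depression = 0.259, anxiety = 0.156
  )
  switch(block,
    null = c(prs = 0),
    basic = c(prs = 0.03, covs),
    llds_i = c(prs = 0.025, covs,
               llds_i_q2 = 0.058, llds_i_q3 = 0.14,
               prs_x_llds_i_q2 = 0.009, prs_x_llds_i_q3 = 0.005),
    kcal = c(prs = 0.008, covs,
             kcal_q2 = 0.058, kcal_q3 = 0.128,
             prs_x_kcal_q2 = 0.032, prs_x_kcal_q3 = 0.038),
    fat = c(prs = 0.019, covs,
            fat_q2 = 0.065, fat_q3 = 0.145,
            prs_x_fat_q2 = 0.017, prs_x_fat_q3 = 0.016),
    sugar = c(prs = 0.031, covs,
              sugar_q2 = 0.001, prs_x_sugar_q2 = -0.002),
    sleep = c(prs = 0.027, covs,
              sleep_short = 0.078, sleep_long = 0.049,
              prs_x_sleep_short = 0.022, prs_x_sleep_long = 0.011),
    smoking = c(prs = 0.03, covs,
                smoking_current = 0.302, smoking_past = 0.208,
                prs_x_smoking_current = -0.012, prs_x_smoking_past = -0.014),
    alcohol = c(prs = 0.025, covs,
                alcohol_occasional = 0.091, alcohol_light = 0.267,
                alcohol_moderate = 0.435, alcohol_heavy = 0.498,
                prs_x_alcohol_occasional = 0.018, prs_x_alcohol_light = -0.001,
                prs_x_alcohol_moderate = 0.001, prs_x_alcohol_heavy = 0.042),
    mvpa = c(prs = 0.03, covs, mvpaq = 0.019, prs_x_mvpaq = -0.001)
  )
}

#' Schofield basal-metabolic-rate coefficients (weight and height variant)
#'
#' Sex- and age-band linear coefficients predicting BMR in kcal/day from
#' weight in kg and height in metres. Bands are 18-30, 30-60 and 60+ years
#' (lower bound inclusive).
#'
#' @return Data frame with columns `sex`, `age_lo`, `age_hi`, `wt`, `ht`,
#'   `const`.
#' @export
schofield_constants <- function() {
  data.frame(
    sex    = rep(c("male", "female"), each = 3),
    age_lo = rep(c(18, 30, 60), 2),
    age_hi = rep(c(30, 60, Inf), 2),
    wt     = c(15.4, 11.3, 8.8, 13.3, 8.7, 9.2),
    ht     = c(-27, 16, 1128, 334, -25, 637),
    const  = c(717, 901, -1071, 35, 865, -302),
    stringsAsFactors = FALSE
  )
}

#' Food-group polarity map for the diet-quality score
#'
#' Twelve food groups scored from within-sample quintiles of intake in grams
#' per 1000 kcal: nine with established positive health effects scored 0-4
#' and three with negative health effects scored 4-0.
#'
#' @return Named numeric vector, +1 for positive and -1 for negative groups.
#' @export
llds_polarity <- function() {
  c(vegetables = 1, fruits = 1, whole_grains = 1, legumes_nuts = 1,
    fish = 1, oils_soft_margarine = 1, unsweetened_dairy = 1,
    coffee = 1, tea = 1,
    red_processed_meat = -1, butter_hard_margarine = -1,
    sugar_sweetened_beverages = -1)
}
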