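# Derived variables: the impulsivity principal-component outcome, the four
# diet indices with censoring and grouping, and lifestyle classifications.

#' Impulsivity principal-component score from NEO facet sums
#'
#' Takes the four facet sum scores (each the sum of eight 1-5 Likert items,
#' so in \[8, 40\]), inverts deliberateness and self-discipline as 48 - sum
#' (which maps \[8, 40\] onto itself) so that higher always means more
#' impulsive, and extracts the first principal component of the 4 x 4
#' Pearson correlation matrix. The component is oriented so the impulsivity
#' facet loads positively and per-person scores are standardized to mean 0,
#' sd 1 over the estimation sample.
#'
#' @param facets Data frame with integer columns `impulsivity_facet`,
#'   `excitement_seeking`, `deliberateness`, `self_discipline`.
#' @param estimation Optional data frame of the same shape on which loadings
#'   and standardization constants are estimated (e.g. a larger superset);
#'   defaults to `facets` itself.
#' @return List with `score` (numeric, one per row of `facets`), `loadings`
#'   (correlation-scale loadings of the four oriented facets) and
#'   `variance_explained` (fraction of total variance carried by the
#'   component).
#' @export
impulsivity_pc <- function(facets, estimation = facets) {
  need <- c("impulsivity_facet", "excitement_seeking",
            "deliberateness", "self_discipline")
  orient <- function(df) {
    miss <- setdiff(need, names(df))
    if (length(miss) > 0)
      stop("facet columns missing: ", paste(miss, collapse = ", "))
    bad <- sapply(need, function(f) any(df[[f]] < 8 | df[[f]] > 40,
                                        na.rm = TRUE))
    if (any(bad))
      stop("facet sums outside [8, 40]: ", paste(need[bad], collapse = ", "))
    cbind(impulsivity_facet = df$impulsivity_facet,
          excitement_seeking = df$excitement_seeking,
          deliberateness_inv = 48 - df$deliberateness,
          self_discipline_inv = 48 - df$self_discipline)
  }
  M_est <- orient(estimation)
  M_est <- M_est[stats::complete.cases(M_est), , drop = FALSE]
  if (nrow(M_est) < 4) stop("need at least 4 complete observations")
  sds <- apply(M_est, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate correlation: constant facet(s) ",
         paste(colnames(M_est)[sds == 0], collapse = ", "))

  C <- stats::cor(M_est)
  e <- eigen(C, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (v[1] < 0) v <- -v

  mus <- colMeans(M_est)
  proj_est <- scale(M_est, center = mus, scale = sds) %*% v
  p_mu <- mean(proj_est)
  p_sd <- stats::sd(proj_est)

  M <- orient(facets)
  score <- as.numeric((scale(M, center = mus, scale = sds) %*% v - p_mu) / p_sd)
  loadings <- v * sqrt(e$values[1])
  names(loadings) <- colnames(M_est)
  list(score = score, loadings = loadings,
       variance_explained = e$values[1] / ncol(C))
}

#' Basal metabolic rate from the Schofield weight-and-height equations
#'
#' Linear prediction of BMR in kcal/day from weight (kg) and height (m)
#' with sex- and age-band coefficients (bands 18-30, 30-60, 60+; see
#' [schofield_constants()]).
#'
#' @param age Age in years (>= 18; the cohort excludes minors).
#' @param sex `"male"` or `"female"` (vectorized).
#' @param weight Weight in kg.
#' @param height Height in metres.
#' @return BMR in kcal/day.
#' @export
schofield_bmr <- function(age, sex, weight, height) {
  if (any(age < 18)) stop("age < 18 is out of scope: adult cohort only")
  if (any(weight <= 0) || any(height <= 0))
    stop("weight and height must be positive")
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  tab <- schofield_constants()
  out <- numeric(length(age))
  for (i in seq_len(nrow(tab))) {
    sel <- sex == tab$sex[i] & age >= tab$age_lo[i] & age < tab$age_hi[i]
    out[sel] <- tab$wt[i] * weight[sel] + tab$ht[i] * height[sel] +
      tab$const[i]
  }
  out
}

#' Energy-reporting reliability filter
#'
#' A food-frequency record is considered reliable when the reported daily
#' energy is between 0.79 and 2.49 times the Schofield BMR (both boundaries
#' retained; the exclusion rule is strictly below/above).
#'
#' @param energy Reported energy intake, kcal/day (> 0).
#' @param bmr Basal metabolic rate, kcal/day (> 0).
#' @return Logical vector, `TRUE` for reliable records.
#' @export
energy_reliability <- function(energy, bmr) {
  if (any(bmr <= 0)) stop("bmr must be positive")
  if (any(energy <= 0)) stop("invalid record: non-positive energy intake")
  ratio <- energy / bmr
  ratio >= 0.79 & ratio <= 2.49
}

#' Excess-intake ratios for energy, fat and free sugars
#'
#' Energy is scaled by the Schofield BMR; fat and free sugars by the
#' WHO-recommended maxima of 30% and 10% of daily energy. Values below 1
#' (non-excessive intake) are censored to 1, so only excess varies.
#'
#' @param energy Energy intake, kcal/day.
#' @param bmr BMR, kcal/day.
#' @param fat_pct Percent of daily energy from fat, in \[0, 100\].
#' @param sugar_pct Percent of daily energy from free sugars, in \[0, 100\].
#' @return List with numeric vectors `kcal`, `fat`, `sugar`, each >= 1.
#' @export
excess_ratios <- function(energy, bmr, fat_pct, sugar_pct) {
  if (any(bmr <= 0)) stop("bmr must be positive")
  if (any(energy <= 0)) stop("invalid record: non-positive energy intake")
  if (any(fat_pct < 0 | fat_pct > 100) || any(sugar_pct < 0 | sugar_pct > 100))
    stop("invalid record: percentage of energy outside [0, 100]")
  list(kcal = pmax(1, energy / bmr),
       fat = pmax(1, fat_pct / 30),
       sugar = pmax(1, sugar_pct / 10))
}

.quintile_score <- function(x) {
  n <- length(x)
  p <- rank(x, ties.method = "average") / n
  # boundary values (p exactly at a cut) fall in the lower bin
  (p > 0.2) + (p > 0.4) + (p > 0.6) + (p > 0.8)
}

#' Diet-quality score from 12 food-group intakes
#'
#' Each food group (intake in g/1000 kcal) is scored by its within-sample
#' quintile: 0-4 points for the nine groups with positive health effects and
#' 4-0 (reversed) for the three with negative effects. The score `llds` is
#' the sum over the 12 groups (range 0-48, higher = healthier); `llds_i` is
#' its inversion 48 - llds (higher = poorer diet). Ties are handled by
#' average ranks with boundary values assigned to the lower quintile, so a
#' fully tied group scores 2 for everyone.
#'
#' @param groups Data frame holding at least the 12 columns named in
#'   [llds_polarity()].
#' @param polarity Named polarity map (+1 healthy, -1 unhealthy).
#' @return List with integer vectors `llds` and `llds_i`.
#' @export
llds <- function(groups, polarity = llds_polarity()) {
  miss <- setdiff(names(polarity), names(groups))
  if (length(miss) > 0)
    stop("schema error: food-group columns missing: ",
         paste(miss, collapse = ", "))
  if (nrow(groups) < 5)
    stop("need at least 5 records to define quintiles")
  total <- rep(0, nrow(groups))
  for (gname in names(polarity)) {
    sc <- .quintile_score(groups[[gname]])
    if (polarity[[gname]] < 0) sc <- 4 - sc
    total <- total + sc
  }
  list(llds = as.integer(total), llds_i = as.integer(48 - total))
}

#' Empirical tertile grouping
#'
#' Cuts at the empirical 1/3 and 2/3 quantiles (order-statistic quantiles,
#' so with distinct values the classes have sizes equal to within one
#' person); values equal to a cut-point go to the lower tertile, matching
#' half-open printed ranges such as "Q3: KCAL > 1.41".
#'
#' @param values Numeric vector with at least 3 distinct values.
#' @return Factor with levels `Q1`, `Q2`, `Q3`.
#' @export
tertile_groups <- function(values) {
  if (length(unique(values)) < 3)
    stop("need at least 3 distinct values for tertiles")
  q <- stats::quantile(values, c(1 / 3, 2 / 3), type = 1, names = FALSE)
  lab <- ifelse(values <= q[1], "Q1", ifelse(values <= q[2], "Q2", "Q3"))
  out <- factor(lab, levels = c("Q1", "Q2", "Q3"))
  shares <- table(out) / length(out)
  if (any(abs(shares - 1 / 3) > 0.1))
    message("tertile imbalance (mass point at a cut): shares ",
            paste(sprintf("%.2f", shares), collapse = "/"))
  out
}

#' Binary grouping for the free-sugar ratio
#'
#' More than a third of participants report non-excessive sugar intake
#' (ratio censored at 1), so the sugar ratio is grouped as Q1 (exactly 1)
#' versus Q2 (> 1) rather than tertiles.
#'
#' @param sugar Censored sugar ratio (>= 1).
#' @return Factor with levels `Q1`, `Q2`.
#' @export
binary_sugar <- function(sugar) {
  if (any(sugar < 1)) stop("sugar ratio below 1; apply excess_ratios first")
  factor(ifelse(sugar == 1, "Q1", "Q2"), levels = c("Q1", "Q2"))
}

#' Semi-continuous quintile score for physical activity
#'
#' Moderate-to-vigorous physical activity in minutes per week is strongly
#' right-skewed and is rescaled to fixed bands: \[0, 60) -> 1,
#' \[60, 150) -> 2, \[150, 255) -> 3, \[255, 420\] -> 4, (420, Inf) -> 5.
#' The 255-minute boundary between bands 3 and 4 resolves a typographical
#' overlap in the published band listing (see the methods vignette).
#'
#' @param minutes Minutes per week (>= 0).
#' @return Integer score 1-5.
#' @export
mvpa_quintile <- function(minutes) {
  if (any(minutes < 0)) stop("invalid record: negative MVPA minutes")
  ifelse(minutes < 60, 1L,
         ifelse(minutes < 150, 2L,
                ifelse(minutes < 255, 3L,
                       ifelse(minutes <= 420, 4L, 5L))))
}

#' Sleep-duration classification by residual deciles
#'
#' Sleep duration changes with age in a sex-dependent way, so short and long
#' sleep are defined relative to expectation: residuals from a least-squares
#' regression of hours on age and sex are ranked, the lowest decile is
#' labelled `short`, the highest `long`, and the rest `normal`. A
#' sample-level operation: the whole cohort is needed to regress and rank.
#'
#' @param hours Sleep duration in hours.
#' @param age Age in years.
#' @param sex `"male"`/`"female"`.
#' @return Factor with levels `normal`, `short`, `long`.
#' @export
sleep_class <- function(hours, age, sex) {
  n <- length(hours)
  if (n < 20) stop("deciles undefined: need at least 20 observations")
  # degenerate designs (constant age or single-sex sample) drop the term
  rhs <- c(if (length(unique(age)) > 1) "age",
           if (length(unique(sex)) > 1) "factor(sex)")
  f <- if (length(rhs) == 0) hours ~ 1 else
    stats::as.formula(paste("hours ~", paste(rhs, collapse = " + ")))
  res <- stats::resid(stats::lm(f, data = data.frame(hours = hours,
                                                     age = age, sex = sex)))
  r <- rank(res, ties.method = "first")
  k <- round(0.1 * n)
  lab <- rep("normal", n)
  lab[r <= k] <- "short"
  lab[r > n - k] <- "long"
  factor(lab, levels = c("normal", "short", "long"))
}

#' Alcohol intake classification
#'
#' Grams of alcohol per day mapped to contiguous half-open bands:
#' 0 -> abstinent, (0, 2.5) -> occasional, \[2.5, 15) -> light,
#' \[15, 30) -> moderate, \[30, Inf) -> heavy. The published band labels
#' print one decimal ("15-29.9"); the half-open bins cover the gaps they
#' leave (see the methods vignette).
#'
#' @param grams_per_day Alcohol in g/day (>= 0).
#' @return Factor with levels `abstinent`, `occasional`, `light`,
#'   `moderate`, `heavy`.
#' @export
alcohol_class <- function(grams_per_day) {
  if (any(grams_per_day < 0)) stop("invalid record: negative alcohol intake")
  lab <- ifelse(grams_per_day == 0, "abstinent",
                ifelse(grams_per_day < 2.5, "occasional",
                       ifelse(grams_per_day < 15, "light",
                              ifelse(grams_per_day < 30, "moderate",
                                     "heavy"))))
  factor(lab, levels = c("abstinent", "occasional", "light", "moderate",
                         "heavy"))
}

#' Smoking status classification
#'
#' `current` if smoked within the month before assessment, otherwise `past`
#' if ever smoked for a year or longer, otherwise `never`. Current takes
#' precedence over past.
#'
#' @param current Logical: smoked within the last month.
#' @param ever_ge_1yr Logical: ever smoked for >= 1 year.
#' @return Factor with levels `never`, `past`, `current`.
#' @export
smoking_class <- function(current, ever_ge_1yr) {
  lab <- ifelse(current, "current", ifelse(ever_ge_1yr, "past", "never"))
  factor(lab, levels = c("never", "past", "current"))
}
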