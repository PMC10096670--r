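# The staged interaction-regression battery: step-1 basic model, step-2a
# diet and step-2b lifestyle interaction models, the two-step
# variance-explained procedure, SES-interaction sensitivity models, and a
# simple covariate imputer.

#' Covariate set of the basic model
#'
#' Age, sex, BMI, the four socioeconomic indices (neighborhood SES,
#' disposable household income, educational attainment, occupational
#' status), lifetime non-communicable disease, current depression and
#' anxiety, and past-year stressful life events and long-term difficulties.
#'
#' @return Character vector of cohort column names.
#' @export
model_covariates <- function() {
  c("age", "sex", "bmi", "neighborhood_ses", "income", "education",
    "occupation", "disease", "life_events", "long_term_difficulties",
    "depression", "anxiety")
}

#' Valid step-2 moderators
#'
#' @return Named character vector mapping moderator keys to cohort columns.
#' @export
step2_moderators <- function() {
  c(llds_i = "llds_i_tertile", kcal = "kcal_tertile", fat = "fat_tertile",
    sugar = "sugar_group", sleep = "sleep_class", smoking = "smoking",
    alcohol = "alcohol_class", mvpa = "mvpaq")
}

.genetic_controls_formula <- function() {
  "chip * (pc1 + pc2 + pc3 + pc4)"
}

.build_formula <- function(outcome, focal, covariates, genetic = TRUE,
                           extra = NULL) {
  rhs <- c(focal, covariates,
           if (genetic) .genetic_controls_formula(), extra)
  stats::as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
}

.fit_ols <- function(formula, data, alpha = bonferroni_alpha()) {
  vars <- all.vars(formula)
  miss <- setdiff(vars, names(data))
  if (length(miss) > 0)
    stop("column(s) missing from data: ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars,
            drop = FALSE]
  fit <- stats::lm(formula, data = d)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  if (nrow(d) <= length(cf))
    stop("fewer observations than parameters")
  sm <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  X <- stats::model.matrix(fit)
  sdy <- stats::sd(d[[all.vars(formula)[1]]])
  est <- sm$coefficients
  terms <- data.frame(
    term = rownames(est),
    B = est[, "Estimate"],
    ci_low = ci[, 1],
    ci_high = ci[, 2],
    p = est[, "Pr(>|t|)"],
    beta = est[, "Estimate"] * apply(X, 2, stats::sd) / sdy,
    stringsAsFactors = FALSE
  )
  terms$beta[terms$term == "(Intercept)"] <- NA_real_
  terms$significant <- terms$p < alpha
  rownames(terms) <- NULL
  structure(list(terms = terms, n_used = nrow(d),
                 adj_r2 = sm$adj.r.squared, formula = formula,
                 alpha = alpha),
            class = "gxe_fit")
}

#' @export
print.gxe_fit <- function(x, ...) {
  cat("Linear model:", deparse(x$formula), "\n")
  cat("n =", x$n_used, "  adjusted R^2 =", signif(x$adj_r2, 4),
      "  significance level =", x$alpha, "\n\n")
  tt <- x$terms
  tt$B <- signif(tt$B, 4)
  tt$ci_low <- signif(tt$ci_low, 4)
  tt$ci_high <- signif(tt$ci_high, 4)
  tt$p <- signif(tt$p, 3)
  tt$beta <- signif(tt$beta, 3)
  print(tt, row.names = FALSE)
  invisible(x)
}

#' Step-1 basic model
#'
#' Ordinary least squares of the impulsivity score on the polygenic score
#' plus the full covariate block, with genetic controls (genotyping chip,
#' four genetic principal components and chip-by-component interactions).
#' Per term the unstandardized coefficient B, its 95% confidence interval
#' from the t distribution, the two-sided p-value, and the standardized
#' coefficient beta = B * sd(x) / sd(y) (computed on the analysis sample,
#' also for dummy columns) are reported. Complete cases on the model
#' variables are used.
#'
#' @param data Cohort data frame (see [simulate_cohort_table()] for the
#'   column dictionary).
#' @param outcome,focal Outcome and focal predictor column names.
#' @param covariates Covariate columns (default [model_covariates()]).
#' @param genetic Include the genetic-control block.
#' @param alpha Significance level for the `significant` flag (default
#'   [bonferroni_alpha()]).
#' @return An object of class `gxe_fit`: list with `terms` (data frame:
#'   `term`, `B`, `ci_low`, `ci_high`, `p`, `beta`, `significant`),
#'   `n_used`, `adj_r2`, `formula`, `alpha`.
#' @export
fit_linear <- function(data, outcome = "impulsivity", focal = "prs",
                       covariates = model_covariates(), genetic = TRUE,
                       alpha = bonferroni_alpha()) {
  .fit_ols(.build_formula(outcome, focal, covariates, genetic), data,
           alpha = alpha)
}

#' Step-2 interaction model for one moderator
#'
#' Adds one diet indicator (step 2a: diet-quality tertile, energy tertile,
#' fat tertile, binary sugar group) or lifestyle predictor (step 2b: sleep
#' class, smoking status, alcohol class, physical-activity quintile score)
#' and its interaction with the polygenic score to the basic model.
#' Categorical moderators enter as dummies against their stated reference
#' level (lowest tertile / Q1 / normal sleep / never smoked / abstinent);
#' the physical-activity score enters as a single semi-continuous term with
#' one product term.
#'
#' @param data Cohort data frame.
#' @param moderator One of `names(step2_moderators())`.
#' @inheritParams fit_linear
#' @return A `gxe_fit`.
#' @export
fit_step2 <- function(data, moderator, outcome = "impulsivity",
                      focal = "prs", covariates = model_covariates(),
                      genetic = TRUE, alpha = bonferroni_alpha()) {
  mods <- step2_moderators()
  if (!moderator %in% names(mods))
    stop("unknown moderator '", moderator, "'; valid: ",
         paste(names(mods), collapse = ", "))
  modcol <- mods[[moderator]]
  .fit_ols(.build_formula(outcome, paste(focal, "*", modcol), covariates,
                          genetic), data, alpha = alpha)
}

#' Two-step variance explained by the polygenic score
#'
#' Step 1 regresses impulsivity on age, sex, genotyping chip, the four
#' genetic principal components and chip-by-component interactions and
#' keeps the residuals; step 2 regresses those residuals on the polygenic
#' score. The adjusted R^2 of the second model, times 100, estimates the
#' percentage of impulsivity variance explained by the score (it can be
#' slightly negative under the null and is reported as computed).
#'
#' @param data Cohort data frame.
#' @param outcome,prs Column names.
#' @return List with `variance_explained_pct` and `p` (slope p-value).
#' @export
two_step_r2 <- function(data, outcome = "impulsivity", prs = "prs") {
  f1 <- .build_formula(outcome, NULL, c("age", "sex"), genetic = TRUE)
  vars <- unique(c(all.vars(f1), prs))
  miss <- setdiff(vars, names(data))
  if (length(miss) > 0)
    stop("column(s) missing from data: ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars,
            drop = FALSE]
  r <- stats::resid(stats::lm(f1, data = d))
  fit2 <- stats::lm(r ~ d[[prs]])
  sm <- summary(fit2)
  list(variance_explained_pct = 100 * sm$adj.r.squared,
       p = sm$coefficients[2, "Pr(>|t|)"])
}

#' SES-interaction sensitivity model
#'
#' Augments a step-2 model with products of the moderator and all four
#' socioeconomic indices, to test whether moderator-by-SES interactions
#' inflated the polygenic-score-by-moderator interaction. Reports the
#' adjusted and unadjusted fits and the attenuation (change in each
#' score-by-moderator coefficient relative to the plain step-2 fit).
#'
#' @param data Cohort data frame.
#' @param moderator One of `names(step2_moderators())`.
#' @inheritParams fit_linear
#' @return List with `adjusted` and `unadjusted` (`gxe_fit`s) and
#'   `attenuation` (data frame: `term`, `B_unadjusted`, `B_adjusted`,
#'   `change`).
#' @export
sensitivity_ses <- function(data, moderator, outcome = "impulsivity",
                            focal = "prs", covariates = model_covariates(),
                            alpha = bonferroni_alpha()) {
  mods <- step2_moderators()
  if (!moderator %in% names(mods))
    stop("unknown moderator '", moderator, "'; valid: ",
         paste(names(mods), collapse = ", "))
  modcol <- mods[[moderator]]
  plain <- fit_step2(data, moderator, outcome = outcome, focal = focal,
                     covariates = covariates, alpha = alpha)
  ses <- c("neighborhood_ses", "income", "education", "occupation")
  extra <- paste0(modcol, ":", ses)
  adj <- .fit_ols(.build_formula(outcome, paste(focal, "*", modcol),
                                 covariates, genetic = TRUE, extra = extra),
                  data, alpha = alpha)
  is_int <- function(tt) grepl(paste0("^", focal, ":"), tt$term) |
    grepl(paste0(":", focal, "$"), tt$term)
  tu <- plain$terms[is_int(plain$terms), c("term", "B")]
  ta <- adj$terms[is_int(adj$terms), c("term", "B")]
  att <- merge(tu, ta, by = "term", suffixes = c("_unadjusted", "_adjusted"))
  att$change <- att$B_adjusted - att$B_unadjusted
  list(adjusted = adj, unadjusted = plain, attenuation = att)
}

.mode_value <- function(x) {
  tb <- table(x)
  names(tb)[which.max(tb)]
}

#' Median/mode imputation of covariates
#'
#' A deliberately simple plumbing imputer: continuous covariates get the
#' column median, categorical covariates the most frequent level.
#' Missingness in the outcome or the polygenic score is an error - those
#' are never imputed. An imputation report is attached as attribute
#' `"imputation_report"`.
#'
#' @param data Cohort data frame.
#' @param columns Covariate columns to impute (default
#'   [model_covariates()]).
#' @param protected Columns that must be complete.
#' @return `data` with imputed covariates.
#' @export
simple_impute <- function(data, columns = model_covariates(),
                          protected = c("impulsivity", "prs")) {
  protected <- intersect(protected, names(data))
  bad <- protected[sapply(protected, function(cn) anyNA(data[[cn]]))]
  if (length(bad) > 0)
    stop("missing values in protected column(s): ",
         paste(bad, collapse = ", "), "; outcome and polygenic score are ",
         "never imputed")
  columns <- intersect(columns, names(data))
  report <- data.frame(column = character(0), n_imputed = integer(0),
                       value = character(0))
  for (cn in columns) {
    x <- data[[cn]]
    nas <- is.na(x)
    if (!any(nas)) next
    if (is.numeric(x)) {
      v <- stats::median(x, na.rm = TRUE)
      data[[cn]][nas] <- v
    } else {
      v <- .mode_value(x[!nas])
      data[[cn]][nas] <- v
    }
    report <- rbind(report, data.frame(column = cn, n_imputed = sum(nas),
                                       value = as.character(v)))
  }
  attr(data, "imputation_report") <- report
  data
}

#' Write model results as CSV and text tables
#'
#' One CSV per model plus a combined text report with significance stars at
#' the Bonferroni level.
#'
#' @param results Named list of `gxe_fit` objects.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
report_tables <- function(results, dir) {
  stopifnot(length(results) >= 1)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(names(results)) || any(!nzchar(names(results))))
    names(results) <- paste0("model_", seq_along(results))
  paths <- character(0)
  txt <- character(0)
  for (nm in names(results)) {
    r <- results[[nm]]
    stopifnot(inherits(r, "gxe_fit"))
    path <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(r$terms, path, row.names = FALSE)
    paths <- c(paths, path)
    tt <- r$terms
    star <- ifelse(tt$significant, " *", "")
    txt <- c(txt,
             sprintf("== %s (n = %d, adj R2 = %.4f) ==", nm, r$n_used,
                     r$adj_r2),
             sprintf("%-40s %9.4g (%9.4g, %9.4g)  p=%-10.3g beta=%8.3g%s",
                     tt$term, tt$B, tt$ci_low, tt$ci_high, tt$p, tt$beta,
                     star),
             "")
  }
  report_path <- file.path(dir, "model_report.txt")
  writeLines(txt, report_path)
  invisible(c(paths, report_path))
}
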