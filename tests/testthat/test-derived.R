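test_that("perfectly correlated facets give a rank-1 component", {
  set.seed(30)
  base <- sample(10:38, 200, replace = TRUE)
  facets <- data.frame(impulsivity_facet = base,
                       excitement_seeking = base,
                       deliberateness = 48 - base,   # stored un-inverted
                       self_discipline = 48 - base)
  out <- impulsivity_pc(facets)
  expect_equal(out$variance_explained, 1, tolerance = 1e-12)
  expect_equal(max(out$loadings) - min(out$loadings), 0, tolerance = 1e-10)
  expect_gt(out$loadings[["impulsivity_facet"]], 0)
  expect_equal(mean(out$score), 0, tolerance = 1e-12)
  expect_equal(sd(out$score), 1, tolerance = 1e-12)
  expect_gt(cor(out$score, base), 0.999)
})

test_that("loading pattern reproduces the published ordering qualitatively", {
  set.seed(31)
  n <- 20000
  y <- rnorm(n)
  r <- c(impulsivity_facet = 0.81, excitement_seeking = 0.37,
         deliberateness = 0.82, self_discipline = 0.68)
  gen <- function(f) {
    o <- 24 + 5 * (r[[f]] * y + sqrt(1 - r[[f]]^2) * rnorm(n))
    pmin(40, pmax(8, round(o)))
  }
  facets <- data.frame(impulsivity_facet = gen("impulsivity_facet"),
                       excitement_seeking = gen("excitement_seeking"),
                       deliberateness = 48 - gen("deliberateness"),
                       self_discipline = 48 - gen("self_discipline"))
  out <- impulsivity_pc(facets)
  l <- out$loadings
  # deliberateness (inverted) and impulsivity load highest, then
  # self-discipline (inverted), excitement-seeking weakest
  top2 <- names(sort(l, decreasing = TRUE))[1:2]
  expect_setequal(top2, c("deliberateness_inv", "impulsivity_facet"))
  expect_gt(l[["self_discipline_inv"]], l[["excitement_seeking"]])
  expect_true(all(l > 0))
})

test_that("component projection equals an independent eigen oracle", {
  for (i in 1:10) {
    set.seed(40 + i)
    n <- 50 + i * 10
    lat <- rnorm(n)
    facets <- data.frame(
      impulsivity_facet = pmin(40, pmax(8, round(24 + 4 * lat + rnorm(n)))),
      excitement_seeking = pmin(40, pmax(8, round(24 + 2 * lat + 2 * rnorm(n)))),
      deliberateness = pmin(40, pmax(8, round(24 - 3 * lat + rnorm(n)))),
      self_discipline = pmin(40, pmax(8, round(24 - 2 * lat + 2 * rnorm(n))))
    )
    out <- impulsivity_pc(facets)
    M <- cbind(facets$impulsivity_facet, facets$excitement_seeking,
               48 - facets$deliberateness, 48 - facets$self_discipline)
    e <- eigen(cor(M), symmetric = TRUE)
    v <- e$vectors[, 1]
    if (v[1] < 0) v <- -v
    oracle <- as.numeric(scale(scale(M) %*% v))
    expect_equal(out$score, oracle, tolerance = 1e-10)
  }
})

test_that("the component is invariant to shifting one facet by a constant", {
  set.seed(45)
  n <- 300
  lat <- rnorm(n)
  clamp_mid <- function(x) pmin(35, pmax(12, round(x)))  # room to shift
  facets <- data.frame(
    impulsivity_facet = clamp_mid(24 + 3 * lat + rnorm(n)),
    excitement_seeking = clamp_mid(24 + 1.5 * lat + 2 * rnorm(n)),
    deliberateness = clamp_mid(24 - 3 * lat + rnorm(n)),
    self_discipline = clamp_mid(24 - 2 * lat + 2 * rnorm(n))
  )
  base <- impulsivity_pc(facets)
  shifted <- facets
  shifted$excitement_seeking <- shifted$excitement_seeking + 3
  out <- impulsivity_pc(shifted)
  expect_equal(out$score, base$score, tolerance = 1e-10)
})

test_that("degenerate facet input is rejected", {
  facets <- data.frame(impulsivity_facet = rep(20, 10),
                       excitement_seeking = 10:19,
                       deliberateness = 10:19,
                       self_discipline = 19:10)
  expect_error(impulsivity_pc(facets), "degenerate|constant")
  expect_error(impulsivity_pc(facets[1:2, ]), "at least 4")
})

test_that("Schofield BMR arithmetic matches the coefficient table", {
  # male, 25 y, 70 kg, 1.75 m: 15.4*70 - 27*1.75 + 717
  expect_equal(schofield_bmr(25, "male", 70, 1.75),
               15.4 * 70 - 27 * 1.75 + 717)
  # female, 45 y, 60 kg, 1.65 m: 8.7*60 - 25*1.65 + 865
  expect_equal(schofield_bmr(45, "female", 60, 1.65),
               8.7 * 60 - 25 * 1.65 + 865)
  # strictly increasing in weight in every band
  for (sex in c("male", "female")) {
    for (age in c(20, 45, 70)) {
      b <- schofield_bmr(rep(age, 3), rep(sex, 3), c(50, 70, 90),
                         rep(1.7, 3))
      expect_true(all(diff(b) > 0))
    }
  }
  # doubling weight doubles the weight term exactly
  d1 <- schofield_bmr(25, "male", 60, 1.75) - schofield_bmr(25, "male", 30, 1.75)
  expect_equal(d1, 15.4 * 30)
  expect_error(schofield_bmr(17, "male", 70, 1.75), "out of scope")
})

test_that("energy reliability keeps boundaries and drops extremes", {
  expect_true(energy_reliability(0.79 * 1600, 1600))
  expect_true(energy_reliability(2.49 * 1600, 1600))
  expect_false(energy_reliability(2.50 * 1600, 1600))
  expect_false(energy_reliability(0.78 * 1600, 1600))
  ratios <- c(0.5, 0.79, 1.0, 1.2, 1.5, 2.0, 2.49, 2.6, 3.0, 1.1)
  keep <- energy_reliability(ratios * 1500, rep(1500, 10))
  expect_equal(sum(keep), 7)
  expect_error(energy_reliability(0, 1500), "invalid record")
})

test_that("excess ratios floor at 1 and scale by the recommended maxima", {
  ex <- excess_ratios(energy = c(2000, 1500), bmr = c(1418, 1500),
                      fat_pct = c(30, 45), sugar_pct = c(5, 20))
  expect_equal(ex$fat[1], 1)        # exactly at the 30% maximum
  expect_equal(ex$sugar[1], 1)      # 5% is below the 10% maximum: floored
  expect_equal(ex$fat[2], 1.5)
  expect_equal(ex$sugar[2], 2)
  ex2 <- excess_ratios(1.41 * 1600, 1600, 35, 12)
  expect_equal(ex2$kcal, 1.41)
  set.seed(50)
  exr <- excess_ratios(runif(200, 1000, 4000), runif(200, 1200, 2000),
                       runif(200, 10, 60), runif(200, 0, 40))
  expect_true(all(exr$kcal >= 1 & exr$fat >= 1 & exr$sugar >= 1))
  expect_error(excess_ratios(2000, 1500, 120, 5), "invalid record")
})

test_that("diet-score extremes and ties behave as specified", {
  set.seed(51)
  pol <- llds_polarity()
  n <- 20
  groups <- as.data.frame(sapply(names(pol), function(g) runif(n, 10, 100)))
  # person 1: best on everything
  for (g in names(pol)) {
    groups[[g]][1] <- if (pol[[g]] > 0) 1000 else 0.001
  }
  out <- llds(groups)
  expect_equal(out$llds[1], 48)
  expect_equal(out$llds_i[1], 0)
  expect_true(all(out$llds + out$llds_i == 48))
  # fully tied sample: every group scores the tie default, same for all
  tied <- as.data.frame(sapply(names(pol), function(g) rep(5, 10)))
  out2 <- llds(tied)
  expect_equal(length(unique(out2$llds)), 1)
  expect_equal(out2$llds[1], 24)  # score 2 per group
})

test_that("quintile scores match hand-ranked values on a 10-person table", {
  pol <- llds_polarity()
  groups <- as.data.frame(sapply(names(pol), function(g) as.numeric(1:10)))
  out <- llds(groups)
  # values 1..10: quintile score 0,0,1,1,2,2,3,3,4,4 per positive group,
  # reversed 4,4,3,3,2,2,1,1,0,0 per negative group
  pos_score <- c(0, 0, 1, 1, 2, 2, 3, 3, 4, 4)
  expected <- 9 * pos_score + 3 * (4 - pos_score)
  expect_equal(out$llds, as.integer(expected))
  expect_error(llds(groups[, 1:5]), "schema error")
})

test_that("raising a healthy intake never lowers the diet score", {
  set.seed(52)
  pol <- llds_polarity()
  groups <- as.data.frame(sapply(names(pol), function(g) runif(30, 10, 100)))
  base <- llds(groups)$llds
  up <- groups
  up$vegetables[7] <- up$vegetables[7] * 3
  expect_gte(llds(up)$llds[7], base[7])
  dn <- groups
  dn$red_processed_meat[7] <- dn$red_processed_meat[7] * 3
  expect_lte(llds(dn)$llds[7], base[7])
})

test_that("tertile grouping splits evenly and respects boundaries", {
  g <- tertile_groups(as.numeric(1:9))
  expect_equal(as.vector(table(g)), c(3, 3, 3))
  # boundary value goes to the lower tertile
  expect_equal(as.character(g[3]), "Q1")
  expect_equal(as.character(g[4]), "Q2")
  expect_error(tertile_groups(c(1, 1, 1)), "distinct")
  # near-even split on continuous data
  set.seed(53)
  x <- rnorm(1000)
  tab <- table(tertile_groups(x))
  expect_true(max(abs(tab - 1000 / 3)) <= 1)
})

test_that("energy-ratio tertile cuts land near the published boundaries", {
  set.seed(54)
  kcal <- pmax(1, exp(rnorm(20000, log(1.28), 0.24)))
  g <- tertile_groups(kcal)
  cut12 <- max(kcal[g == "Q1"])
  cut23 <- max(kcal[g == "Q2"])
  expect_lt(abs(cut12 - 1.14), 0.04)
  expect_lt(abs(cut23 - 1.41), 0.04)
})

test_that("binary sugar grouping puts exactly-1 in Q1", {
  g <- binary_sugar(c(1, 1.2, 1, 3))
  expect_equal(as.character(g), c("Q1", "Q2", "Q1", "Q2"))
  expect_error(binary_sugar(c(0.9, 1.2)), "below 1")
})

test_that("physical-activity bands follow the fixed cut-points", {
  expect_equal(mvpa_quintile(c(0, 59, 60, 149, 150, 200, 254, 255, 420,
                               421, 1e6)),
               c(1L, 1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 5L, 5L))
  expect_error(mvpa_quintile(-5), "negative")
})

test_that("sleep classes are residual deciles partitioning 10/80/10", {
  set.seed(55)
  n <- 10000
  age <- runif(n, 18, 80)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  hours <- 7.3 + 0.3 * (sex == "female") - 0.01 * age + rnorm(n, 0, 0.8)
  cls <- sleep_class(hours, age, sex)
  shares <- as.vector(table(cls)) / n
  expect_equal(shares[2], 0.10, tolerance = 0.005)  # short
  expect_equal(shares[3], 0.10, tolerance = 0.005)  # long
  expect_equal(sum(shares), 1)

  # with no age/sex signal the classes reduce to raw-hours deciles
  hours0 <- rnorm(200, 7.5, 1)
  cls0 <- sleep_class(hours0, rep(40, 200), rep("male", 200))
  r <- rank(hours0, ties.method = "first")
  expect_true(all(cls0[r <= 20] == "short"))
  expect_true(all(cls0[r > 180] == "long"))

  # age-dependent sleep: residual ranking, not raw ranking
  age2 <- rep(c(20, 70), each = 50)
  hours2 <- 9 - 0.04 * age2 + rnorm(100, 0, 0.1)
  cls2 <- sleep_class(hours2, age2, rep("female", 100))
  res <- resid(lm(hours2 ~ age2))
  rr <- rank(res, ties.method = "first")
  expect_true(all(cls2[rr <= 10] == "short"))
  expect_true(all(cls2[rr > 90] == "long"))
  # raw deciles would put almost all old subjects in "short"; residual
  # classes must include both age groups
  expect_true(all(table(cls2, age2)["short", ] > 0))
  expect_error(sleep_class(rnorm(10), rnorm(10), rep("male", 10)),
               "at least 20")
})

test_that("alcohol and smoking classifications follow the band definitions", {
  expect_equal(as.character(alcohol_class(c(0, 1, 2.49, 2.5, 7.96, 14.9,
                                            15, 29.9, 30, 45))),
               c("abstinent", "occasional", "occasional", "light", "light",
                 "light", "moderate", "moderate", "heavy", "heavy"))
  expect_error(alcohol_class(-1), "negative")
  expect_equal(as.character(smoking_class(c(TRUE, FALSE, FALSE, TRUE),
                                          c(TRUE, TRUE, FALSE, FALSE))),
               c("current", "past", "never", "current"))
})
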