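make_cohort <- function(n = 200, seed = 1) {
  set.seed(seed)
  freq <- sample(0:4, n, replace = TRUE, prob = c(0.6, 0.2, 0.1, 0.06, 0.04))
  data.frame(
    cannabis_ever = as.integer(freq > 0),
    cannabis_freq = freq,
    y = rbinom(n, 1, 0.3),
    age = rnorm(n),
    income = rnorm(n),
    edu = factor(sample(c("low", "mid", "high"), n, replace = TRUE,
                        prob = c(0.2, 0.5, 0.3)))
  )
}

test_that("design construction counts columns per coding and covariate type", {
  co <- make_cohort()
  d <- build_design(co, exposure_coding("ever_binary"), c("age", "income"))
  expect_equal(ncol(d$X), 4)  # intercept + exposure + 2 continuous
  d2 <- build_design(co, exposure_coding("ever_binary"), "edu")
  expect_equal(ncol(d2$X), 4)  # 3-level categorical -> 2 indicators
  # reference is the most frequent level ("mid")
  expect_setequal(setdiff(colnames(d2$X), c("(Intercept)", "cannabis_ever")),
                  c("edu_low", "edu_high"))
  d3 <- build_design(co, exposure_coding("category_indicators"))
  expect_equal(d3$exposure_cols,
               c("freq_ever", "freq_monthly", "freq_weekly", "freq_daily"))
  expect_equal(ncol(d3$X), 5)
})

test_that("listwise deletion masks rows and accounts exactly", {
  co <- make_cohort()
  co$age[1:7] <- NA
  co$y[8:10] <- NA
  d <- build_design(co, exposure_coding("ever_binary"), "age", outcome = "y")
  expect_equal(sum(d$mask), nrow(co) - 10)
  expect_equal(nrow(d$X), length(d$y))
  expect_equal(sum(d$mask) + sum(!d$mask), nrow(co))
  co2 <- make_cohort()
  co2$cannabis_ever <- NA
  expect_error(build_design(co2, exposure_coding("ever_binary")),
               class = "prsinteract_param_error")
})

test_that("single-level covariates are dropped with a warning", {
  co <- make_cohort()
  co$site <- factor("A")
  expect_warning(d <- build_design(co, exposure_coding("ever_binary"), "site"),
                 "single level")
  expect_equal(ncol(d$X), 2)
})

test_that("intercept-only fit recovers the closed-form logit", {
  y <- rep(c(1, 0), c(25, 75))
  f <- fit_logistic(matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)")), y)
  expect_equal(unname(f$coefficients[1]), stats::qlogis(0.25), tolerance = 1e-8)
  expect_true(f$converged)
})

test_that("2x2 fits match the cross-product closed form", {
  # exposed 30/100 cases, unexposed 10/100
  y <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  x <- rep(c(1, 0), c(100, 100))
  X <- cbind(`(Intercept)` = 1, exposure = x)
  f <- fit_logistic(X, y)
  expect_equal(unname(f$coefficients["exposure"]),
               crossprod_logor(30, 70, 10, 90), tolerance = 1e-6)
  expect_equal(exp(unname(f$coefficients["exposure"])), 3.857, tolerance = 1e-3)
})

test_that("biobank-scale never/ever prevalences give the expected crude OR", {
  # 87,010 never-users at 4.1% vs 22,298 ever-users at 7.0%: crude OR ~ 1.76
  a <- round(22298 * 0.070); b <- 22298 - a
  c <- round(87010 * 0.041); d <- 87010 - c
  or <- exp(crossprod_logor(a, b, c, d))
  expect_equal(or, 1.76, tolerance = 0.01)
})

test_that("separation is flagged rather than silently reported", {
  y <- rep(c(0, 1), each = 20)
  X <- cbind(`(Intercept)` = 1, x = y)  # perfect separation
  f <- fit_logistic(X, y)
  expect_true(f$separation)
  expect_false(f$converged)
})

test_that("AOR estimates exponentiate with 95% Wald intervals", {
  f <- structure(list(coefficients = c(term = 0), se = c(term = 0.1)),
                 class = "logistic_fit")
  a <- estimate_aor(f, "term")
  expect_equal(a$aor, 1)
  expect_equal(a$ci_low, exp(-0.196), tolerance = 1e-10)
  expect_equal(a$ci_high, exp(0.196), tolerance = 1e-10)
  expect_equal(a$p, 1)
  # printed-table round trip: AOR 1.20 with SE back-solved from CI [1.16, 1.24]
  se <- (log(1.24) - log(1.16)) / (2 * 1.96)
  f2 <- structure(list(coefficients = c(x = log(1.20)), se = c(x = se)),
                  class = "logistic_fit")
  a2 <- estimate_aor(f2, "x")
  expect_equal(round(a2$ci_low, 2), 1.16)
  expect_equal(round(a2$ci_high, 2), 1.24)
  expect_error(estimate_aor(f2, "absent"), class = "prsinteract_param_error")
  # CI width is monotone in the SE
  widths <- sapply(c(0.05, 0.1, 0.2), function(s) {
    fi <- structure(list(coefficients = c(x = 0.5), se = c(x = s)),
                    class = "logistic_fit")
    ai <- estimate_aor(fi, "x")
    ai$ci_high - ai$ci_low
  })
  expect_true(all(diff(widths) > 0))
})

test_that("exposure AOR is invariant to affine covariate rescaling", {
  co <- make_cohort(500, seed = 3)
  a1 <- fit_association(co, "y", exposure_coding("ever_binary"),
                        c("age", "income"))
  co$age <- 100 + 15 * co$age
  a2 <- fit_association(co, "y", exposure_coding("ever_binary"),
                        c("age", "income"))
  expect_equal(a1$aors$cannabis_ever$aor, a2$aors$cannabis_ever$aor,
               tolerance = 1e-6)
})

test_that("Wald intervals achieve nominal coverage", {
  # 200 simulations at n = 5,000 with a known exposure log-OR of 0.4
  set.seed(40)
  truth <- 0.4
  hits <- logical(200)
  for (i in 1:200) {
    x <- rbinom(5000, 1, 0.3)
    z <- rnorm(5000)
    y <- rbinom(5000, 1, plogis(-2 + truth * x + 0.2 * z))
    co <- data.frame(cannabis_ever = x, cannabis_freq = x, y = y, z = z)
    a <- fit_association(co, "y", exposure_coding("ever_binary"), "z")
    ci <- c(a$aors$cannabis_ever$ci_low, a$aors$cannabis_ever$ci_high)
    hits[i] <- ci[1] <= exp(truth) && exp(truth) <= ci[2]
  }
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("prevalence tables stratify with correct denominators", {
  co <- data.frame(
    y = c(rep(1, 4), rep(0, 96), NA, NA),
    grp = c(rep("a", 100), "a", "b")
  )
  tab <- prevalence_table(co, "y", "grp")
  a_row <- tab[tab$stratum == "a", ]
  expect_equal(a_row$n, 100)          # missing outcome excluded
  expect_equal(a_row$prevalence_pct, 4)
  b_row <- tab[tab$stratum == "b", ]
  expect_equal(b_row$n, 0)
  expect_true(is.na(b_row$prevalence_pct))  # empty cell, not zero
})

test_that("coefficient-difference Z-test matches the normal oracle", {
  d0 <- coef_difference_test(0.5, 0.1, 0.5, 0.2)
  expect_equal(d0$z, 0); expect_equal(d0$p, 1)
  # SEs back-solved from printed CIs: 1.90 [1.64, 2.20] vs 1.52 [1.38, 1.66]
  se1 <- (log(2.20) - log(1.64)) / (2 * 1.96)
  se2 <- (log(1.66) - log(1.38)) / (2 * 1.96)
  dt <- coef_difference_test(log(1.90), se1, log(1.52), se2)
  expect_equal(dt$z, 2.52, tolerance = 0.01)
  expect_equal(dt$p, 0.0117, tolerance = 2e-3)
  # doubling both SEs halves the Z-score
  dt2 <- coef_difference_test(log(1.90), 2 * se1, log(1.52), 2 * se2)
  expect_equal(dt2$z, dt$z / 2, tolerance = 1e-12)
  expect_error(coef_difference_test(1, 0, 1, 0.1),
               class = "prsinteract_param_error")
})
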