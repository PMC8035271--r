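gxe_cohort <- function(n = 500, seed = 60, k_cont = 2) {
  set.seed(seed)
  co <- data.frame(
    cannabis_ever = rbinom(n, 1, 0.3),
    prs = rnorm(n)
  )
  co$cannabis_freq <- co$cannabis_ever * sample(1:4, n, replace = TRUE)
  for (i in seq_len(k_cont)) co[[paste0("c", i)]] <- rnorm(n)
  co$y <- rbinom(n, 1, plogis(-1 + 0.4 * co$cannabis_ever + 0.3 * co$prs))
  co
}

test_that("interaction designs have the documented column counts", {
  co <- gxe_cohort(k_cont = 3)
  spec <- interaction_spec(exposure_coding("ever_binary"), "y",
                           c("c1", "c2", "c3"))
  ds <- build_interaction_designs(co, spec)
  k <- 3
  expect_equal(ncol(ds$full), 4 + 3 * k)
  expect_equal(ncol(ds$reduced), 3 + 3 * k)
  expect_equal(ds$df, 1)
  spec0 <- interaction_spec(exposure_coding("ever_binary"), "y",
                            c("c1", "c2", "c3"),
                            include_covariate_interactions = FALSE)
  ds0 <- build_interaction_designs(co, spec0)
  expect_equal(ncol(ds0$full), 4 + k)
})

test_that("a covariate duplicating the exposure is dropped pairwise, df stays 1", {
  co <- gxe_cohort()
  co$dup <- co$cannabis_ever
  spec <- interaction_spec(exposure_coding("ever_binary"), "y", c("c1", "dup"))
  ds <- build_interaction_designs(co, spec)
  expect_gt(length(ds$dropped), 0)
  expect_equal(ds$df, 1)
  f <- fit_logistic(ds$full, ds$y)
  r <- fit_logistic(ds$reduced, ds$y)
  expect_s3_class(lrt(f, r, df = ds$df), "lrt_result")
})

test_that("the PRS is standardized before products are formed", {
  co <- gxe_cohort()
  spec <- interaction_spec(exposure_coding("ever_binary"), "y", "c1")
  ds <- build_interaction_designs(co, spec)
  expect_equal(mean(ds$full[, "prs"]), 0, tolerance = 1e-12)
  expect_equal(sd(ds$full[, "prs"]), 1, tolerance = 1e-12)
})

test_that("the LRT p-value is invariant to affine rescaling of the raw PRS", {
  co <- gxe_cohort(800, seed = 61)
  spec <- interaction_spec(exposure_coding("ever_binary"), "y", c("c1", "c2"))
  p1 <- test_interaction(co, spec)$lrt$p
  co2 <- co; co2$prs <- 3.7 * co$prs - 11
  p2 <- test_interaction(co2, spec)$lrt$p
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("degenerate and oracle LRT cases behave", {
  co <- gxe_cohort()
  X <- cbind(`(Intercept)` = 1, x = co$cannabis_ever)
  f <- fit_logistic(X, co$y)
  same <- lrt(f, f, df = 0)
  expect_equal(same$chi2, 0); expect_equal(same$p, 1)
  # chi-square survival oracle at chi2 = 5, df = 1
  fake_full <- structure(list(loglik = -100, n_used = 10,
                              coefficients = c(a = 1, b = 1)),
                         class = "logistic_fit")
  fake_red <- structure(list(loglik = -102.5, n_used = 10,
                             coefficients = c(a = 1)),
                        class = "logistic_fit")
  r <- lrt(fake_full, fake_red)
  expect_equal(r$chi2, 5)
  expect_equal(r$p, 0.025347, tolerance = 1e-4)
  # negative statistic beyond tolerance surfaces a convergence error
  bad_full <- structure(list(loglik = -103, n_used = 10,
                             coefficients = c(a = 1, b = 1)),
                        class = "logistic_fit")
  expect_error(lrt(bad_full, fake_red), class = "prsinteract_param_error")
})

test_that("BH adjustment validates, caps, and preserves order", {
  expect_error(bh_adjust(c(0.5, 0)), class = "prsinteract_param_error")
  expect_error(bh_adjust(c(0.5, 1.2)), class = "prsinteract_param_error")
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
  expect_equal(bh_adjust(0.73), 0.73)
  set.seed(62)
  for (i in 1:30) {
    p <- runif(sample(1:20, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))           # brute-force min-over-tail
    expect_true(all(adj >= p))                # FDR >= p elementwise
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in rank
  }
})

test_that("quintile labels balance bins and respect stable tie-breaking", {
  expect_equal(as.vector(table(quintile_stratify(1:100))), rep(20L, 5))
  expect_equal(sort(quintile_stratify(c(5, 3, 9, 1, 7))), 1:5)
  expect_equal(quintile_stratify(c(5, 3, 9, 1, 7)), c(3L, 2L, 5L, 1L, 4L))
  # tied block straddling a boundary: sizes stay within the tie-block size
  x <- c(1, 2, rep(3, 4), 4, 5, 6, 7)
  sizes <- table(quintile_stratify(x))
  expect_true(max(sizes) - min(sizes) <= 4)
  # property: distinct values of any n >= 5 give sizes differing by <= 1
  set.seed(63)
  for (n in c(5, 7, 23, 100, 101, 104)) {
    sizes <- table(quintile_stratify(rnorm(n)))
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_error(quintile_stratify(1:4), class = "prsinteract_param_error")
  expect_error(quintile_stratify(c(1, NA, 3, 4, 5)),
               class = "prsinteract_param_error")
})

test_that("the interaction suite applies BH within each exposure family", {
  set.seed(64)
  co <- gxe_cohort(1500, seed = 64)
  for (o in c("y2", "y3")) co[[o]] <- rbinom(1500, 1, 0.2)
  res <- run_interaction_suite(co, c("y", "y2", "y3"),
                               covariate_names = c("c1", "c2"))
  expect_equal(nrow(res), 6)
  for (k in unique(res$exposure)) {
    idx <- res$exposure == k
    expect_equal(res$fdr[idx], bh_oracle(res$p[idx]))
  }
  expect_true(all(res$fdr >= res$p))
  res_j <- run_interaction_suite(co, c("y", "y2", "y3"),
                                 covariate_names = c("c1", "c2"),
                                 fdr_family = "joint")
  expect_equal(res_j$fdr, bh_oracle(res_j$p))
})

test_that("stratified AOR tables cover 5 quintiles per outcome", {
  co <- gxe_cohort(1000, seed = 65)
  tab <- stratified_aor_table(co, "y", covariate_names = "c1")
  expect_equal(nrow(tab), 5)
  expect_equal(tab$quintile, 1:5)
  expect_true(all(tab$n == 200))
  expect_true(all(is.finite(tab$aor)))
})

test_that("a strong positive interaction raises the top-quintile AOR", {
  set.seed(66)
  n <- 20000
  x <- rbinom(n, 1, 0.3)
  prs <- rnorm(n)
  y <- rbinom(n, 1, plogis(-2 + 0.3 * x + 0.2 * prs + 0.4 * x * prs))
  co <- data.frame(cannabis_ever = x, cannabis_freq = x, prs = prs, y = y)
  tab <- stratified_aor_table(co, "y")
  expect_gt(tab$aor[tab$quintile == 5], tab$aor[tab$quintile == 1])
})
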