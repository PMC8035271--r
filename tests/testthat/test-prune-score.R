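test_that("variants outside the window are never pruned", {
  set.seed(20)
  x <- rbinom(200, 2, 0.5)
  D <- cbind(x, ifelse(runif(200) < 0.99, x, 2 - x))  # r2 ~ 0.96
  panel <- toy_panel(D, pos = c(1L, 600001L))
  cand <- data.frame(variant_id = c("v001", "v002"), p = c(0.001, 0.01))
  expect_equal(nrow(ld_prune(panel, cand)), 2L)
  # same pair inside the window collapses to the smaller p
  panel2 <- toy_panel(D, pos = c(1L, 400001L))
  kept <- ld_prune(panel2, cand)
  expect_identical(kept$variant_id, "v001")
})

test_that("greedy pruning keeps the smaller-p member of a correlated pair", {
  # three variants at 1 kb spacing; only the (1,2) pair is correlated
  set.seed(21)
  n <- 3000
  z <- rbinom(n, 2, 0.5)
  v1 <- z
  v2 <- ifelse(runif(n) < 0.95, z, rbinom(n, 2, 0.5))  # r2 ~ 0.8 with v1
  v3 <- rbinom(n, 2, 0.5)
  panel <- toy_panel(cbind(v1, v2, v3), pos = c(1000L, 2000L, 3000L))
  expect_gt(cor(v1, v2)^2, 0.5)
  cand <- data.frame(variant_id = c("v001", "v002", "v003"),
                     p = c(0.001, 0.02, 0.04))
  expect_identical(ld_prune(panel, cand)$variant_id, c("v001", "v003"))
  # if variant 2 has the smaller p it displaces variant 1
  cand2 <- data.frame(variant_id = c("v001", "v002", "v003"),
                      p = c(0.02, 0.001, 0.04))
  expect_identical(ld_prune(panel, cand2)$variant_id, c("v002", "v003"))
})

test_that("vacuous threshold and constant variants retain everything", {
  set.seed(22)
  D <- cbind(rbinom(100, 2, 0.4), rep(1, 100), rbinom(100, 2, 0.4))
  panel <- toy_panel(D, pos = c(100L, 200L, 300L))
  cand <- data.frame(variant_id = sprintf("v%03d", 1:3), p = c(0.01, 0.02, 0.03))
  expect_equal(nrow(ld_prune(panel, cand, r2_max = 1.01)), 3L)
  # constant dosage: correlation undefined, treated as r2 = 0
  expect_equal(nrow(ld_prune(panel, cand[2:3, ], r2_max = 0.1)), 2L)
})

test_that("pruned output certifies r2 < threshold within the window", {
  p <- sim_params(n_individuals = 300, n_variants = 40, ld_block_size = 8,
                  ld_rho = 0.9, missing_rate = 0.02, seed = 23)
  g <- simulate_genotypes(p)
  cand <- data.frame(variant_id = g$variants$id,
                     p = runif(40, 1e-6, 0.05))
  kept <- ld_prune(g, cand, r2_max = 0.5, window_bp = 5e5)
  idx <- match(kept$variant_id, g$variants$id)
  pos <- g$variants$pos[idx]
  for (a in seq_along(idx)) for (b in seq_len(a - 1)) {
    if (abs(pos[a] - pos[b]) <= 5e5) {
      da <- g$dosages[, idx[a]]; db <- g$dosages[, idx[b]]
      ok <- !is.na(da) & !is.na(db)
      r2 <- suppressWarnings(cor(da[ok], db[ok])^2)
      if (!is.na(r2)) expect_lt(r2, 0.5)
    }
  }
})

test_that("scoring applies weights, offsets, and mean imputation", {
  panel <- toy_panel(matrix(c(2, 1, 0), 3, 1))
  expect_equal(unname(score_individuals(panel,
    data.frame(variant_id = "v001", weight = 0, offset = 0, p = 0.1))),
    c(0, 0, 0))
  panel2 <- toy_panel(matrix(c(2, 1, 0, 1, 1, 1), 3, 2))
  sc <- score_individuals(panel2, data.frame(
    variant_id = c("v001", "v002"), weight = c(0.1, -0.2),
    offset = c(0, 0), p = c(0.1, 0.1)))
  expect_equal(unname(sc[1]), 0.1 * 2 - 0.2 * 1)
  # mean imputation: dosages (0, 2, NA) with weight 0.5 -> (0, 1, 0.5)
  panel3 <- toy_panel(matrix(c(0, 2, NA), 3, 1))
  sc3 <- score_individuals(panel3, data.frame(
    variant_id = "v001", weight = 0.5, offset = 0, p = 0.1))
  expect_equal(unname(sc3), c(0, 1, 0.5))
})

test_that("scores are additive over a partition of the variant set", {
  p <- sim_params(n_individuals = 100, n_variants = 30, missing_rate = 0.05,
                  seed = 24)
  g <- simulate_genotypes(p)
  entries <- data.frame(variant_id = g$variants$id,
                        weight = rnorm(30, 0, 0.1),
                        offset = rnorm(30, 0, 0.01), p = runif(30))
  whole <- score_individuals(g, entries)
  parts <- score_individuals(g, entries[1:13, ]) +
    score_individuals(g, entries[14:30, ])
  expect_equal(whole, parts, tolerance = 1e-9)
})

test_that("entirely missing variants are dropped from scoring with a warning", {
  D <- cbind(c(1, 2, 0), c(NA, NA, NA))
  panel <- toy_panel(D)
  entries <- data.frame(variant_id = c("v001", "v002"), weight = c(0.5, 1),
                        offset = c(0, 0), p = c(0.1, 0.1))
  expect_warning(sc <- score_individuals(panel, entries), "entirely missing")
  expect_equal(unname(sc), 0.5 * c(1, 2, 0))
})
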