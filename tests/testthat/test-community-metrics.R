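test_that("rarefaction honors its size and determinism contracts", {
  m <- matrix(c(10, 5, 3, 0,
                500, 300, 150, 50), nrow = 2, byrow = TRUE,
              dimnames = list(c("low", "high"), paste0("t", 1:4)))
  tbl <- as_count_tbl(m)
  # total == depth: the sample comes back untouched
  same <- rarefy(tbl[1, ], depth = 18, seed = 1)
  expect_equal(same, tbl[1, ])
  # depth 1: exactly one read survives
  one <- rarefy(tbl[2, ], depth = 1, seed = 3)
  expect_equal(sum(one[, -1]), 1)
  expect_equal(sum(one[, -1] > 0), 1)
  # short samples are refused by name
  expect_error(rarefy(tbl, depth = 100, seed = 1), "low")
  # fixed seed, fixed draw; and a sample rarefies the same alone or in a table
  r1 <- rarefy(tbl, depth = 18, seed = 9)
  expect_identical(r1, rarefy(tbl, depth = 18, seed = 9))
  expect_identical(rarefy(tbl[1, ], 18, seed = 9)[1, ], r1[1, ])
})

test_that("rarefied counts match the hypergeometric expectation", {
  total <- 1000
  m <- matrix(c(500, 500), nrow = 1, dimnames = list("s1", c("half", "rest")))
  tbl <- as_count_tbl(m)
  draws <- vapply(1:1000, function(s) rarefy(tbl, 500, seed = s)$half, numeric(1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 250), 3 * se)
})

test_that("expected richness is non-decreasing in rarefaction depth", {
  m <- matrix(rpois(30, 8) + 1, nrow = 1,
              dimnames = list("s1", paste0("t", 1:30)))
  tbl <- as_count_tbl(m)
  depths <- c(20, 60, 120, sum(m))
  mean_rich <- vapply(depths, function(d) {
    mean(vapply(1:200, function(s) sum(rarefy(tbl, d, seed = s)[, -1] > 0),
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_rich) >= 0))
})

test_that("chao1 follows the bias-corrected formula", {
  # S_obs = 10, F1 = 4, F2 = 2 -> 10 + 4*3/(2*3) = 12
  x <- c(1, 1, 1, 1, 2, 2, 3, 4, 5, 6)
  expect_equal(chao1(x), 12)
  # no singletons: estimator collapses to observed richness
  expect_equal(chao1(c(2, 3, 5)), 3)
  expect_equal(chao1(rep(0, 4)), 0)
  # correction is never negative, and vegan agrees on random samples
  withr::with_seed(21, {
    for (i in 1:20) {
      x <- rpois(50, 2)
      expect_gte(chao1(x), sum(x > 0))
      if (sum(x) > 0) {
        expect_equal(chao1(x), unname(vegan::estimateR(x)["S.chao1"]))
      }
    }
  })
})

test_that("shannon entropy matches hand values and its invariances", {
  expect_equal(shannon(c(7)), 0)
  expect_equal(shannon(c(5, 5, 5, 5)), log(4))
  expect_equal(shannon(c(2, 1, 1)), 1.039721, tolerance = 1e-6)
  x <- c(4, 9, 1, 0, 6)
  expect_equal(shannon(x), shannon(rev(x)))
  expect_equal(shannon(x), shannon(10 * x))
  expect_error(shannon(c(0, 0)), "all-zero")
})

test_that("bray-curtis satisfies hand values, symmetry and range", {
  m <- matrix(c(2, 2,
                2, 0,
                0, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("t1", "t2")))
  d <- bray_curtis(as_count_tbl(m))
  expect_equal(d["a", "b"], 1 / 3)
  expect_equal(d["b", "c"], 1)          # disjoint
  expect_equal(unname(diag(d)), rep(0, 3))
  dup <- as_count_tbl(rbind(m, a2 = m["a", ]))
  expect_equal(bray_curtis(dup)["a", "a2"], 0)
  withr::with_seed(5, {
    mm <- matrix(rpois(60, 4), nrow = 6,
                 dimnames = list(paste0("s", 1:6), paste0("t", 1:10)))
    mm[rowSums(mm) == 0, 1] <- 1
    dd <- bray_curtis(as_count_tbl(mm))
    expect_equal(dd, t(dd))
    expect_true(all(dd >= 0 & dd <= 1))
  })
})

test_that("linear_fit reproduces hand OLS and flags degenerate input", {
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  fit <- linear_fit(x, y)
  expect_equal(fit$slope, 1.5)
  expect_equal(fit$intercept, -2 / 3)
  expect_equal(fit$r_squared, fit$r^2, tolerance = 1e-12)
  perfect <- suppressWarnings(linear_fit(1:10, 2 * (1:10)))
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$r, 1)
  expect_equal(suppressWarnings(linear_fit(1:10, -2 * (1:10)))$r, -1)
  expect_error(linear_fit(rep(1, 5), 1:5), "constant")
  expect_true(fit$p_value >= 0 && fit$p_value <= 1)
})

test_that("diversity_table and regress_diversity plumb together", {
  st <- simulate_decay_study(n_parents = 6, seed = 31)
  rar <- rarefy(st$bacteria, 1080, seed = 2)
  div <- diversity_table(rar)
  expect_true(all(div$chao1 >= div$observed_richness))
  expect_true(all(div$shannon >= 0 &
                    div$shannon <= log(pmax(div$observed_richness, 2))))
  fits <- regress_diversity(div, st$metadata)
  expect_equal(fits$metric, c("chao1", "shannon"))
  pooled <- regress_diversity(div, st$metadata, average = TRUE)
  expect_equal(pooled$n, c(6L, 6L))
})
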