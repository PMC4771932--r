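make_two_block_data <- function() {
  # two internally identical community blocks separated by one covariate
  m <- rbind(matrix(rep(c(10, 0, 5), each = 4), nrow = 4),
             matrix(rep(c(0, 10, 5), each = 4), nrow = 4))
  dimnames(m) <- list(paste0("s", 1:8), c("t1", "t2", "t3"))
  env <- tibble::tibble(sample_id = rownames(m),
                        depthvar = c(1, 2, 3, 4, 10, 11, 12, 13))
  list(counts = as_count_tbl(m), env = env)
}

test_that("a perfectly separable instance splits once at the midpoint", {
  d <- make_two_block_data()
  tree <- fit_mrt(d$counts, d$env, max_leaves = 2)
  expect_equal(nrow(tree$splits), 1L)
  expect_equal(tree$splits$variable, "depthvar")
  expect_equal(tree$splits$threshold, 7)   # midpoint between 4 and 10
  expect_equal(tree$total_impurity, 0)
  expect_equal(canonical_partition(tree$leaves),
               canonical_partition(list(paste0("s", 1:4), paste0("s", 5:8))))
})

test_that("degenerate configurations collapse to a single leaf", {
  d <- make_two_block_data()
  one <- fit_mrt(d$counts, d$env, max_leaves = 1)
  expect_equal(length(one$leaves), 1L)
  expect_equal(nrow(one$splits), 0L)
  flat_env <- tibble::tibble(sample_id = d$env$sample_id, x = rep(1, 8))
  expect_warning(flat <- fit_mrt(d$counts, flat_env, max_leaves = 3),
                 "constant")
  expect_equal(length(flat$leaves), 1L)
})

test_that("the greedy fit equals an independent brute-force greedy", {
  withr::with_seed(77, {
    for (i in 1:10) {
      n <- 8
      X <- cbind(runif(n), runif(n))
      comm <- cbind(5 + 8 * (X[, 1] > 0.5) + rpois(n, 2),
                    5 + 8 * (X[, 2] > 0.4) + rpois(n, 2),
                    rpois(n, 5) + 1)
      dimnames(comm) <- list(paste0("s", seq_len(n)), paste0("t", 1:3))
      env <- tibble::tibble(sample_id = rownames(comm),
                            v1 = X[, 1], v2 = X[, 2])
      D <- bray_curtis(as_count_tbl(comm))
      tree <- fit_mrt(D, env, max_leaves = 3, min_node_size = 2)
      oracle <- brute_greedy_mrt(D, X, max_leaves = 3, min_node = 2)
      expect_equal(
        canonical_partition(tree$leaves),
        canonical_partition(lapply(oracle$leaves, function(ix) rownames(comm)[ix])))
    }
  })
})

test_that("total leaf impurity never increases with tree size", {
  st <- simulate_decay_study(n_parents = 10, seed = 13)
  avg <- average_replicates(st$bacteria, st$metadata)
  env <- dplyr::distinct(st$metadata, .data$replicate_of, .keep_all = TRUE) |>
    dplyr::mutate(sample_id = .data$replicate_of) |>
    dplyr::select("sample_id", "wood_density", "ph")
  imp <- vapply(1:4, function(k) {
    fit_mrt(avg, env, max_leaves = k)$total_impurity
  }, numeric(1))
  expect_true(all(diff(imp) <= 1e-12))
})

test_that("stage labels follow density ordering across the 0.40/0.30 bands", {
  # a tree trained on density bands 0.40/0.30 routes new samples by band
  dens <- c(0.45, 0.44, 0.35, 0.34, 0.20, 0.19)
  m <- rbind(matrix(rep(c(9, 0, 0), each = 2), nrow = 2),
             matrix(rep(c(0, 9, 0), each = 2), nrow = 2),
             matrix(rep(c(0, 0, 9), each = 2), nrow = 2))
  dimnames(m) <- list(paste0("s", 1:6), paste0("t", 1:3))
  env <- tibble::tibble(sample_id = rownames(m), wood_density = dens)
  tree <- fit_mrt(as_count_tbl(m), env, max_leaves = 3)
  new_env <- tibble::tibble(sample_id = c("n1", "n2", "n3"),
                            wood_density = c(0.45, 0.35, 0.20))
  stages <- assign_stages(tree, new_env)
  expect_equal(stages$stage, c("early", "middle", "late"))
  expect_identical(stages, assign_stages(tree, new_env))
  # a single-leaf tree labels everything early
  one <- fit_mrt(as_count_tbl(m), env, max_leaves = 1)
  expect_true(all(assign_stages(one, env)$stage == "early"))
  expect_error(assign_stages(tree, tibble::tibble(sample_id = "x", ph = 4)),
               "wood_density")
})

test_that("the first greedy split is the best single split globally", {
  withr::with_seed(99, {
    for (i in 1:5) {
      n <- 10
      X <- cbind(runif(n), runif(n))
      comm <- matrix(rpois(n * 4, 6) + 1, nrow = n,
                     dimnames = list(paste0("s", 1:n), paste0("t", 1:4)))
      env <- tibble::tibble(sample_id = rownames(comm), v1 = X[, 1], v2 = X[, 2])
      D <- bray_curtis(as_count_tbl(comm))
      tree <- fit_mrt(D, env, max_leaves = 2, min_node_size = 2)
      oracle <- brute_greedy_mrt(D, X, max_leaves = 2, min_node = 2)
      if (length(oracle$splits)) {
        expect_equal(tree$splits$threshold, oracle$splits[[1]][2])
        expect_equal(match(tree$splits$variable, c("v1", "v2")),
                     oracle$splits[[1]][1])
      } else {
        expect_equal(nrow(tree$splits), 0L)
      }
    }
  })
})
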