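test_that("the genus filter applies both readings of representation", {
  m <- matrix(0, nrow = 3, ncol = 10,
              dimnames = list(paste0("s", 1:3), paste0("g", 1:10)))
  m[1, ] <- c(5, 4, 10, 2, 0, 6, 1, 7, 3, 9)   # totals drive "reads" mode
  tbl <- as_count_tbl(m)
  kept <- filter_genera(tbl, min_representatives = 5, mode = "reads")
  expect_setequal(names(kept)[-1], c("g1", "g3", "g6", "g8", "g10"))
  # boundary: exactly five reads in one sample is kept; four is not
  expect_true("g1" %in% names(kept))
  expect_false("g2" %in% names(kept))
  # prevalence mode counts samples instead
  m2 <- rbind(g = c(1, 1, 1, 1, 1), h = c(9, 0, 0, 0, 0))
  m2 <- t(m2); rownames(m2) <- paste0("s", 1:5)
  kept2 <- filter_genera(as_count_tbl(m2), 5, mode = "samples")
  expect_equal(names(kept2)[-1], "g")
  expect_error(filter_genera(tbl, min_representatives = 100), "lower")
})

test_that("fixture with three under-threshold genera keeps seven", {
  withr::with_seed(3, {
    m <- matrix(rpois(40, 20), nrow = 4,
                dimnames = list(paste0("s", 1:4), paste0("g", 1:10)))
  })
  m[, 2] <- c(1, 1, 1, 1); m[, 5] <- c(0, 0, 2, 2); m[, 9] <- c(3, 0, 0, 0)
  kept <- filter_genera(as_count_tbl(m), 5)
  expect_equal(ncol(kept) - 1L, 7L)
})

test_that("correlation matrix matches hand Pearson values and contracts", {
  m <- cbind(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4), z = c(4, 3, 2, 1))
  rownames(m) <- paste0("s", 1:4)
  cm <- correlation_matrix(as_count_tbl(m))
  expect_equal(cm$r["x", "y"], 0.8)
  expect_equal(cm$r["x", "z"], -1)
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  # p from the t transform agrees with cor.test
  ct <- cor.test(m[, "x"], m[, "y"])
  expect_equal(cm$p["x", "y"], ct$p.value, tolerance = 1e-12)
  expect_lt(cm$p["x", "z"], 1e-10)
  expect_error(correlation_matrix(as_count_tbl(m[1:3, ])), "at least 4")
  m2 <- cbind(m, const = rep(2, 4))
  expect_warning(cm2 <- correlation_matrix(as_count_tbl(m2)), "const")
  expect_false("const" %in% colnames(cm2$r))
})

test_that("network thresholds are strict and conjunctive", {
  r <- matrix(c(1, 0.80, 0.95,
                0.80, 1, -0.99,
                0.95, -0.99, 1), nrow = 3,
              dimnames = list(letters[1:3], letters[1:3]))
  p <- matrix(c(0, 0.001, 0.20,
                0.001, 0, 0.001,
                0.20, 0.001, 0), nrow = 3,
              dimnames = dimnames(r))
  net <- build_network(list(r = r, p = p), use_fdr = FALSE)
  # a-b: r exactly 0.80 -> excluded; a-c: p 0.20 -> excluded; b-c passes
  expect_equal(nrow(net$edges), 1L)
  expect_equal(sort(c(net$edges$genus_a, net$edges$genus_b)), c("b", "c"))
  expect_equal(net$edges$sign, "negative")
  # isolated genus "a" is not a node
  expect_setequal(net$nodes$genus, c("b", "c"))
})

test_that("a planted five-pair fixture recovers exactly its edges", {
  withr::with_seed(8, {
    n <- 19
    base <- matrix(rnorm(n * 10, 10, 1), nrow = n)
    pairs <- lapply(1:5, function(k) {
      x <- rnorm(n, 10, 2)
      cbind(x, x + rnorm(n, 0, 0.05))
    })
    m <- cbind(base, do.call(cbind, pairs))
    colnames(m) <- c(paste0("bg", 1:10), paste0("pl", 1:10))
    rownames(m) <- paste0("s", 1:n)
  })
  cm <- correlation_matrix(as_count_tbl(m))
  net <- build_network(cm, use_fdr = FALSE)
  expect_equal(nrow(net$edges), 5L)
  expect_setequal(paste(net$edges$genus_a, net$edges$genus_b),
                  paste(paste0("pl", c(1, 3, 5, 7, 9)),
                        paste0("pl", c(2, 4, 6, 8, 10))))
  # genus ordering does not change the edge set
  shuffled <- as_count_tbl(m[, sample(ncol(m))])
  net2 <- build_network(correlation_matrix(shuffled), use_fdr = FALSE)
  key <- function(nt) {
    sort(paste(pmin(nt$edges$genus_a, nt$edges$genus_b),
               pmax(nt$edges$genus_a, nt$edges$genus_b)))
  }
  expect_equal(key(net2), key(net))
})

test_that("exported edges recompute identically from the abundance table", {
  withr::with_seed(12, {
    n <- 12
    x <- rnorm(n)
    m <- cbind(a = x, b = x + rnorm(n, 0, 0.1), c = rnorm(n), d = -x + rnorm(n, 0, 0.1))
    m <- m + 10
    rownames(m) <- paste0("s", 1:n)
  })
  tbl <- as_count_tbl(m)
  net <- build_network(correlation_matrix(tbl), use_fdr = FALSE)
  expect_gt(nrow(net$edges), 0)
  for (i in seq_len(nrow(net$edges))) {
    ct <- cor.test(m[, net$edges$genus_a[i]], m[, net$edges$genus_b[i]])
    expect_equal(net$edges$r[i], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(net$edges$p[i], ct$p.value, tolerance = 1e-12)
  }
})

test_that("degree statistics match closed forms", {
  triangle <- list(r = NULL, p = NULL)
  edges <- tibble::tibble(genus_a = c("a", "a", "b"),
                          genus_b = c("b", "c", "c"),
                          r = 0.9, p = 0.001, q = 0.01, sign = "positive")
  net <- structure(list(nodes = tibble::tibble(
    genus = c("a", "b", "c"), kingdom = NA_character_, degree = c(2L, 2L, 2L)),
    edges = edges), class = "co_network")
  s <- network_stats(net)
  expect_equal(s$average_degree, 2)
  expect_equal(unname(s$degree), c(2, 2, 2))
  star <- structure(list(nodes = tibble::tibble(
    genus = c("hub", paste0("leaf", 1:4)), kingdom = NA_character_,
    degree = c(4L, 1L, 1L, 1L, 1L)),
    edges = tibble::tibble(genus_a = "hub", genus_b = paste0("leaf", 1:4),
                           r = 0.9, p = 0.001, q = 0.01, sign = "positive")),
    class = "co_network")
  s2 <- network_stats(star)
  expect_equal(s2$average_degree, 8 / 5)
  expect_equal(s2$key_nodes$genus[1], "hub")
  empty <- structure(list(nodes = tibble::tibble(genus = character(),
                                                 kingdom = character(),
                                                 degree = integer()),
                          edges = edges[0, ]), class = "co_network")
  expect_equal(network_stats(empty)$average_degree, 0)
})

test_that("network exports are readable by igraph and carry attributes", {
  withr::with_seed(4, {
    x <- rnorm(10)
    m <- cbind(a = x, b = x + rnorm(10, 0, 0.05), c = rnorm(10)) + 5
    rownames(m) <- paste0("s", 1:10)
  })
  net <- build_network(correlation_matrix(as_count_tbl(m)), use_fdr = FALSE,
                       kingdom = c(a = "Bacteria", b = "Bacteria", c = "Fungi"))
  dir <- withr::local_tempdir()
  paths <- export_network(net, file.path(dir, "net"))
  expect_true(all(file.exists(paths)))
  g <- igraph::read_graph(file.path(dir, "net.graphml"), format = "graphml")
  expect_equal(igraph::gsize(g), nrow(net$edges))
  edges_back <- readr::read_tsv(file.path(dir, "net_edges.tsv"),
                                show_col_types = FALSE)
  expect_equal(nrow(edges_back), nrow(net$edges))
})
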