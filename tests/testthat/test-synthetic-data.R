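test_that("neutral urn handles the single-individual and determinism contracts", {
  expect_equal(simulate_neutral_sample(3, 0.4, 1, seed = 1), 1L)
  expect_equal(simulate_neutral_sample(10, 0.7, 1, seed = 99), 1L)
  a <- simulate_neutral_sample(20, 0.3, 500, seed = 42)
  b <- simulate_neutral_sample(20, 0.3, 500, seed = 42)
  expect_identical(a, b)
  expect_equal(sum(a), 500)
  expect_true(all(diff(a) <= 0))
  expect_error(simulate_neutral_sample(5, 0.5, 0), "J")
  expect_error(simulate_neutral_sample(-1, 0.5, 10), "theta")
})

test_that("neutral urn at m = 1 matches the Ewens expected richness", {
  theta <- 5; J <- 100; reps <- 2000
  expected_s <- sum(theta / (theta + seq_len(J) - 1))
  s_obs <- vapply(seq_len(reps), function(i) {
    length(simulate_neutral_sample(theta, 1, J, seed = i))
  }, numeric(1))
  se <- sd(s_obs) / sqrt(reps)
  expect_lt(abs(mean(s_obs) - expected_s), 3 * se)
})

test_that("niche sampler draws Poisson around normalized expectations", {
  # expectations rescale to J exactly before sampling
  lam <- expected_abundance("lognormal", list(mu = 1, sigma = 1.3), S = 20, J = 500)
  expect_equal(sum(lam * (500 / sum(lam))), 500, tolerance = 1e-9)
  # extreme preemption: rank 1 holds ~99% of the community (exactly
  # alpha/(alpha + alpha(1-alpha)) = 1/(2 - alpha) after normalization)
  lam2 <- expected_abundance("preemption", list(alpha = 0.99), S = 2, J = 1e6)
  expect_equal(lam2[1] / sum(lam2), 1 / (2 - 0.99), tolerance = 1e-12)
  expect_equal(lam2[1] / sum(lam2), 0.99, tolerance = 2e-4)
  expect_identical(simulate_niche_sample("zipf", list(p1 = 0.3, gamma = -1.2),
                                         S = 30, J = 400, seed = 7),
                   simulate_niche_sample("zipf", list(p1 = 0.3, gamma = -1.2),
                                         S = 30, J = 400, seed = 7))
  expect_error(simulate_niche_sample("lognormal", list(mu = 1, sigma = -1),
                                     S = 5, J = 100, seed = 1), "sigma")
})

test_that("per-rank means over many draws track the expected abundances", {
  S <- 5; J <- 200
  lam <- expected_abundance("brokenstick", S = S, J = J)
  reps <- 10000
  draws <- matrix(0, nrow = reps, ncol = S)
  withr::with_seed(11, {
    for (i in seq_len(reps)) draws[i, ] <- rpois(S, lam)
  })
  for (r in seq_len(S)) {
    se <- sd(draws[, r]) / sqrt(reps)
    expect_lt(abs(mean(draws[, r]) - lam[r]), 3 * se)
  }
})

test_that("decay study generates the advertised design", {
  st <- simulate_decay_study(seed = 5)
  expect_equal(nrow(st$bacteria), 57)
  expect_equal(nrow(st$fungi), 57)
  expect_equal(nrow(st$metadata), 57)
  # stage bands respected on the density gradient
  expect_true(all(st$truth$density[st$truth$stage == "early"] > 0.40))
  expect_true(all(st$truth$density[st$truth$stage == "late"] < 0.30))
  # replicate depths support the target rarefaction
  expect_true(all(rowSums(st$bacteria[, -1]) >= 1080))
  expect_true(all(rowSums(st$fungi[, -1]) >= 2000))
  # every fungal sample is dominated by one phylotype
  fm <- as.matrix(st$fungi[, -1])
  expect_true(all(apply(fm / rowSums(fm), 1, max) >= 0.5))
  # the early indicator taxon is confined to early parents
  ind <- st$bacteria$OTU_ind_early
  stage_rep <- st$truth$stage[match(st$metadata$replicate_of, st$truth$parent)]
  expect_true(all(ind[stage_rep == "early"] > 0))
  expect_true(all(ind[stage_rep != "early"] == 0))
  # taxonomy covers both tables; metadata passes its own validation
  expect_true(all(setdiff(names(st$bacteria), "sample_id") %in%
                    st$taxonomy$taxon_id))
  expect_true(all(setdiff(names(st$fungi), "sample_id") %in%
                    st$taxonomy$taxon_id))
  expect_identical(simulate_decay_study(seed = 5)$bacteria, st$bacteria)
  expect_error(decay_study_config(bands = c(early = 0.2, late = 0.4)), "bands")
})

test_that("bacterial richness rises as wood density falls", {
  st <- simulate_decay_study(seed = 8)
  rar <- rarefy(st$bacteria, 1080, seed = 1)
  div <- diversity_table(rar)
  fit <- regress_diversity(div, st$metadata, metrics = "chao1")
  expect_lt(fit$slope, 0)
  expect_lt(fit$p_value, 0.01)
})

test_that("planted genus pairs carry their correlation into the tables", {
  hits <- 0
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    st <- simulate_decay_study(seed = 1000 + s)
    avg <- average_replicates(st$bacteria, st$metadata)
    r <- cor(avg$OTU_pair1a, avg$OTU_pair1b)
    hits <- hits + (r > 0.8)
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("a study written to disk reads back into equivalent tables", {
  st <- simulate_decay_study(seed = 2)
  dir <- withr::local_tempdir()
  write_decay_study(st, dir)
  expect_equal(read_count_table(file.path(dir, "bacteria_counts.tsv")),
               st$bacteria)
  expect_equal(read_taxonomy(file.path(dir, "taxonomy.tsv")), st$taxonomy)
  meta <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(meta$wood_density, st$metadata$wood_density, tolerance = 1e-12)
  manifest <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(unlist(manifest$stage), st$truth$stage)
})
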