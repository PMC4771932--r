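#' Rarefy samples to a common depth
#'
#' Draws, for each sample, a uniform subsample of exactly `depth` reads
#' without replacement, removing sequencing-depth bias before diversity
#' estimation. Samples with fewer than `depth` reads are an error naming
#' them (callers that mirror the study's exclusion policy should drop such
#' samples first; see [run_pipeline()]).
#'
#' Each sample uses its own deterministic substream derived from `seed` and
#' the sample's position, so a single sample rarefies identically whether
#' processed alone or within the full table.
#'
#' @param counts A count tibble.
#' @param depth Target depth (reads per sample).
#' @param seed Integer seed controlling the subsampling.
#' @return A count tibble with every row summing to `depth`.
#' @export
rarefy <- function(counts, depth, seed = 1L) {
  m <- count_tbl_to_matrix(counts)
  check_counts_nonneg(m)
  totals <- rowSums(m)
  short <- totals < depth
  if (any(short)) {
    abort(sprintf("samples below rarefaction depth %d: %s", depth,
                  paste(sprintf("%s (%d reads)", rownames(m)[short],
                                as.integer(totals[short])), collapse = ", ")))
  }
  out <- m
  for (i in seq_len(nrow(m))) {
    out[i, ] <- with_substream(seed, i, rarefy_vector(m[i, ], depth))
  }
  matrix_to_count_tbl(out)
}

# uniform subsample without replacement of one sample's counts
rarefy_vector <- function(x, depth) {
  if (sum(x) == depth) return(x)
  reads <- rep.int(seq_along(x), x)
  picked <- sample(reads, depth, replace = FALSE)
  tabulate(picked, nbins = length(x))
}

#' Bias-corrected Chao1 richness estimate
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, with `F1`/`F2` the singleton and
#' doubleton counts. The bias-corrected form keeps the estimator defined
#' when no doubletons are observed; it equals the observed richness when
#' there are no singletons. An all-zero sample returns 0.
#'
#' @param x Non-negative integer counts for one sample.
#' @return The estimated richness (a single number, `>= sum(x > 0)`).
#' @export
chao1 <- function(x) {
  if (any(x < 0) || any(x != floor(x))) abort("chao1 needs non-negative integer counts")
  s_obs <- sum(x > 0)
  if (s_obs == 0L) return(0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity index (natural log)
#'
#' Entropy of the relative-abundance distribution, `-sum(p_i log p_i)` in
#' nats. Requires at least one positive count.
#'
#' @param x Non-negative counts for one sample.
#' @return Shannon index in nats.
#' @export
shannon <- function(x) {
  if (any(x < 0)) abort("counts must be non-negative")
  if (sum(x) == 0) abort("shannon is undefined for an all-zero sample")
  as.numeric(vegan::diversity(x, index = "shannon", base = exp(1)))
}

#' Per-sample alpha diversity table
#'
#' Observed richness, bias-corrected Chao1 and Shannon index for every
#' sample of a count tibble.
#'
#' @param counts A count tibble (ideally rarefied to a common depth).
#' @return A tibble with columns `sample_id`, `observed_richness`, `chao1`,
#'   `shannon`.
#' @export
diversity_table <- function(counts) {
  m <- count_tbl_to_matrix(counts)
  tibble::tibble(
    sample_id = rownames(m),
    observed_richness = as.integer(rowSums(m > 0)),
    chao1 = apply(m, 1L, chao1),
    shannon = apply(m, 1L, shannon)
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` between all sample pairs:
#' 0 for identical samples, 1 for samples sharing no taxa.
#'
#' @param counts A count tibble (counts or relative abundances).
#' @return A symmetric base matrix with zero diagonal, dimnames = sample ids.
#' @export
bray_curtis <- function(counts) {
  m <- count_tbl_to_matrix(counts)
  check_counts_nonneg(m, "abundance table")
  if (nrow(m) < 2L) abort("need at least two samples")
  if (any(rowSums(m) == 0)) {
    abort(paste0("all-zero samples have undefined dissimilarity: ",
                 paste(rownames(m)[rowSums(m) == 0], collapse = ", ")))
  }
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Ordinary least-squares fit of y on x
#'
#' Simple linear regression with the two-sided slope p-value from the t
#' distribution on n - 2 degrees of freedom. Both the Pearson correlation
#' `r` and `r_squared = r^2` are reported, since signed strength-of-fit
#' values in the decay literature are Pearson r even when labelled R2.
#'
#' @param x Covariate values (not constant, length >= 3).
#' @param y Response values, same length.
#' @return A one-row tibble: `slope`, `intercept`, `r`, `r_squared`,
#'   `p_value`, `n`.
#' @export
linear_fit <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) abort("need at least 3 complete observations")
  if (sd(x) == 0) abort("x is constant; slope is undefined")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r = cor(x, y),
    r_squared = cor(x, y)^2,
    p_value = unname(sm$coefficients[2, 4]),
    n = length(x)
  )
}

#' Regress alpha diversity against a wood covariate
#'
#' Joins a [diversity_table()] with sample metadata and fits one OLS line
#' per requested diversity metric against the covariate (by default wood
#' density, the decay-stage proxy). Replicates are pooled — each replicate
#' enters as its own point — unless `average = TRUE`, which first averages
#' each metric over the replicates of a parent sample.
#'
#' @param diversity A tibble from [diversity_table()].
#' @param metadata A metadata tibble.
#' @param covariate Metadata column name (default `"wood_density"`).
#' @param metrics Which diversity columns to regress.
#' @param average Average replicate metrics per parent before fitting?
#' @return A tibble with one row per metric, columns of [linear_fit()].
#' @export
regress_diversity <- function(diversity, metadata, covariate = "wood_density",
                              metrics = c("chao1", "shannon"),
                              average = FALSE) {
  if (!covariate %in% names(metadata)) {
    abort(paste0("metadata has no column ", covariate))
  }
  dat <- dplyr::inner_join(diversity, metadata, by = "sample_id")
  if (average) {
    dat <- dat |>
      dplyr::group_by(.data$replicate_of) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(c(metrics, covariate)), mean),
                       .groups = "drop")
  }
  purrr::map_dfr(metrics, function(mt) {
    dplyr::bind_cols(tibble::tibble(metric = mt),
                     linear_fit(dat[[covariate]], dat[[mt]]))
  })
}

#' Scatter plot of a diversity metric against a covariate with its OLS line
#'
#' @inheritParams regress_diversity
#' @param metric One diversity column to plot.
#' @return A ggplot object.
#' @export
plot_diversity_regression <- function(diversity, metadata,
                                      covariate = "wood_density",
                                      metric = "chao1") {
  dat <- dplyr::inner_join(diversity, metadata, by = "sample_id")
  ggplot2::ggplot(dat, ggplot2::aes(.data[[covariate]], .data[[metric]])) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = covariate, y = metric)
}
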