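#' Metastats-style permutation test for differential abundance
#'
#' Two-group comparison of per-taxon relative abundances: counts are
#' converted to relative abundances within each sample, an
#' unequal-variance (Welch) t statistic is computed per taxon, and its null
#' distribution is built by randomly relabelling samples across the two
#' groups. The two-sided p-value uses the add-one rule
#' `p = (1 + #permutations with |t*| >= |t_obs|) / (n_perm + 1)`, so the
#' smallest attainable p is `1/(n_perm + 1)`. q-values come from
#' [benjamini_hochberg()].
#'
#' With `exhaustive = TRUE` every distinct relabelling is enumerated
#' instead (feasible for small groups), giving the exact permutation
#' p-value `#{|t*| >= |t_obs|} / #relabellings` including the identity.
#' `mode = "bootstrap"` resamples group labels with replacement instead of
#' permuting, mirroring tools that describe the procedure as a bootstrap.
#'
#' Taxa absent from every sample are dropped with a warning. Taxa with
#' fewer than 2 samples carrying them per group are still tested but
#' flagged `low_information`.
#'
#' @param counts A count tibble restricted to the samples of two groups.
#' @param groups A data frame `sample_id`, `group` (exactly two levels), or
#'   a vector of labels named by sample id.
#' @param n_perm Number of random relabellings (ignored when exhaustive).
#' @param seed Integer seed for the permutation stream.
#' @param exhaustive Enumerate all distinct relabellings?
#' @param mode `"permutation"` (without replacement, default) or
#'   `"bootstrap"` (labels resampled with replacement).
#' @return A tibble with one row per taxon: group means and standard
#'   errors, `t_statistic`, `p_value`, `q_value`, `low_information`.
#' @export
metastats_test <- function(counts, groups, n_perm = 1000, seed = 1,
                           exhaustive = FALSE,
                           mode = c("permutation", "bootstrap")) {
  mode <- match.arg(mode)
  m <- count_tbl_to_matrix(counts)
  check_counts_nonneg(m)
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$group), groups$sample_id)
  }
  g <- groups[rownames(m)]
  if (anyNA(g)) abort("every sample needs a group label")
  lev <- unique(unname(g))
  if (length(lev) != 2L) abort("exactly two groups are required")
  in_a <- g == lev[1]
  if (sum(in_a) < 2L || sum(!in_a) < 2L) abort("both groups need >= 2 samples")

  empty <- colSums(m) == 0
  if (any(empty)) {
    warn(paste0("dropping taxa absent from all samples: ",
                paste(colnames(m)[empty], collapse = ", ")))
    m <- m[, !empty, drop = FALSE]
  }
  rel <- m / rowSums(m)
  n <- nrow(rel)
  na <- sum(in_a); nb <- n - na

  welch_t <- function(is_a) {
    xa <- rel[is_a, , drop = FALSE]; xb <- rel[!is_a, , drop = FALSE]
    ma <- colMeans(xa); mb <- colMeans(xb)
    va <- (colSums(xa^2) - na * ma^2) / (na - 1)
    vb <- (colSums(xb^2) - nb * mb^2) / (nb - 1)
    va <- pmax(va, 0); vb <- pmax(vb, 0)  # guard tiny negative round-off
    se2 <- va / na + vb / nb
    t <- (ma - mb) / sqrt(se2)
    t[se2 == 0] <- 0  # both groups constant: no evidence either way
    list(t = t, ma = ma, mb = mb, sea = sqrt(va / na), seb = sqrt(vb / nb))
  }
  obs <- welch_t(in_a)

  if (exhaustive) {
    picks <- combn(n, na)
    tmat <- apply(picks, 2L, function(ix) {
      is_a <- seq_len(n) %in% ix
      abs(welch_t(is_a)$t)
    })
    tmat <- matrix(tmat, nrow = ncol(rel))
    p <- rowMeans(tmat >= abs(obs$t) - 1e-12)
  } else {
    exceed <- rep(0L, ncol(rel))
    with_substream(seed, 1L, {
      for (b in seq_len(n_perm)) {
        is_a <- if (mode == "permutation") {
          seq_len(n) %in% sample.int(n, na)
        } else {
          resampled <- sample(g, n, replace = TRUE)
          # with replacement a draw can be one-sided; redraw until two-sided
          while (length(unique(resampled)) < 2L ||
                 sum(resampled == lev[1]) < 2L ||
                 sum(resampled != lev[1]) < 2L) {
            resampled <- sample(g, n, replace = TRUE)
          }
          resampled == lev[1]
        }
        exceed <- exceed + (abs(welch_t(is_a)$t) >= abs(obs$t) - 1e-12)
      }
    })
    p <- (1 + exceed) / (n_perm + 1)
  }

  nz_a <- colSums(rel[in_a, , drop = FALSE] > 0)
  nz_b <- colSums(rel[!in_a, , drop = FALSE] > 0)
  tibble::tibble(
    taxon = colnames(rel),
    group_a = lev[1], group_b = lev[2],
    mean_a = unname(obs$ma), mean_b = unname(obs$mb),
    se_a = unname(obs$sea), se_b = unname(obs$seb),
    t_statistic = unname(obs$t),
    p_value = unname(p),
    q_value = benjamini_hochberg(unname(p)),
    low_information = unname(nz_a < 2 | nz_b < 2)
  ) |> dplyr::arrange(.data$q_value, .data$p_value, .data$taxon)
}

#' Benjamini-Hochberg step-up q-values
#'
#' False-discovery-rate adjusted p-values:
#' `q_(i) = min_{j >= i} (m p_(j) / j)` clipped to 1, mapped back to the
#' input order. Input p-values outside `[0, 1]` are an error.
#'
#' @param p Numeric vector of p-values.
#' @return q-values of the same length and order.
#' @export
benjamini_hochberg <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
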