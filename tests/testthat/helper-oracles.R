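# Independent oracles used across the suite. Everything here is coded
# directly from the defining formulas, without touching the package's
# internal helpers, so tests compare two genuinely separate routes.

# all integer partitions of n (abundance configurations of a community of n)
partitions_of <- function(n, max_part = n) {
  if (n == 0L) return(list(integer(0)))
  out <- list()
  for (k in seq_len(min(n, max_part))) {
    for (rest in partitions_of(n - k, k)) {
      out <- c(out, list(c(k, rest)))
    }
  }
  out
}

# Ewens sampling formula, written from the multiplicity form
# P = J! / prod_j (j^phi_j phi_j!) * theta^S / theta^(J rising)
ewens_loglik_oracle <- function(a, theta) {
  J <- sum(a)
  S <- length(a)
  phi <- tabulate(a, nbins = J)
  lfactorial(J) - sum(phi * log(seq_len(J))) - sum(lfactorial(phi)) +
    S * log(theta) - sum(log(theta + seq_len(J) - 1))
}

# brute-force BH step-up: q_(i) = min over j >= i of m p_(j) / j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(pmin((m / (i:m)) * p[ord][i:m], 1))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Welch t on relative abundances, one taxon, coded independently
welch_t_oracle <- function(xa, xb) {
  num <- mean(xa) - mean(xb)
  den <- sqrt(var(xa) / length(xa) + var(xb) / length(xb))
  if (den == 0) 0 else num / den
}

# brute-force greedy MRT: at each step exhaustively enumerate every
# (leaf, variable, threshold), apply the same maximal-decrease rule with
# (variable order, lower threshold) tie-breaks, and split until max_leaves
brute_greedy_mrt <- function(D, X, max_leaves = 3, min_node = 2) {
  n <- nrow(D)
  imp <- function(ix) {
    if (length(ix) < 2L) return(0)
    tot <- 0
    for (i in ix) for (j in ix) tot <- tot + D[i, j]^2
    tot / 2 / length(ix)
  }
  all_splits <- function(ix) {
    out <- list()
    for (v in seq_len(ncol(X))) {
      u <- sort(unique(X[ix, v]))
      if (length(u) < 2L) next
      for (thr in (u[-length(u)] + u[-1]) / 2) {
        l <- ix[X[ix, v] <= thr]
        r <- ix[X[ix, v] > thr]
        if (length(l) >= min_node && length(r) >= min_node) {
          out <- c(out, list(list(v = v, thr = thr, l = l, r = r,
                                  dec = imp(ix) - imp(l) - imp(r))))
        }
      }
    }
    out
  }
  leaves <- list(seq_len(n))
  splits <- list()
  while (length(leaves) < max_leaves) {
    best <- NULL
    for (k in seq_along(leaves)) {
      for (s in all_splits(leaves[[k]])) {
        if (is.null(best) || s$dec > best$s$dec + 1e-12) {
          best <- list(k = k, s = s)
        }
      }
    }
    if (is.null(best) || best$s$dec <= 1e-12) break
    leaves <- append(leaves[-best$k], list(best$s$l, best$s$r),
                     after = best$k - 1L)
    splits <- c(splits, list(c(best$s$v, best$s$thr)))
  }
  list(leaves = leaves, splits = splits)
}

canonical_partition <- function(parts) {
  paste(sort(vapply(parts, function(p) paste(sort(p), collapse = ","),
                    character(1))), collapse = "|")
}

# small wide count tibble from a named matrix
as_count_tbl <- function(m) {
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                   tibble::as_tibble(as.data.frame(m)))
}

# 4-sample, 10-OTU toy community used by several io tests
toy_counts <- function() {
  m <- matrix(c(
    3, 5, 0, 2, 1, 0, 4, 0, 1, 2,
    1, 0, 2, 0, 3, 1, 0, 5, 0, 0,
    0, 2, 2, 1, 0, 4, 1, 0, 3, 1,
    2, 1, 1, 0, 2, 0, 0, 3, 1, 4), nrow = 4, byrow = TRUE,
    dimnames = list(paste0("s", 1:4), paste0("otu", 1:10)))
  as_count_tbl(m)
}

toy_taxonomy <- function() {
  tibble::tibble(
    taxon_id = paste0("otu", 1:10),
    kingdom = "Bacteria",
    phylum = "B_phylum",
    class = "unclassified",
    order = rep(c("OrderA", "OrderB"), each = 5),
    family = "unclassified",
    genus = c("Burkholderia", "Burkholderia", "Pseudomonas", "Luteibacter",
              "Acidicapsa", "unclassified", "Pseudomonas", "unclassified",
              "Granulicella", "Acidicapsa"))
}
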