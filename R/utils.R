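# Shared numerical helpers. Everything here is internal.

# log(exp(x) + exp(y)), elementwise, -Inf safe
logaddexp <- function(x, y) {
  m <- pmax(x, y)
  out <- m + log1p(exp(pmin(x, y) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (is.infinite(m) && m < 0) return(-Inf)
  m + log(sum(exp(x - m)))
}

# Deterministic substream derivation: a global seed plus a small integer
# counter yields an independent-looking child seed, kept below 2^31.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 16807 + 11) %%
               2147483647)
}

with_substream <- function(seed, counter, expr) {
  withr::with_seed(derive_seed(seed, counter), expr)
}

is_count_tbl <- function(x) {
  is.data.frame(x) && ncol(x) >= 1L && names(x)[1] == "sample_id"
}

# Wide count tibble (sample_id + one column per taxon) -> integer matrix
count_tbl_to_matrix <- function(counts) {
  stopifnot(is_count_tbl(counts))
  m <- as.matrix(counts[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(counts$sample_id)
  m
}

matrix_to_count_tbl <- function(m) {
  tibble::as_tibble(m, rownames = "sample_id")
}

check_counts_nonneg <- function(m, what = "count table") {
  if (anyNA(m)) abort(paste0(what, " contains missing values"))
  if (any(m < 0)) abort(paste0(what, " contains negative entries"))
  invisible(m)
}
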