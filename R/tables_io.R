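#' Read a taxon count table
#'
#' Reads a tab-separated count table into a wide count tibble: one row per
#' sample, first column `sample_id`, one integer column per taxon. The
#' on-disk layout is declared explicitly because both conventions are common
#' in amplicon workflows: `"samples_rows"` expects samples down the first
#' column (header cell `#SampleID`), `"samples_cols"` expects taxa down the
#' first column (header cell `#TaxonID`) and transposes on read.
#'
#' Empty cells are read as 0. Any cell that is not a non-negative integer is
#' an error naming the offending row and column; duplicate sample or taxon
#' identifiers are an error.
#'
#' @param path Path to a UTF-8 TSV file.
#' @param orientation `"samples_rows"` (default) or `"samples_cols"`.
#' @return A count tibble (`sample_id` + one column per taxon).
#' @seealso [write_count_table()], [aggregate_taxa()]
#' @export
read_count_table <- function(path, orientation = c("samples_rows", "samples_cols")) {
  orientation <- match.arg(orientation)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  if (ncol(raw) < 2L) abort("count table needs a header column plus at least one data column")
  row_ids <- as.character(raw[[1]])
  col_ids <- names(raw)[-1]
  if (anyDuplicated(row_ids)) {
    abort(paste0("duplicate identifiers in first column: ",
                 paste(unique(row_ids[duplicated(row_ids)]), collapse = ", ")))
  }
  if (anyDuplicated(col_ids)) {
    abort(paste0("duplicate identifiers in header: ",
                 paste(unique(col_ids[duplicated(col_ids)]), collapse = ", ")))
  }
  cells <- as.matrix(raw[, -1, drop = FALSE])
  cells[cells == ""] <- "0"
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- is.na(num) | num < 0 | num != floor(num)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("cell (%s, %s) = \"%s\" is not a non-negative integer",
                  row_ids[idx[1]], col_ids[idx[2]], cells[idx[1], idx[2]]))
  }
  dimnames(num) <- list(row_ids, col_ids)
  if (orientation == "samples_cols") num <- t(num)
  matrix_to_count_tbl(num)
}

#' Write a taxon count table
#'
#' Inverse of [read_count_table()]: writes the wide count tibble as TSV in
#' the requested orientation, with header cell `#SampleID` (samples as rows)
#' or `#TaxonID` (samples as columns). Reading the file back with the same
#' orientation reproduces the input exactly.
#'
#' @param counts A count tibble.
#' @inheritParams read_count_table
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, orientation = c("samples_rows", "samples_cols")) {
  orientation <- match.arg(orientation)
  m <- count_tbl_to_matrix(counts)
  check_counts_nonneg(m)
  if (orientation == "samples_cols") {
    out <- tibble::as_tibble(t(m), rownames = "#TaxonID")
  } else {
    out <- tibble::as_tibble(m, rownames = "#SampleID")
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

tax_ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
tax_prefixes <- c(kingdom = "k__", phylum = "p__", class = "c__",
                  order = "o__", family = "f__", genus = "g__")

#' Read a taxonomy lineage map
#'
#' Reads a two-column TSV of `taxon_id` and a QIIME-style lineage string
#' (`k__...;p__...;c__...;o__...;f__...;g__...`) into a tibble with one
#' column per rank (kingdom to genus). Ranks missing from the lineage are
#' filled with `"unclassified"`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `taxon_id`, `kingdom`, `phylum`, `class`,
#'   `order`, `family`, `genus`.
#' @export
read_taxonomy <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("taxon_id", "lineage"),
                         col_types = "cc", skip = 0, progress = FALSE)
  if (raw$taxon_id[1] %in% c("#TaxonID", "taxon_id")) raw <- raw[-1, ]
  if (anyDuplicated(raw$taxon_id)) abort("duplicate taxon ids in taxonomy")
  parts <- strsplit(raw$lineage, ";", fixed = TRUE)
  lineages <- purrr::map(parts, function(p) {
    p <- trimws(p)
    vals <- setNames(rep("unclassified", length(tax_ranks)), tax_ranks)
    for (token in p) {
      hit <- which(startsWith(token, tax_prefixes))
      if (length(hit) != 1L) abort(paste0("unrecognized lineage token: ", token))
      name <- substring(token, 4L)
      if (nzchar(name)) vals[names(tax_prefixes)[hit]] <- name
    }
    vals
  })
  dplyr::bind_cols(tibble::tibble(taxon_id = raw$taxon_id),
                   tibble::as_tibble(do.call(rbind, lineages)))
}

#' Write a taxonomy lineage map
#'
#' @param taxonomy A taxonomy tibble as returned by [read_taxonomy()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  stopifnot(all(c("taxon_id", tax_ranks) %in% names(taxonomy)))
  lineage <- apply(as.matrix(taxonomy[, tax_ranks]), 1L, function(v) {
    v[v == "unclassified"] <- ""
    paste0(tax_prefixes, v, collapse = ";")
  })
  readr::write_tsv(tibble::tibble(taxon_id = taxonomy$taxon_id, lineage = lineage),
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

metadata_cols <- c("sample_id", "wood_density", "ph", "moisture",
                   "c_n_ratio", "ergosterol", "replicate_of")

#' Read per-sample wood metadata
#'
#' Reads the sample metadata TSV: `sample_id`, `wood_density` (g/cm3),
#' `ph`, `moisture` (% of dry mass), `c_n_ratio`, `ergosterol` (mg/kg,
#' a fungal-biomass proxy) and `replicate_of` (parent wood-sample id).
#' Basic domain checks are applied (density > 0, moisture >= 0,
#' C/N > 0).
#'
#' @param path Path to the TSV file.
#' @return A metadata tibble.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", wood_density = "d", ph = "d", moisture = "d",
    c_n_ratio = "d", ergosterol = "d", replicate_of = "c"), progress = FALSE)
  missing <- setdiff(metadata_cols, names(meta))
  if (length(missing)) abort(paste0("metadata is missing columns: ",
                                    paste(missing, collapse = ", ")))
  validate_metadata(meta)
  meta
}

validate_metadata <- function(meta) {
  if (anyDuplicated(meta$sample_id)) abort("duplicate sample ids in metadata")
  if (any(meta$wood_density <= 0, na.rm = TRUE)) abort("wood_density must be > 0")
  if (any(meta$moisture < 0, na.rm = TRUE)) abort("moisture must be >= 0")
  if (any(meta$c_n_ratio <= 0, na.rm = TRUE)) abort("c_n_ratio must be > 0")
  invisible(meta)
}

#' Write per-sample wood metadata
#'
#' @param metadata A metadata tibble (see [read_sample_metadata()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  readr::write_tsv(metadata[, metadata_cols], path, progress = FALSE)
  invisible(path)
}

#' Aggregate a count table to a taxonomic rank
#'
#' Sums taxa sharing the same name at the requested rank. Taxa that are
#' unclassified at that rank are pooled into one `"<kingdom>_unclassified_<rank>"`
#' taxon per kingdom rather than dropped, so per-sample totals (and hence
#' downstream relative abundances) are conserved exactly.
#'
#' @param counts A count tibble.
#' @param taxonomy A taxonomy tibble covering every taxon in `counts`.
#' @param rank One of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return A count tibble with one column per distinct name at `rank`.
#' @export
aggregate_taxa <- function(counts, taxonomy, rank = "genus") {
  rank <- match.arg(rank, tax_ranks)
  m <- count_tbl_to_matrix(counts)
  missing <- setdiff(colnames(m), taxonomy$taxon_id)
  if (length(missing)) {
    abort(paste0("taxa absent from the taxonomy map: ",
                 paste(missing, collapse = ", ")))
  }
  tax <- taxonomy[match(colnames(m), taxonomy$taxon_id), ]
  label <- tax[[rank]]
  pooled <- label == "unclassified"
  label[pooled] <- paste0(tax$kingdom[pooled], "_unclassified_", rank)
  groups <- factor(label, levels = unique(label))
  agg <- t(rowsum(t(m), group = groups))
  matrix_to_count_tbl(agg)
}

#' Average replicate samples into parent-level relative abundances
#'
#' Converts each replicate to relative abundances (count / replicate total)
#' and averages the replicates of each parent wood sample. Averaging on the
#' relative-abundance scale coincides with averaging raw counts when all
#' replicates share one rarefaction depth, and stays well-defined when they
#' do not. Output rows sum to 1.
#'
#' Parents listed in `metadata` with no replicate present in `counts` are
#' excluded with a warning; replicates with a zero total are an error.
#'
#' @param counts A count tibble of replicate-level samples.
#' @param metadata A metadata tibble with `sample_id` and `replicate_of`.
#' @return A tibble of relative abundances, `sample_id` holding parent ids.
#' @export
average_replicates <- function(counts, metadata) {
  m <- count_tbl_to_matrix(counts)
  check_counts_nonneg(m)
  idx <- match(rownames(m), metadata$sample_id)
  if (anyNA(idx)) {
    abort(paste0("samples missing from metadata: ",
                 paste(rownames(m)[is.na(idx)], collapse = ", ")))
  }
  parent <- metadata$replicate_of[idx]
  totals <- rowSums(m)
  if (any(totals == 0)) {
    abort(paste0("replicates with zero total counts: ",
                 paste(rownames(m)[totals == 0], collapse = ", ")))
  }
  rel <- m / totals
  orphan <- setdiff(unique(metadata$replicate_of), unique(parent))
  if (length(orphan)) {
    warn(paste0("parents with no replicates present, excluded: ",
                paste(orphan, collapse = ", ")))
  }
  groups <- factor(parent, levels = unique(parent))
  avg <- rowsum(rel, group = groups) / as.vector(table(groups))
  matrix_to_count_tbl(avg)
}
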