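#' Filter genera by representation
#'
#' Keeps genera with at least `min_representatives` across the table. By
#' default a representative is a sequence read (total count across samples,
#' `mode = "reads"`); `mode = "samples"` instead requires presence in at
#' least that many samples — the two readings of a "five or more
#' representatives" rule.
#'
#' @param counts A genus-aggregated count tibble.
#' @param min_representatives Threshold (default 5).
#' @param mode `"reads"` (default) or `"samples"`.
#' @return The filtered count tibble.
#' @export
filter_genera <- function(counts, min_representatives = 5,
                          mode = c("reads", "samples")) {
  mode <- match.arg(mode)
  m <- count_tbl_to_matrix(counts)
  keep <- if (mode == "reads") colSums(m) >= min_representatives else
    colSums(m > 0) >= min_representatives
  if (!any(keep)) {
    abort("no genus passes the representation filter; lower min_representatives")
  }
  matrix_to_count_tbl(m[, keep, drop = FALSE])
}

#' All-pairs Pearson correlations with significance
#'
#' Pearson correlation between every pair of genera across samples, with a
#' two-sided p-value from `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of
#' freedom. Genera with zero variance are excluded with a warning (their
#' correlation is undefined).
#'
#' @param abund A tibble of abundances (typically replicate-averaged
#'   relative abundances) with `sample_id` first; at least 4 samples.
#' @return A list with symmetric matrices `r` and `p` (unit diagonal /
#'   zero-diagonal p), and `n` the sample count.
#' @export
correlation_matrix <- function(abund) {
  m <- count_tbl_to_matrix(abund)
  n <- nrow(m)
  if (n < 4L) abort("need at least 4 samples for correlation p-values")
  sds <- apply(m, 2L, sd)
  if (any(sds == 0)) {
    warn(paste0("excluding constant genera: ",
                paste(colnames(m)[sds == 0], collapse = ", ")))
    m <- m[, sds > 0, drop = FALSE]
  }
  r <- cor(m)
  rr <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- rr * sqrt((n - 2) / (1 - rr^2))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  list(r = r, p = p, n = n)
}

#' Build a co-occurrence network from correlation matrices
#'
#' Edges are unordered genus pairs with `|r| > abs_r` (strict, so r equal
#' to the threshold is excluded) and `p < p_max`; when `use_fdr = TRUE`
#' (default) the off-diagonal p-values are additionally
#' Benjamini-Hochberg-adjusted and the q-value must pass `q_max`. Nodes are
#' the genera incident to at least one edge — isolated genera do not enter
#' the network.
#'
#' @param corr A list from [correlation_matrix()] (or matching `r`/`p`
#'   matrices in a list).
#' @param abs_r Absolute-correlation threshold (default 0.80).
#' @param p_max Raw p-value threshold (default 0.05).
#' @param use_fdr Apply BH correction across all pairs?
#' @param q_max q-value threshold when `use_fdr` (default 0.05).
#' @param kingdom Optional named character vector genus -> kingdom tag
#'   carried onto the nodes.
#' @return A `co_network` object: tibbles `nodes` (genus, kingdom, degree)
#'   and `edges` (genus_a, genus_b, r, p, q, sign).
#' @export
build_network <- function(corr, abs_r = 0.80, p_max = 0.05, use_fdr = TRUE,
                          q_max = 0.05, kingdom = NULL) {
  r <- corr$r; p <- corr$p
  if (!all(dim(r) == dim(p))) abort("r and p matrices do not match")
  genera <- colnames(r)
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  er <- r[pairs]; ep <- p[pairs]
  eq <- benjamini_hochberg(ep)
  keep <- abs(er) > abs_r & ep < p_max
  if (use_fdr) keep <- keep & eq < q_max
  edges <- tibble::tibble(
    genus_a = genera[pairs[keep, 1]],
    genus_b = genera[pairs[keep, 2]],
    r = er[keep], p = ep[keep], q = eq[keep],
    sign = ifelse(er[keep] > 0, "positive", "negative"))
  connected <- sort(unique(c(edges$genus_a, edges$genus_b)))
  degree <- vapply(connected, function(g) {
    sum(edges$genus_a == g) + sum(edges$genus_b == g)
  }, numeric(1))
  nodes <- tibble::tibble(
    genus = connected,
    kingdom = if (is.null(kingdom)) NA_character_ else
      unname(kingdom[connected]),
    degree = as.integer(degree))
  structure(list(nodes = nodes, edges = edges,
                 thresholds = list(abs_r = abs_r, p_max = p_max,
                                   use_fdr = use_fdr, q_max = q_max)),
            class = "co_network")
}

#' @method print co_network
#' @export
print.co_network <- function(x, ...) {
  s <- network_stats(x)
  cat(sprintf("<co_network> %d nodes, %d edges, average degree %.2f\n",
              s$n_nodes, s$n_edges, s$average_degree))
  invisible(x)
}

#' @rdname build_network
#' @param x A `co_network`.
#' @param ... Unused.
#' @method tidy co_network
#' @export
tidy.co_network <- function(x, ...) x$edges

#' @rdname build_network
#' @method glance co_network
#' @export
glance.co_network <- function(x, ...) {
  s <- network_stats(x)
  tibble::tibble(n_nodes = s$n_nodes, n_edges = s$n_edges,
                 average_degree = s$average_degree)
}

#' Degree statistics of a co-occurrence network
#'
#' Node degree (incident edges), the network's average degree `2 E / N`,
#' and the key nodes — genera ranked by descending degree, ties
#' alphabetical — whose many correlations mark them as hubs.
#'
#' @param net A `co_network` from [build_network()].
#' @return A list: `n_nodes`, `n_edges`, `average_degree`, `degree`
#'   (named vector) and `key_nodes` (tibble genus/degree in rank order).
#' @export
network_stats <- function(net) {
  n_nodes <- nrow(net$nodes); n_edges <- nrow(net$edges)
  if (n_nodes == 0L) {
    return(list(n_nodes = 0L, n_edges = 0L, average_degree = 0,
                degree = setNames(numeric(0), character(0)),
                key_nodes = tibble::tibble(genus = character(),
                                           degree = integer())))
  }
  ord <- order(-net$nodes$degree, net$nodes$genus)
  list(n_nodes = n_nodes, n_edges = n_edges,
       average_degree = 2 * n_edges / n_nodes,
       degree = setNames(net$nodes$degree, net$nodes$genus),
       key_nodes = net$nodes[ord, c("genus", "degree")])
}

#' Export a network for Cytoscape
#'
#' Writes an edge-list TSV (source, target, r, p, q, sign), a
#' node-attribute TSV (genus, kingdom, degree) and a GraphML file, all
#' loadable by Cytoscape.
#'
#' @param net A `co_network`.
#' @param prefix Output path prefix; writes `<prefix>_edges.tsv`,
#'   `<prefix>_nodes.tsv`, `<prefix>.graphml`.
#' @return The three paths, invisibly.
#' @export
export_network <- function(net, prefix) {
  edge_path <- paste0(prefix, "_edges.tsv")
  node_path <- paste0(prefix, "_nodes.tsv")
  graphml_path <- paste0(prefix, ".graphml")
  readr::write_tsv(dplyr::rename(net$edges, source = "genus_a",
                                 target = "genus_b"),
                   edge_path, progress = FALSE)
  readr::write_tsv(net$nodes, node_path, progress = FALSE)
  g <- igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = data.frame(name = net$nodes$genus,
                          kingdom = ifelse(is.na(net$nodes$kingdom), "",
                                           net$nodes$kingdom),
                          degree = net$nodes$degree))
  igraph::write_graph(g, graphml_path, format = "graphml")
  invisible(c(edge_path, node_path, graphml_path))
}

#' Scatter-style plot of a co-occurrence network
#'
#' Simple ggplot rendering: nodes on a deterministic circular layout,
#' edges drawn solid for positive and dashed for negative correlations.
#'
#' @param object A `co_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot co_network
#' @export
autoplot.co_network <- function(object, ...) {
  nodes <- object$nodes
  if (!nrow(nodes)) abort("network has no nodes to plot")
  ang <- seq(0, 2 * pi, length.out = nrow(nodes) + 1)[seq_len(nrow(nodes))]
  layout <- tibble::tibble(genus = nodes$genus, x = cos(ang), y = sin(ang),
                           kingdom = nodes$kingdom, degree = nodes$degree)
  ed <- object$edges |>
    dplyr::left_join(layout[, c("genus", "x", "y")],
                     by = c(genus_a = "genus")) |>
    dplyr::left_join(layout[, c("genus", "x", "y")],
                     by = c(genus_b = "genus"), suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$sign),
      colour = "grey50") +
    ggplot2::geom_point(data = layout,
      ggplot2::aes(.data$x, .data$y, size = .data$degree,
                   colour = .data$kingdom)) +
    ggplot2::theme_void()
}
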