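#' Fit a multivariate regression tree on community dissimilarity
#'
#' Greedy recursive binary partitioning of samples by thresholds on
#' environmental covariates, minimizing within-node community
#' heterogeneity. Node impurity is the distance-based surrogate for the
#' sum of squares about the centroid,
#' `sum_{i<j in node} d(i,j)^2 / n_node`, with `d` the Bray-Curtis
#' dissimilarity by default (`distance = "euclidean"` uses Euclidean
#' distances on the abundance rows instead). Each split maximizes the
#' impurity decrease over all (covariate, threshold) pairs, where candidate
#' thresholds are midpoints between consecutive sorted unique covariate
#' values; ties are broken deterministically by covariate order then lower
#' threshold. Splitting stops at `max_leaves`, when no split leaves both
#' children with at least `min_node_size` samples, or when no split
#' decreases impurity.
#'
#' @param community A count/abundance tibble, or a precomputed symmetric
#'   dissimilarity matrix with sample ids as dimnames.
#' @param env A data frame with `sample_id` plus numeric covariate columns;
#'   must cover every sample in `community`.
#' @param max_leaves Maximum number of leaves (default 3, one per decay
#'   stage).
#' @param min_node_size Minimum samples per leaf.
#' @param distance `"bray"` or `"euclidean"` (ignored when `community` is
#'   already a dissimilarity matrix).
#' @return A `decay_mrt` object with `tidy()`/`glance()` methods.
#' @seealso [assign_stages()]
#' @export
fit_mrt <- function(community, env, max_leaves = 3, min_node_size = 2,
                    distance = c("bray", "euclidean")) {
  distance <- match.arg(distance)
  if (is.matrix(community) && nrow(community) == ncol(community) &&
      isTRUE(all.equal(community, t(community), tolerance = 1e-8))) {
    D <- community
  } else {
    D <- if (distance == "bray") bray_curtis(community) else
      as.matrix(stats::dist(count_tbl_to_matrix(community)))
  }
  ids <- rownames(D)
  if (is.null(ids)) abort("dissimilarity matrix needs sample ids as dimnames")
  vars <- setdiff(names(env), c("sample_id", "replicate_of"))
  vars <- vars[vapply(env[vars], is.numeric, logical(1))]
  if (!length(vars)) abort("env has no numeric covariate columns")
  idx <- match(ids, env$sample_id)
  if (anyNA(idx)) {
    abort(paste0("samples missing from env: ", paste(ids[is.na(idx)], collapse = ", ")))
  }
  X <- as.matrix(env[idx, vars, drop = FALSE])
  n <- length(ids)
  if (n < 2 * min_node_size) abort("too few samples to split")
  D2 <- D^2
  impurity <- function(members) {
    if (length(members) < 2L) return(0)
    sum(D2[members, members]) / 2 / length(members)
  }
  best_split_of <- function(members) {
    best <- NULL
    node_imp <- impurity(members)
    for (v in seq_along(vars)) {
      x <- X[members, v]
      u <- sort(unique(x))
      if (length(u) < 2L) next
      for (thr in (head(u, -1) + u[-1]) / 2) {
        left <- members[x <= thr]
        right <- members[x > thr]
        if (length(left) < min_node_size || length(right) < min_node_size) next
        dec <- node_imp - impurity(left) - impurity(right)
        if (is.null(best) || dec > best$decrease + 1e-12) {
          best <- list(variable = vars[v], threshold = thr,
                       left = left, right = right, decrease = dec)
        }
      }
    }
    best
  }

  constant_env <- all(vapply(vars, function(v) length(unique(X[, v])) == 1L,
                             logical(1)))
  if (constant_env) warn("all covariates are constant; returning a single leaf")

  # leaves as member index vectors carrying their ancestor split path;
  # grow greedily, always taking the single best (leaf, variable, threshold)
  leaves <- list(list(members = seq_len(n), split = NULL, path = list()))
  while (length(leaves) < max_leaves && !constant_env) {
    for (i in seq_along(leaves)) {
      if (is.null(leaves[[i]]$split) && !isTRUE(leaves[[i]]$tried)) {
        leaves[[i]]$split <- best_split_of(leaves[[i]]$members)
        leaves[[i]]$tried <- TRUE
      }
    }
    gains <- vapply(leaves, function(l) {
      if (is.null(l$split) || l$split$decrease <= 1e-12) -Inf else l$split$decrease
    }, numeric(1))
    if (all(!is.finite(gains))) break
    k <- which.max(gains)
    sp <- leaves[[k]]$split
    node <- leaves[[k]]
    cond <- function(side) list(variable = sp$variable,
                                threshold = sp$threshold, side = side)
    leaves[[k]] <- NULL
    leaves <- append(leaves, list(
      list(members = sp$left, split = NULL,
           path = c(node$path, list(cond("left")))),
      list(members = sp$right, split = NULL,
           path = c(node$path, list(cond("right"))))),
      after = k - 1L)
  }

  splits <- collect_splits(leaves)
  structure(list(
    leaves = purrr::map(leaves, function(l) ids[l$members]),
    leaf_paths = purrr::map(leaves, "path"),
    splits = splits,
    leaf_impurity = vapply(leaves, function(l) impurity(l$members), numeric(1)),
    total_impurity = sum(vapply(leaves, function(l) impurity(l$members), numeric(1))),
    variables = vars, sample_ids = ids, env = env[idx, c("sample_id", vars)],
    distance = distance, max_leaves = max_leaves,
    min_node_size = min_node_size), class = "decay_mrt")
}

# flatten the leaf ancestry into an ordered split table
collect_splits <- function(leaves) {
  rows <- purrr::map_dfr(leaves, function(l) {
    purrr::map_dfr(l$path, function(cond) {
      tibble::tibble(variable = cond$variable, threshold = cond$threshold)
    })
  })
  if (!nrow(rows)) {
    return(tibble::tibble(variable = character(), threshold = numeric()))
  }
  dplyr::distinct(rows)
}

#' @method print decay_mrt
#' @export
print.decay_mrt <- function(x, ...) {
  cat(sprintf("<decay_mrt> %d leaves, total impurity %.4f (%s distance)\n",
              length(x$leaves), x$total_impurity, x$distance))
  for (i in seq_along(x$leaves)) {
    cat(sprintf("  leaf %d: n = %d, impurity %.4f\n", i,
                length(x$leaves[[i]]), x$leaf_impurity[i]))
  }
  if (nrow(x$splits)) {
    cat("  splits:\n")
    for (i in seq_len(nrow(x$splits))) {
      cat(sprintf("    %s <= %.4g\n", x$splits$variable[i], x$splits$threshold[i]))
    }
  }
  invisible(x)
}

#' @rdname fit_mrt
#' @param x A `decay_mrt` object.
#' @param ... Unused.
#' @method tidy decay_mrt
#' @export
tidy.decay_mrt <- function(x, ...) {
  tibble::tibble(
    leaf = seq_along(x$leaves),
    n = lengths(x$leaves),
    impurity = x$leaf_impurity,
    sample_ids = purrr::map_chr(x$leaves, paste, collapse = ","))
}

#' @rdname fit_mrt
#' @method glance decay_mrt
#' @export
glance.decay_mrt <- function(x, ...) {
  tibble::tibble(n_leaves = length(x$leaves),
                 total_impurity = x$total_impurity,
                 n_splits = nrow(x$splits),
                 distance = x$distance)
}

#' Assign decay-stage labels from a fitted tree
#'
#' Routes each sample of `env` down the fitted tree and names the leaves by
#' descending mean wood density — `early` for the densest leaf, then
#' `middle`, `late`, and `stage4`, `stage5`, ... should the tree have more
#' leaves. Routing reuses the training partition's split structure: a
#' sample follows each recorded split by comparing its covariate value with
#' the threshold.
#'
#' @param tree A `decay_mrt` from [fit_mrt()].
#' @param env A data frame with `sample_id`, the tree's split covariates
#'   and `wood_density`.
#' @return A tibble `sample_id`, `leaf`, `stage`.
#' @export
assign_stages <- function(tree, env) {
  missing_var <- setdiff(tree$splits$variable, names(env))
  if (length(missing_var)) {
    abort(paste0("env lacks split variables: ", paste(missing_var, collapse = ", ")))
  }
  if (anyNA(env[, unique(tree$splits$variable), drop = FALSE])) {
    abort("missing values in split variables")
  }
  # a sample belongs to the leaf whose ancestor half-spaces all contain it;
  # the paths partition covariate space, so exactly one leaf matches
  leaf_of <- function(row) {
    for (k in seq_along(tree$leaf_paths)) {
      ok <- all(vapply(tree$leaf_paths[[k]], function(cond) {
        v <- row[[cond$variable]]
        if (cond$side == "left") v <= cond$threshold else v > cond$threshold
      }, logical(1)))
      if (ok) return(k)
    }
    NA_integer_
  }
  leaf <- vapply(seq_len(nrow(env)), function(i) leaf_of(env[i, ]), integer(1))
  if (anyNA(leaf)) abort("some samples could not be routed to a leaf")
  dens <- if ("wood_density" %in% names(env)) env$wood_density else
    rep(NA_real_, nrow(env))
  mean_dens <- vapply(seq_along(tree$leaves), function(k) {
    mean(dens[leaf == k], na.rm = TRUE)
  }, numeric(1))
  ord <- order(-mean_dens)
  stage_names <- c("early", "middle", "late",
                   if (length(tree$leaves) > 3)
                     paste0("stage", 4:length(tree$leaves)))
  stage_by_leaf <- character(length(tree$leaves))
  stage_by_leaf[ord] <- stage_names[seq_along(ord)]
  tibble::tibble(sample_id = env$sample_id, leaf = leaf,
                 stage = stage_by_leaf[leaf])
}
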