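#' Assemble a pipeline configuration
#'
#' Collects input paths, per-stage parameters and the global seed for
#' [run_pipeline()]. Defaults follow the study design the package models:
#' bacterial tables rarefied to 1,080 reads per sample and fungal to
#' 2,000; a three-leaf regression tree on Bray-Curtis dissimilarity;
#' 1,000 permutations for differential abundance; network thresholds
#' |r| > 0.80 with BH-adjusted p < 0.05; genus filter at 5 reads.
#'
#' @param bacteria,fungi,taxonomy,metadata Paths to the four input TSVs
#'   (see [read_count_table()], [read_taxonomy()],
#'   [read_sample_metadata()]).
#' @param out_dir Output directory for all result files.
#' @param bacterial_depth,fungal_depth Rarefaction depths.
#' @param max_leaves,min_node_size Regression-tree size controls.
#' @param n_perm Permutations for [metastats_test()].
#' @param abs_r,p_max,use_fdr,q_max Network thresholds ([build_network()]).
#' @param min_representatives,filter_mode Genus filter ([filter_genera()]).
#' @param sad_margin,sad_scoring Assembly-comparison controls
#'   ([compare_models()]).
#' @param seed Global integer seed; every stochastic step derives a
#'   substream from it.
#' @param skip Character vector of stages to skip (any of `"diversity"`,
#'   `"stages"`, `"diffabund"`, `"network"`, `"sad"`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(bacteria, fungi, taxonomy, metadata, out_dir,
                            bacterial_depth = 1080, fungal_depth = 2000,
                            max_leaves = 3, min_node_size = 2,
                            n_perm = 1000,
                            abs_r = 0.80, p_max = 0.05, use_fdr = TRUE,
                            q_max = 0.05,
                            min_representatives = 5,
                            filter_mode = "reads",
                            sad_margin = 2, sad_scoring = "rank_poisson",
                            seed = 1, skip = character(0)) {
  cfg <- as.list(environment())
  if (cfg$bacterial_depth <= 0 || cfg$fungal_depth <= 0) {
    abort("rarefaction depths must be positive")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full decay-succession pipeline
#'
#' Executes, in order: per-kingdom rarefaction (samples below depth are
#' excluded from that kingdom only, and logged), alpha diversity with
#' diversity-versus-density regressions, decay-stage partitioning by
#' multivariate regression tree on parent-averaged bacterial communities,
#' per-stage-pair genus-level differential abundance, per-stage and global
#' genus co-occurrence networks across both kingdoms, and per-sample
#' neutral-versus-niche assembly classification. All outputs (TSV, JSON,
#' GraphML) plus a manifest recording the configuration, seed and every
#' exclusion are written under `config$out_dir`; outputs are a pure
#' function of inputs, configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the in-memory results (`diversity`,
#'   `regressions`, `stages`, `diffabund`, `networks`, `sad`, `manifest`).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logs <- character(0)
  log_line <- function(...) {
    logs <<- c(logs, paste0(...))
  }
  res <- list()

  counts <- list(bacteria = read_count_table(cfg$bacteria),
                 fungi = read_count_table(cfg$fungi))
  taxonomy <- read_taxonomy(cfg$taxonomy)
  metadata <- read_sample_metadata(cfg$metadata)
  depths <- c(bacteria = cfg$bacterial_depth, fungi = cfg$fungal_depth)

  # --- rarefaction with per-kingdom exclusion ---------------------------
  excluded <- list()
  rarefied <- list()
  for (k in names(counts)) {
    m <- count_tbl_to_matrix(counts[[k]])
    short <- rowSums(m) < depths[[k]]
    excluded[[k]] <- rownames(m)[short]
    if (all(short)) {
      abort(sprintf("stage rarefy (%s): every sample is below depth %d: %s",
                    k, depths[[k]], paste(rownames(m), collapse = ", ")))
    }
    if (any(short)) {
      log_line("stage=rarefy kingdom=", k, " excluded=",
               paste(excluded[[k]], collapse = ","))
    }
    kept <- counts[[k]][!short, ]
    rarefied[[k]] <- rarefy(kept, depths[[k]],
                            seed = derive_seed(cfg$seed, match(k, names(counts))))
    log_line("stage=rarefy kingdom=", k, " samples_in=", nrow(m),
             " samples_out=", nrow(rarefied[[k]]), " depth=", depths[[k]])
    write_count_table(rarefied[[k]],
                      file.path(cfg$out_dir, paste0(k, "_rarefied.tsv")))
  }

  # --- diversity + regressions ------------------------------------------
  if (!"diversity" %in% cfg$skip) {
    res$diversity <- purrr::imap(rarefied, function(tbl, k) diversity_table(tbl))
    res$regressions <- purrr::imap_dfr(res$diversity, function(d, k) {
      dplyr::bind_cols(tibble::tibble(kingdom = k),
                       regress_diversity(d, metadata))
    })
    for (k in names(res$diversity)) {
      readr::write_tsv(res$diversity[[k]],
                       file.path(cfg$out_dir, paste0("diversity_", k, ".tsv")),
                       progress = FALSE)
    }
    readr::write_tsv(res$regressions, file.path(cfg$out_dir, "regressions.tsv"),
                     progress = FALSE)
    log_line("stage=diversity kingdoms=", length(res$diversity))
  }

  # --- MRT staging on parent-averaged bacterial communities -------------
  parent_meta <- metadata |>
    dplyr::distinct(.data$replicate_of, .keep_all = TRUE) |>
    dplyr::mutate(sample_id = .data$replicate_of)
  if (!"stages" %in% cfg$skip) {
    bact_avg <- average_replicates(rarefied$bacteria, metadata)
    env <- parent_meta[parent_meta$sample_id %in% bact_avg$sample_id, ]
    tree <- fit_mrt(bact_avg, env, max_leaves = cfg$max_leaves,
                    min_node_size = cfg$min_node_size)
    parent_stages <- assign_stages(tree, env)
    res$tree <- tree
    res$stages <- metadata |>
      dplyr::select("sample_id", "replicate_of") |>
      dplyr::left_join(parent_stages |>
                         dplyr::rename(replicate_of = "sample_id"),
                       by = "replicate_of")
    readr::write_tsv(res$stages, file.path(cfg$out_dir, "stages.tsv"),
                     progress = FALSE)
    jsonlite::write_json(
      list(splits = tree$splits, leaves = tree$leaves,
           leaf_impurity = tree$leaf_impurity),
      file.path(cfg$out_dir, "mrt.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    writeLines(utils::capture.output(print(tree)),
               file.path(cfg$out_dir, "mrt.txt"))
    log_line("stage=mrt leaves=", length(tree$leaves), " splits=",
             nrow(tree$splits))
  }

  stage_of_parent <- if (!is.null(res$stages)) {
    res$stages |>
      dplyr::distinct(.data$replicate_of, .data$stage)
  } else NULL

  # --- genus aggregation shared by diffabund and networks ---------------
  genus <- purrr::map(rarefied, aggregate_taxa, taxonomy = taxonomy,
                      rank = "genus")
  genus_avg <- purrr::map(genus, average_replicates, metadata = metadata)

  # --- per-stage-pair differential abundance (bacteria, genus level) ----
  if (!"diffabund" %in% cfg$skip && !is.null(stage_of_parent)) {
    pairs <- combn(sort(unique(stage_of_parent$stage)), 2, simplify = FALSE)
    res$diffabund <- purrr::imap(pairs, function(pr, pair_idx) {
      grp <- stage_of_parent[stage_of_parent$stage %in% pr, ]
      tbl <- genus_avg$bacteria[genus_avg$bacteria$sample_id %in%
                                  grp$replicate_of, ]
      if (length(unique(grp$stage)) < 2L || nrow(tbl) < 4L) return(NULL)
      out <- withCallingHandlers(
        metastats_test(
          tbl, setNames(grp$stage, grp$replicate_of), n_perm = cfg$n_perm,
          seed = derive_seed(cfg$seed, 10L + pair_idx)),
        warning = function(w) {
          log_line("stage=diffabund pair=", pr[1], "-", pr[2], " note=",
                   conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      readr::write_tsv(out, file.path(cfg$out_dir,
                                      sprintf("diffabund_%s_vs_%s.tsv",
                                              pr[1], pr[2])),
                       progress = FALSE)
      log_line("stage=diffabund pair=", pr[1], "-", pr[2], " taxa=", nrow(out))
      out
    })
    names(res$diffabund) <- purrr::map_chr(pairs, paste, collapse = "_vs_")
  }

  # --- co-occurrence networks -------------------------------------------
  if (!"network" %in% cfg$skip) {
    genus_kingdom <- taxonomy |>
      dplyr::distinct(.data$genus, .data$kingdom)
    kingdom_of <- setNames(genus_kingdom$kingdom, genus_kingdom$genus)
    filt <- purrr::map(genus, filter_genera,
                       min_representatives = cfg$min_representatives,
                       mode = cfg$filter_mode)
    filt_avg <- purrr::map(filt, average_replicates, metadata = metadata)
    combined <- dplyr::inner_join(filt_avg$bacteria, filt_avg$fungi,
                                  by = "sample_id")
    make_net <- function(tbl, label) {
      net <- withCallingHandlers(
        build_network(correlation_matrix(tbl), abs_r = cfg$abs_r,
                      p_max = cfg$p_max, use_fdr = cfg$use_fdr,
                      q_max = cfg$q_max, kingdom = kingdom_of),
        warning = function(w) invokeRestart("muffleWarning"))
      export_network(net, file.path(cfg$out_dir, paste0("network_", label)))
      s <- network_stats(net)
      log_line("stage=network scope=", label, " nodes=", s$n_nodes,
               " edges=", s$n_edges,
               " thresholds=|r|>", cfg$abs_r,
               if (cfg$use_fdr) paste0(",q<", cfg$q_max) else
                 paste0(",p<", cfg$p_max))
      net
    }
    res$networks <- list(all = make_net(combined, "all"))
    if (!is.null(stage_of_parent)) {
      for (st in sort(unique(stage_of_parent$stage))) {
        members <- stage_of_parent$replicate_of[stage_of_parent$stage == st]
        tbl <- combined[combined$sample_id %in% members, ]
        if (nrow(tbl) < 4L) {
          log_line("stage=network scope=", st,
                   " skipped=too_few_samples n=", nrow(tbl))
          next
        }
        res$networks[[st]] <- make_net(tbl, st)
      }
    }
  }

  # --- neutral vs niche assembly per sample -----------------------------
  if (!"sad" %in% cfg$skip) {
    res$sad <- purrr::imap(rarefied, function(tbl, k) {
      out <- sad_comparison_table(tbl, margin = cfg$sad_margin,
                                  scoring = cfg$sad_scoring)
      if (!is.null(res$stages)) {
        out <- dplyr::left_join(out,
                                res$stages[, c("sample_id", "stage")],
                                by = "sample_id")
      }
      readr::write_tsv(out, file.path(cfg$out_dir, paste0("sad_", k, ".tsv")),
                       progress = FALSE)
      log_line("stage=sad kingdom=", k, " samples=", nrow(out))
      out
    })
  }

  # --- summary + manifest -----------------------------------------------
  summary <- pipeline_summary(res)
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(config = unclass(cfg), excluded = excluded,
                   seed = cfg$seed)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(logs, file.path(cfg$out_dir, "log.txt"))
  res$manifest <- manifest
  res$summary <- summary
  invisible(res)
}

pipeline_summary <- function(res) {
  out <- list()
  if (!is.null(res$regressions)) {
    out$regressions <- res$regressions
  }
  if (!is.null(res$tree)) {
    out$mrt_splits <- res$tree$splits
    out$stage_sizes <- res$stages |>
      dplyr::distinct(.data$replicate_of, .data$stage) |>
      dplyr::count(.data$stage)
  }
  if (!is.null(res$networks)) {
    out$networks <- purrr::imap(res$networks, function(n, nm) {
      s <- network_stats(n)
      list(scope = nm, n_nodes = s$n_nodes, n_edges = s$n_edges,
           average_degree = s$average_degree)
    })
  }
  if (!is.null(res$sad)) {
    out$assembly <- purrr::imap(res$sad, function(tbl, k) {
      if ("stage" %in% names(tbl)) {
        tbl |>
          dplyr::count(.data$stage, .data$verdict) |>
          as.list()
      } else {
        tbl |> dplyr::count(.data$verdict) |> as.list()
      }
    })
  }
  out
}
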