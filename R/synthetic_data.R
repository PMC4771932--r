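#' Simulate one local community under Hubbell's neutral model
#'
#' Sequential urn construction of a local community of `J` individuals with
#' immigration parameter `I = m (J - 1) / (1 - m)`: individual `j` is an
#' immigrant with probability `I / (I + j - 1)`; immigrant ancestry follows
#' a Ewens(`theta`) urn over immigration events (a new metacommunity
#' species with probability `theta / (theta + k)` after `k` previous
#' immigration events, otherwise the species of a uniformly chosen previous
#' immigrant); a non-immigrant copies the species of a uniformly chosen
#' earlier local individual. At `m = 1` every individual is an immigrant
#' and the construction reduces to the Ewens urn. This is the sampling
#' counterpart of the ZSM likelihood in [zsm_loglik()].
#'
#' @param theta Fundamental biodiversity number, `> 0`.
#' @param m Immigration probability, in `(0, 1]`.
#' @param J Community size (positive integer).
#' @param seed Optional integer seed (uses its own substream).
#' @return Integer species abundances sorted descending, summing to `J`.
#' @export
simulate_neutral_sample <- function(theta, m, J, seed = NULL) {
  if (J < 1) abort("J must be >= 1")
  if (theta <= 0) abort("theta must be > 0")
  if (m <= 0 || m > 1) abort("m must be in (0, 1]")
  run <- function() {
    I <- if (m < 1) m * (J - 1) / (1 - m) else Inf
    species <- integer(J)
    imm_species <- integer(0)   # species of each immigration event so far
    n_species <- 0L
    for (j in seq_len(J)) {
      immigrant <- j == 1L || is.infinite(I) || runif(1) < I / (I + j - 1)
      if (immigrant) {
        k <- length(imm_species)
        if (k == 0L || runif(1) < theta / (theta + k)) {
          n_species <- n_species + 1L
          s <- n_species
        } else {
          s <- imm_species[sample.int(k, 1L)]
        }
        imm_species <- c(imm_species, s)
      } else {
        s <- species[sample.int(j - 1L, 1L)]
      }
      species[j] <- s
    }
    sort(tabulate(species, nbins = n_species), decreasing = TRUE)
  }
  if (is.null(seed)) run() else with_substream(seed, 0L, run())
}

#' Simulate one sample from a niche rank-abundance model
#'
#' Evaluates the model's expected abundances ([expected_abundance()]),
#' rescales them to sum exactly to `J`, then draws the observed abundance of
#' each rank independently as Poisson around its expectation — the same
#' error model under which the fitter operates. Ranks drawn at zero are
#' dropped, so the realized richness can fall below `S`.
#'
#' @inheritParams expected_abundance
#' @param seed Optional integer seed (uses its own substream).
#' @return Integer abundances sorted descending.
#' @export
simulate_niche_sample <- function(model, params = list(), S, J, seed = NULL) {
  lambda <- expected_abundance(model, params, S, J)
  lambda <- lambda * (J / sum(lambda))
  run <- function() {
    a <- rpois(S, lambda)
    sort(a[a > 0], decreasing = TRUE)
  }
  if (is.null(seed)) run() else with_substream(seed, 0L, run())
}

#' Configuration for the synthetic decay study
#'
#' Defaults emulate the processed-table level of a 19-sample, 3-replicate
#' pine-decay survey: a wood-density gradient from 0.50 down to
#' 0.15 g/cm3 with stage bands early > 0.40, middle 0.30-0.40 and
#' late < 0.30 g/cm3; bacterial replicate depths at or above 1,080 reads
#' and fungal at or above 2,000; bacterial richness rising as density falls
#' (~35 OTUs at 0.50 g/cm3, slope `richness_slope` OTUs per g/cm3 lost);
#' per-stage assembly mechanisms (early neutral, middle and late
#' niche-generated) providing ground truth for assembly classification;
#' each fungal sample dominated by its own phylotype; one indicator OTU
#' confined to each stage; and planted genus-genus correlations across
#' parents. Stage-level covariate means/sds mimic measured wood chemistry
#' (pH drop after the early stage, late-stage moisture surge, falling C/N,
#' rising ergosterol).
#'
#' @param bands Named density thresholds `c(early = , late = )`: early
#'   above the first, late below the second.
#' @param density_range Gradient endpoints (high to low, g/cm3).
#' @param density_jitter Half-width of uniform jitter on parent densities.
#' @param bacterial_depth,fungal_depth Rarefaction-target depths; replicate
#'   raw depths are drawn above these.
#' @param richness_base Bacterial richness at the top density.
#' @param richness_slope Added bacterial richness per g/cm3 of density loss.
#' @param stage_models Per-stage generating model for bacterial communities.
#' @param fungal_dominance Range of the dominant fungal phylotype's share.
#' @param fungal_tail_s,fungal_tail_sigma Richness and lognormal sigma of
#'   the non-dominant fungal tail.
#' @param corr_pairs Data frame of planted genus pairs (`genus_a`,
#'   `genus_b`, `rho` the target sign/strength).
#' @param planted_weight Mean relative abundance of each planted genus.
#' @param otus_per_genus,genera_per_order Taxonomy granularity.
#' @param covariates Per-stage means/sds for pH, moisture, C/N, ergosterol.
#' @return A config list for [simulate_decay_study()].
#' @export
decay_study_config <- function(
    bands = c(early = 0.40, late = 0.30),
    density_range = c(0.50, 0.15),
    density_jitter = 0.004,
    bacterial_depth = 1080,
    fungal_depth = 2000,
    richness_base = 35,
    richness_slope = 500,
    stage_models = list(
      early = list(type = "neutral", m = 0.5),
      middle = list(type = "zipf", gamma = -1.3),
      late = list(type = "lognormal", sigma = 1.1)),
    fungal_dominance = c(0.55, 0.85),
    fungal_tail_s = 40,
    fungal_tail_sigma = 1.2,
    corr_pairs = data.frame(
      genus_a = c("Plantedia_A1", "Plantedia_A2", "Plantedia_A3"),
      genus_b = c("Plantedia_B1", "Plantedia_B2", "Plantedia_B3"),
      rho = c(0.95, 0.95, -0.95)),
    planted_weight = 0.02,
    otus_per_genus = 3,
    genera_per_order = 4,
    covariates = list(
      ph = list(mean = c(early = 4.90, middle = 3.96, late = 4.16),
                sd = c(early = 0.12, middle = 0.08, late = 0.14)),
      moisture = list(mean = c(early = 31.62, middle = 33.34, late = 138.99),
                      sd = c(early = 1.27, middle = 1.24, late = 1.24)),
      c_n_ratio = list(mean = c(early = 1009.25, middle = 743.02, late = 267.30),
                       sd = c(early = 267.19, middle = 38.06, late = 125.34)),
      ergosterol = list(mean = c(early = 14.19, middle = 41.98, late = 46.13),
                        sd = c(early = 1.10, middle = 1.15, late = 1.32)))) {
  cfg <- as.list(environment())
  if (!(cfg$bands[["early"]] > cfg$bands[["late"]] &&
        cfg$bands[["early"]] < cfg$density_range[1] &&
        cfg$bands[["late"]] > cfg$density_range[2])) {
    abort("stage bands must lie inside the density gradient, early above late")
  }
  cfg
}

stage_of_density <- function(d, bands) {
  ifelse(d > bands[["early"]], "early",
         ifelse(d >= bands[["late"]], "middle", "late"))
}

#' Simulate a full mock wood-decay study
#'
#' Generates a complete processed-table dataset — bacterial and fungal
#' count tables over `n_parents * reps` replicate samples, a taxonomy map
#' and sample metadata — with known ground truth (per-sample generating
#' model, planted correlated genus pairs, stage membership) recorded in the
#' `truth` element. See [decay_study_config()] for what is emulated.
#'
#' A single global `seed` expands into per-component substreams by a fixed
#' counter scheme (densities/covariates, then bacterial parents, fungal
#' parents, and replicate draws each get `derive_seed(seed, counter)` with
#' a documented counter), so any component is reproducible in isolation.
#'
#' @param n_parents Number of parent wood samples.
#' @param reps Replicates per parent.
#' @param seed Integer seed.
#' @param config A list from [decay_study_config()].
#' @return A list with elements `bacteria`, `fungi` (count tibbles),
#'   `taxonomy`, `metadata`, and `truth`.
#' @export
simulate_decay_study <- function(n_parents = 19, reps = 3, seed = 1,
                                 config = decay_study_config()) {
  cfg <- config
  parents <- sprintf("Pi%02d", seq_len(n_parents))
  density <- with_substream(seed, 1L, {
    seq(cfg$density_range[1], cfg$density_range[2], length.out = n_parents) +
      runif(n_parents, -cfg$density_jitter, cfg$density_jitter)
  })
  stage <- stage_of_density(density, cfg$bands)

  # --- per-parent covariates (parent-level wood properties) -------------
  covar <- with_substream(seed, 2L, {
    draw <- function(spec, floor_at = -Inf) {
      pmax(rnorm(n_parents, spec$mean[stage], spec$sd[stage]), floor_at)
    }
    tibble::tibble(
      ph = draw(cfg$covariates$ph, 2.5),
      moisture = draw(cfg$covariates$moisture, 5),
      c_n_ratio = draw(cfg$covariates$c_n_ratio, 20),
      ergosterol = draw(cfg$covariates$ergosterol, 0.5))
  })

  # --- planted cross-parent genus correlations --------------------------
  npairs <- nrow(cfg$corr_pairs)
  planted <- with_substream(seed, 3L, {
    lapply(seq_len(npairs), function(k) {
      z <- rnorm(n_parents)                 # latent driver across parents
      noise_sd <- sqrt(1 / abs(cfg$corr_pairs$rho[k])^2 - 1)
      zb <- sign(cfg$corr_pairs$rho[k]) * z + rnorm(n_parents, sd = noise_sd)
      wa <- cfg$planted_weight * exp(0.6 * z) / mean(exp(0.6 * z))
      wb <- cfg$planted_weight * exp(0.6 * zb) / mean(exp(0.6 * zb))
      list(wa = wa, wb = wb)
    })
  })

  # --- bacterial parent profiles ----------------------------------------
  stages <- c("early", "middle", "late")
  richness_target <- pmax(5L, round(cfg$richness_base +
    cfg$richness_slope * (cfg$density_range[1] - density)))
  max_s <- max(richness_target) + 60L
  pool_ids <- lapply(setNames(stages, stages), function(st) {
    sprintf("OTU_%s_%04d", st, seq_len(max_s))
  })
  bact_profiles <- vector("list", n_parents)
  truth_model <- character(n_parents)
  for (p in seq_len(n_parents)) {
    mdl <- cfg$stage_models[[stage[p]]]
    s_t <- richness_target[p]
    a <- with_substream(seed, 100L + p, switch(mdl$type,
      neutral = {
        theta <- ewens_theta_for_richness(s_t, cfg$bacterial_depth)
        simulate_neutral_sample(theta, mdl$m, cfg$bacterial_depth)
      },
      zipf = simulate_niche_sample("zipf",
        list(p1 = 0.5, gamma = mdl$gamma),
        S = round(s_t * 1.4), J = cfg$bacterial_depth),
      lognormal = simulate_niche_sample("lognormal",
        list(mu = 0, sigma = mdl$sigma),
        S = round(s_t * 1.15), J = cfg$bacterial_depth),
      preemption = simulate_niche_sample("preemption",
        list(alpha = mdl$alpha), S = s_t, J = cfg$bacterial_depth),
      abort(paste0("unknown stage model type: ", mdl$type))))
    truth_model[p] <- mdl$type
    ids <- pool_ids[[stage[p]]][seq_along(a)]
    w <- a / sum(a)
    # stage-indicator OTU plus planted pair taxa, folded in proportionally
    extra_ids <- sprintf("OTU_ind_%s", stage[p])
    extra_w <- 0.01
    for (k in seq_len(npairs)) {
      extra_ids <- c(extra_ids, paste0("OTU_pair", k, "a"), paste0("OTU_pair", k, "b"))
      extra_w <- c(extra_w, planted[[k]]$wa[p], planted[[k]]$wb[p])
    }
    w <- c(w * (1 - sum(extra_w)), extra_w)
    bact_profiles[[p]] <- setNames(w, c(ids, extra_ids))
  }

  # --- fungal parent profiles (own dominant phylotype each) -------------
  fung_profiles <- vector("list", n_parents)
  for (p in seq_len(n_parents)) {
    fung_profiles[[p]] <- with_substream(seed, 300L + p, {
      w1 <- runif(1, cfg$fungal_dominance[1], cfg$fungal_dominance[2])
      tail <- simulate_niche_sample("lognormal",
        list(mu = 0, sigma = cfg$fungal_tail_sigma),
        S = cfg$fungal_tail_s, J = cfg$fungal_depth)
      tail_ids <- sprintf("FOTU_%s_%04d", stage[p], seq_along(tail))
      w <- c(w1, (1 - w1) * tail / sum(tail))
      setNames(w, c(sprintf("FOTU_dom_%s", parents[p]), tail_ids))
    })
  }

  # --- replicate-level count tables -------------------------------------
  sample_ids <- as.vector(t(outer(parents, letters[seq_len(reps)], paste0)))
  draw_table <- function(profiles, depth, counter0) {
    all_ids <- unique(unlist(lapply(profiles, names)))
    m <- matrix(0, nrow = n_parents * reps, ncol = length(all_ids),
                dimnames = list(sample_ids, all_ids))
    for (p in seq_len(n_parents)) for (r in seq_len(reps)) {
      i <- (p - 1L) * reps + r
      m[i, names(profiles[[p]])] <- with_substream(seed, counter0 + i, {
        d <- depth + sample.int(round(depth * 0.25), 1L)
        as.vector(rmultinom(1, d, profiles[[p]]))
      })
    }
    matrix_to_count_tbl(m)
  }
  bacteria <- draw_table(bact_profiles, cfg$bacterial_depth, 500L)
  fungi <- draw_table(fung_profiles, cfg$fungal_depth, 700L)

  # --- taxonomy ---------------------------------------------------------
  taxonomy <- build_study_taxonomy(
    bact_ids = setdiff(names(bacteria), "sample_id"),
    fung_ids = setdiff(names(fungi), "sample_id"),
    cfg = cfg)

  metadata <- tibble::tibble(
    sample_id = sample_ids,
    wood_density = rep(density, each = reps),
    ph = rep(covar$ph, each = reps),
    moisture = rep(covar$moisture, each = reps),
    c_n_ratio = rep(covar$c_n_ratio, each = reps),
    ergosterol = rep(covar$ergosterol, each = reps),
    replicate_of = rep(parents, each = reps))

  list(bacteria = bacteria, fungi = fungi, taxonomy = taxonomy,
       metadata = metadata,
       truth = list(parent = parents, density = density, stage = stage,
                    generating_model = truth_model,
                    corr_pairs = cfg$corr_pairs,
                    pair_taxa = if (npairs) data.frame(
                      taxon_a = paste0("OTU_pair", seq_len(npairs), "a"),
                      taxon_b = paste0("OTU_pair", seq_len(npairs), "b"),
                      genus_a = cfg$corr_pairs$genus_a,
                      genus_b = cfg$corr_pairs$genus_b,
                      rho = cfg$corr_pairs$rho) else NULL,
                    seed = seed, config = cfg))
}

# theta such that the Ewens expected richness at community size J matches s
ewens_theta_for_richness <- function(s, J) {
  f <- function(th) sum(th / (th + seq_len(J) - 1)) - s
  stats::uniroot(f, c(1e-3, 5e3))$root
}

build_study_taxonomy <- function(bact_ids, fung_ids, cfg) {
  assign_lineage <- function(ids, kingdom, genus_prefix, order_prefix,
                             special_genus = NULL) {
    n <- length(ids)
    gidx <- ((seq_len(n) - 1L) %/% cfg$otus_per_genus) + 1L
    genus <- sprintf("%s%03d", genus_prefix, gidx)
    if (!is.null(special_genus)) {
      hit <- match(names(special_genus), ids)
      genus[hit[!is.na(hit)]] <- special_genus[!is.na(hit)]
    }
    oidx <- ((match(genus, unique(genus)) - 1L) %/% cfg$genera_per_order) + 1L
    tibble::tibble(
      taxon_id = ids, kingdom = kingdom,
      phylum = paste0(substr(kingdom, 1, 1), "_phylum"),
      class = "unclassified",
      order = sprintf("%s%03d", order_prefix, oidx),
      family = "unclassified", genus = genus)
  }
  npairs <- nrow(cfg$corr_pairs)
  special <- character(0)
  if (npairs) {
    special <- setNames(
      c(cfg$corr_pairs$genus_a, cfg$corr_pairs$genus_b),
      c(paste0("OTU_pair", seq_len(npairs), "a"),
        paste0("OTU_pair", seq_len(npairs), "b")))
  }
  dplyr::bind_rows(
    assign_lineage(bact_ids, "Bacteria", "Bgenus_", "Border_", special),
    assign_lineage(fung_ids, "Fungi", "Fgenus_", "Forder_"))
}

#' Write a simulated decay study to disk
#'
#' Writes the four TSV tables (bacterial counts, fungal counts, taxonomy,
#' metadata) plus a JSON manifest of the ground-truth parameters into a
#' directory, in the formats the readers in this package consume.
#'
#' @param study A list from [simulate_decay_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_decay_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(study$bacteria, file.path(dir, "bacteria_counts.tsv"))
  write_count_table(study$fungi, file.path(dir, "fungi_counts.tsv"))
  write_taxonomy(study$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_sample_metadata(study$metadata, file.path(dir, "metadata.tsv"))
  truth <- study$truth
  truth$config$corr_pairs <- NULL  # duplicated at top level
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
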