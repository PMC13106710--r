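#' Per-fly feature extraction from a raw track
#'
#' Convenience wrapper running annotation, sleep scoring, death QC,
#' feature extraction and (optionally) the 1440-bin sleep vector for the
#' flies of one track table.
#'
#' @param track Track table (`fly_id, genotype, t, x, y`), one or more
#'   flies.
#' @param move_threshold,min_sleep,interval Annotation parameters.
#' @param zt0_offset,photoperiod Light-schedule metadata.
#' @param fps Frames per second (`NULL`: estimated).
#' @param sleep_vector Also compute per-fly sleep vectors (blurred with
#'   `sigma`)?
#' @param sigma Gaussian-blur sd in bins.
#' @return List with `features` (one row per retained fly), `qc`, and —
#'   when requested — `vectors` (named list of blurred 1440-vectors).
#' @export
fly_features <- function(track, move_threshold = 0.25, min_sleep = 300,
                         interval = 10, zt0_offset = 0, photoperiod = 12,
                         fps = NULL, sleep_vector = TRUE, sigma = 5) {
  ann <- annotate_intervals(track,
    move_threshold = move_threshold,
    interval = interval, fps = fps
  )
  scored <- score_sleep(ann, min_sleep = min_sleep, interval = interval)
  qc <- detect_death(scored$annotations, interval = interval)
  feats <- extract_features(scored$annotations, scored$bouts, qc,
    zt0_offset = zt0_offset, photoperiod = photoperiod, interval = interval
  )
  out <- list(features = feats, qc = qc)
  if (sleep_vector) {
    vecs <- list()
    retained <- intersect(
      unique(scored$annotations$fly_id),
      if (nrow(feats)) feats$fly_id else character(0)
    )
    for (id in retained) {
      excl <- qc[fly_id == id]$excluded_days[[1]]
      v <- build_vector(scored$annotations[fly_id == id],
        zt0_offset = zt0_offset, exclude_days = excl, interval = interval
      )
      vecs[[id]] <- gaussian_blur(v, sigma = sigma)
    }
    out$vectors <- vecs
  }
  out
}

#' End-to-end behavioral stratification on synthetic cohorts
#'
#' Runs the full pipeline on generated tracks: per-fly annotation, sleep
#' scoring and QC, feature extraction, sleep-vector construction, NMF of
#' the stacked pattern matrix, per-genotype component means, feature
#' assembly (z-scored, morning anticipation excluded) and hierarchical
#' clustering (correlation distance, WPGMA) cut into `n_groups`. Flies
#' are simulated and processed one at a time so memory stays flat.
#'
#' @param config A [simulation_config()].
#' @param archetypes List of [archetype()]s; genotype labels may repeat
#'   with different labels to emulate multiple genotypes per archetype
#'   (pass distinct `genotype_label`s).
#' @param k NMF components; `NULL` selects k by the elbow rule over
#'   `k_range`.
#' @param k_range Candidate k values when `k` is `NULL`.
#' @param n_groups Groups to cut the genotype dendrogram into.
#' @param nmf_seed Seed for the NMF restarts (default: from config).
#' @return List with `features` (per fly), `genotype_features`,
#'   `decomposition`, `component_means`, `feature_matrix`, `tree`,
#'   `partition`.
#' @export
run_behavior_pipeline <- function(config, archetypes, k = 3, k_range = 1:6,
                                  n_groups = 2, nmf_seed = NULL) {
  if (inherits(archetypes, "archetype_spec")) archetypes <- list(archetypes)
  if (is.null(nmf_seed)) nmf_seed <- derive_seed(config$seed, 9999L)
  feats <- list()
  vectors <- list()
  genotypes <- character(0)
  idx <- 0L
  for (a in seq_along(archetypes)) {
    # one genotype at a time keeps memory flat on large cohorts
    tracks <- vector("list", config$n_flies_per_genotype)
    for (f in seq_len(config$n_flies_per_genotype)) {
      idx <- idx + 1L
      tracks[[f]] <- generate_fly_track(config, archetypes[[a]], fly_index = idx)
    }
    batch <- rbindlist(tracks)
    rm(tracks)
    res <- fly_features(batch,
      photoperiod = config$photoperiod,
      fps = config$fps, sleep_vector = TRUE
    )
    rm(batch)
    if (nrow(res$features)) {
      feats[[length(feats) + 1L]] <- res$features
      vectors <- c(vectors, res$vectors)
      genotypes <- c(
        genotypes,
        rep(archetypes[[a]]$genotype_label, length(res$vectors))
      )
    }
  }
  features <- rbindlist(feats)
  pm <- pattern_matrix(vectors, genotypes)
  if (is.null(k)) {
    ev <- nmf_variance_curve(pm$M, k_range, seed = nmf_seed)
    k <- select_k_elbow(ev)
  }
  dec <- fit_nmf(pm$M, k, seed = nmf_seed)
  comp_means <- genotype_component_means(dec$H, pm$genotypes)
  geno_feats <- features[, lapply(.SD, mean), by = genotype, .SDcols = !"fly_id"]
  fmat <- assemble_features(geno_feats, comp_means)
  tree <- wpgma_linkage(correlation_distance(fmat))
  partition <- cut_tree(tree, n_groups)
  list(
    features = features, genotype_features = geno_feats,
    decomposition = dec, component_means = comp_means,
    feature_matrix = fmat, tree = tree, partition = partition
  )
}
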