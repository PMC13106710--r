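#' Normalize ERG amplitudes to each batch's control
#'
#' Divides every amplitude by the mean control amplitude of its batch, so
#' genotype effects are expressed as fractions of the control and batch
#' gain cancels.
#'
#' @param erg ERG table with columns `batch, genotype_a, genotype_b,
#'   amplitude, is_control`.
#' @return Copy of the table with a `norm_amplitude` column.
#' @export
normalize_to_control <- function(erg) {
  dt <- copy(as.data.table(erg))
  stopifnot(all(c("batch", "genotype_a", "amplitude", "is_control") %in% names(dt)))
  if (any(dt$amplitude <= 0)) stop("amplitudes must be > 0")
  ctrl <- dt[is_control == TRUE, .(ctrl_mean = mean(amplitude)), by = batch]
  missing_ctrl <- setdiff(unique(dt$batch), ctrl$batch)
  if (length(missing_ctrl)) {
    stop(
      "batch(es) without control rows: ",
      paste(missing_ctrl, collapse = ", ")
    )
  }
  dt <- ctrl[dt, on = "batch"]
  dt[, norm_amplitude := amplitude / ctrl_mean]
  dt[, ctrl_mean := NULL]
  dt[]
}

#' Expected double-mutant amplitude under the multiplicative model
#'
#' In the non-interacting model the expected normalized depolarization of
#' a double mutant is the product of the two single-mutant normalized
#' means (two singles at 50% give an expected double of 25%).
#'
#' @param mean_a,mean_b Normalized single-mutant means (fractions of
#'   control).
#' @return Expected double-mutant fraction.
#' @export
expected_double <- function(mean_a, mean_b) {
  if (any(c(mean_a, mean_b) <= 0)) stop("single-mutant means must be > 0")
  mean_a * mean_b
}

#' Genetic-interaction strength
#'
#' Per-replicate strength is the observed normalized double-mutant
#' amplitude minus the multiplicative expectation; the pair strength is
#' their mean.
#'
#' @param observed Normalized double-mutant replicate amplitudes.
#' @param expected Expected double-mutant fraction.
#' @return List with `strengths` (per replicate) and `mean`.
#' @export
gi_strength <- function(observed, expected) {
  stopifnot(length(observed) >= 1)
  s <- observed - expected
  list(strengths = s, mean = mean(s))
}

#' Classify a genetic-interaction strength
#'
#' `strength >= +threshold` is alleviating (phenotype milder than
#' expected), `strength <= -threshold` aggravating (lower-than-expected
#' depolarization, i.e. a worse phenotype), anything within the band is
#' no/weak interaction.
#'
#' @param strength Numeric strength(s).
#' @param threshold Interaction threshold (default 0.3).
#' @return Character vector in `{"aggravating", "alleviating", "none"}`.
#' @export
classify_gi <- function(strength, threshold = 0.3) {
  ifelse(strength >= threshold, "alleviating",
    ifelse(strength <= -threshold, "aggravating", "none")
  )
}

#' Enumerate unordered gene pairs
#'
#' @param genes Character vector of distinct labels (24 genes give the
#'   276 tested combinations).
#' @return List of 2-element character vectors.
#' @export
enumerate_pairs <- function(genes) {
  if (anyDuplicated(genes)) stop("gene labels must be distinct")
  if (length(genes) < 2) {
    return(list())
  }
  combn(genes, 2, simplify = FALSE)
}

#' Genetic-interaction records from an ERG table
#'
#' Normalizes per batch, computes single-mutant means, and for every
#' tested pair the multiplicative expectation, the interaction strength
#' and its class.
#'
#' @param erg ERG table (see [normalize_to_control()]).
#' @param threshold Classification threshold (default 0.3).
#' @param min_replicates Minimum double-mutant replicates per pair.
#' @return `data.table(gene_a, gene_b, mean_a, mean_b, expected,
#'   observed_mean, strength, class, n_replicates)`.
#' @export
gi_table <- function(erg, threshold = 0.3, min_replicates = 5) {
  dt <- normalize_to_control(erg)
  singles <- dt[
    is_control == FALSE & is.na(genotype_b),
    .(mean_single = mean(norm_amplitude)),
    by = .(genotype = genotype_a)
  ]
  doubles <- dt[is_control == FALSE & !is.na(genotype_b)]
  if (!nrow(doubles)) {
    return(data.table())
  }
  doubles[, `:=`(
    gene_a = pmin(genotype_a, genotype_b),
    gene_b = pmax(genotype_a, genotype_b)
  )]
  rec <- doubles[, .(
    observed_mean = mean(norm_amplitude),
    n_replicates = .N
  ), by = .(gene_a, gene_b)]
  unknown <- setdiff(unique(c(rec$gene_a, rec$gene_b)), singles$genotype)
  if (length(unknown)) {
    stop(
      "double mutants reference genotypes without single-mutant data: ",
      paste(unknown, collapse = ", ")
    )
  }
  rec <- merge(rec, singles[, .(gene_a = genotype, mean_a = mean_single)],
    by = "gene_a"
  )
  rec <- merge(rec, singles[, .(gene_b = genotype, mean_b = mean_single)],
    by = "gene_b"
  )
  if (any(rec$n_replicates < min_replicates)) {
    warning("some pairs have fewer than ", min_replicates, " replicates")
  }
  rec[, expected := expected_double(mean_a, mean_b)]
  rec[, strength := observed_mean - expected]
  rec[, class := classify_gi(strength, threshold)]
  setcolorder(rec, c(
    "gene_a", "gene_b", "mean_a", "mean_b", "expected",
    "observed_mean", "strength", "class", "n_replicates"
  ))
  rec[]
}

#' Gene x gene interaction-strength profile matrix
#'
#' @param records Output of [gi_table()].
#' @param genes Optional gene order; default: all genes in the records.
#' @param diagonal Value for the untested self-pairs (default 0); use
#'   `NA` to exclude them from downstream distances.
#' @return Symmetric numeric matrix of strengths.
#' @export
gi_profile_matrix <- function(records, genes = NULL, diagonal = 0) {
  rec <- as.data.table(records)
  if (is.null(genes)) genes <- sort(unique(c(rec$gene_a, rec$gene_b)))
  m <- matrix(NA_real_, length(genes), length(genes),
    dimnames = list(genes, genes)
  )
  for (i in seq_len(nrow(rec))) {
    m[rec$gene_a[i], rec$gene_b[i]] <- rec$strength[i]
    m[rec$gene_b[i], rec$gene_a[i]] <- rec$strength[i]
  }
  diag(m) <- diagonal
  m
}

#' Cluster genes on their interaction profiles
#'
#' Each gene's profile is its row of pairwise strengths; profiles are
#' clustered with Euclidean distance and WPGMA linkage and cut into two
#' groups.
#'
#' @param profile Symmetric strength matrix from [gi_profile_matrix()].
#' @param n_groups Number of groups to cut (default 2).
#' @return Named partition (gene -> group label), with the [wpgma_linkage()]
#'   tree attached as attribute `"tree"`.
#' @export
cluster_gi_profiles <- function(profile, n_groups = 2) {
  if (all(abs(profile) < 1e-12)) {
    warning("all interaction strengths are zero; clustering is degenerate")
  }
  tree <- wpgma_linkage(dist(profile, method = "euclidean"))
  part <- cut_tree(tree, n_groups, prefix = "GI")
  attr(part, "tree") <- tree
  part
}
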