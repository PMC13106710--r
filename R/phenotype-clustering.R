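#' Assemble the genotype x feature matrix
#'
#' Joins per-genotype behavioral feature means with per-genotype NMF
#' component means, drops morning anticipation (it is highly correlated
#' with the temporal components by construction) and z-scores every column
#' (sample standard deviation). A constant column cannot be scaled and is
#' an error.
#'
#' @param feature_means `data.frame` with a `genotype` column and one
#'   column per behavioral feature (per-genotype means).
#' @param component_means `data.frame` with a `genotype` column and one
#'   column per NMF component (from [genotype_component_means()]); may be
#'   `NULL` to cluster on behavioral features alone.
#' @return Numeric matrix (genotypes x features), scaled, with
#'   `attr(, "scaled") = TRUE`.
#' @export
assemble_features <- function(feature_means, component_means = NULL) {
  fm <- as.data.table(feature_means)
  stopifnot("genotype" %in% names(fm))
  if (!is.null(component_means)) {
    cm <- as.data.table(component_means)
    stopifnot("genotype" %in% names(cm))
    miss_a <- setdiff(fm$genotype, cm$genotype)
    miss_b <- setdiff(cm$genotype, fm$genotype)
    if (length(miss_a) || length(miss_b)) {
      stop(
        "genotype sets differ between inputs: ",
        paste(c(miss_a, miss_b), collapse = ", ")
      )
    }
    fm <- merge(fm, cm, by = "genotype")
  }
  drop <- intersect(c("morning_anticipation", "fly_id"), names(fm))
  if (length(drop)) fm[, (drop) := NULL]
  m <- as.matrix(fm[, -"genotype"])
  rownames(m) <- fm$genotype
  if (anyNA(m)) stop("feature matrix contains missing cells")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    stop(
      "zero-variance feature(s) cannot be scaled: ",
      paste(colnames(m)[sds == 0], collapse = ", ")
    )
  }
  m <- scale(m)
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  attr(m, "scaled") <- TRUE
  m
}

#' Correlation distance between matrix rows
#'
#' `d(i, j) = 1 - Pearson(row_i, row_j)`; identical rows are at distance 0,
#' perfectly anti-correlated rows at 2.
#'
#' @param m Numeric matrix with at least two columns.
#' @return A `dist` object over rows.
#' @export
correlation_distance <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least two columns")
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    stop(
      "zero-variance row(s): ",
      paste(rownames(m)[sds == 0], collapse = ", ")
    )
  }
  as.dist(1 - cor(t(m)))
}

#' WPGMA (mcquitty) hierarchical clustering
#'
#' Agglomerative clustering where the distance of a merged cluster to any
#' other is the unweighted mean of its two constituents' distances.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @return An `hclust` tree.
#' @export
wpgma_linkage <- function(d) {
  if (!inherits(d, "dist")) d <- as.dist(d)
  hclust(d, method = "mcquitty")
}

#' Cut a dendrogram into a named partition
#'
#' @param tree An `hclust` object.
#' @param n_groups Number of groups, `1 <= n_groups <=` leaves.
#' @param prefix Label prefix for group names.
#' @return Named character vector: genotype -> group label.
#' @export
cut_tree <- function(tree, n_groups, prefix = "G") {
  stopifnot(inherits(tree, "hclust"))
  cl <- cutree(tree, k = n_groups)
  setNames(paste0(prefix, cl), names(cl))
}

# Partition (named vector genotype -> label) to list of member sets.
partition_sets <- function(partition) {
  split(names(partition), partition)
}

#' Principal component analysis of the feature matrix
#'
#' Centered PCA of the already-scaled matrix (scaling is applied once,
#' upstream in [assemble_features()]).
#'
#' @param m Scaled feature matrix (genotypes x features).
#' @return List with `scores`, `loadings`, `variance_fraction` (sums to 1)
#'   and `cor2` (squared correlation of each feature with each PC).
#' @export
pca_features <- function(m) {
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  vf <- p$sdev^2 / sum(p$sdev^2)
  keep <- seq_len(sum(p$sdev > 1e-12))
  cor2 <- cor(m, p$x[, keep, drop = FALSE])^2
  list(
    scores = p$x, loadings = p$rotation,
    variance_fraction = vf, cor2 = cor2
  )
}

#' Leave-one-feature-out cluster stability
#'
#' Drops one feature column at a time, re-scales, re-clusters (correlation
#' distance + WPGMA), cuts at the reference number of subgroups and
#' records, for every reference subgroup, the best-match Jaccard
#' similarity with the new groups. Jaccard values are binned into the
#' stability categories 0-0.34, 0.35-0.69 and 0.7-1.
#'
#' @param m Scaled feature matrix from [assemble_features()].
#' @param reference Named partition (genotype -> subgroup label), e.g.
#'   from [cut_tree()].
#' @return List with `detail` (`data.table(feature, subgroup, jaccard,
#'   category)`) and `summary` (percentage of cases per category, plus the
#'   percentage with Jaccard >= 0.35).
#' @export
stability_loo <- function(m, reference) {
  stopifnot(setequal(rownames(m), names(reference)))
  n_groups <- length(unique(reference))
  ref_sets <- partition_sets(reference)
  rows <- list()
  for (f in colnames(m)) {
    sub <- m[, setdiff(colnames(m), f), drop = FALSE]
    sub <- scale(sub)
    part <- cut_tree(wpgma_linkage(correlation_distance(sub)), n_groups)
    new_sets <- partition_sets(part)
    for (g in names(ref_sets)) {
      jac <- max(vapply(new_sets, jaccard, 0, b = ref_sets[[g]]))
      rows[[length(rows) + 1L]] <- data.table(
        feature = f, subgroup = g, jaccard = jac
      )
    }
  }
  detail <- rbindlist(rows)
  cats <- categorize_stability(detail$jaccard)
  detail[, category := cats$category]
  list(detail = detail[], summary = cats$summary)
}
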