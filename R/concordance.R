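#' Jaccard similarity (intersection over union)
#'
#' @param a,b Sets, as character/atomic vectors (duplicates ignored).
#' @return `|a intersect b| / |a union b|`; two empty sets are an error.
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) stop("Jaccard similarity of two empty sets is undefined")
  length(intersect(a, b)) / u
}

#' Permutation test for partition concordance
#'
#' Tests whether a behavior-defined group resembles one of the genetic-
#' interaction groups more than random gene sets do. Each iteration draws
#' mutually disjoint random groups from the universe with the same size
#' distribution as `gi_groups` (i.e. a random relabeling) and records
#' whether the maximal Jaccard similarity of the behavior group with a
#' random group strictly exceeds its maximal similarity with a real
#' group. The p-value is the exceedance fraction (one-sided, uncorrected);
#' ties are not exceedances. `add_one = TRUE` gives the
#' `(count + 1) / (n + 1)` variant, which cannot report p = 0.
#'
#' @param behavior_group Character vector: members of the behavior group.
#' @param gi_groups List of character vectors: the reference groups.
#' @param universe Character vector of all genes.
#' @param n Number of iterations (default 10000).
#' @param seed Integer seed.
#' @param add_one Use the add-one p-value variant (default `FALSE`).
#' @return An object of class `permutation_result`: `observed_similarity`,
#'   `n_iterations`, `exceed_count`, `p_value`, `seed`.
#' @export
permutation_test <- function(behavior_group, gi_groups, universe,
                             n = 10000, seed = 1L, add_one = FALSE) {
  if (!is.list(gi_groups)) gi_groups <- list(gi_groups)
  if (!all(behavior_group %in% universe) ||
    !all(unlist(gi_groups) %in% universe)) {
    stop("groups must be subsets of the universe")
  }
  sizes <- lengths(gi_groups)
  if (sum(sizes) > length(universe)) {
    stop("group sizes exceed the universe")
  }
  observed <- max(vapply(gi_groups, jaccard, 0, b = behavior_group))
  nu <- length(universe)
  b_mask <- universe %in% behavior_group
  nb <- sum(b_mask)
  offsets <- cumsum(c(0, sizes))
  exceed <- 0L
  with_preserved_rng({
    set.seed(seed)
    for (i in seq_len(n)) {
      perm <- b_mask[sample.int(nu)]
      best <- 0
      for (g in seq_along(sizes)) {
        inter <- sum(perm[(offsets[g] + 1):offsets[g + 1]])
        best <- max(best, inter / (nb + sizes[g] - inter))
      }
      if (best > observed) exceed <- exceed + 1L
    }
  })
  p <- if (add_one) (exceed + 1) / (n + 1) else exceed / n
  structure(
    list(
      observed_similarity = observed, n_iterations = n,
      exceed_count = exceed, p_value = p, seed = as.integer(seed),
      add_one = add_one
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "observed max Jaccard %.3f; p = %.4f (%d/%d exceedances)\n",
    x$observed_similarity, x$p_value, x$exceed_count, x$n_iterations
  ))
  invisible(x)
}

#' Bin Jaccard similarities into stability categories
#'
#' Categories 0-0.34, 0.35-0.69 and 0.7-1; values of at least 0.35 count
#' as substantial overlap.
#'
#' @param values Jaccard similarities in `[0, 1]`.
#' @return List with `category` (factor per value), `summary`
#'   (`data.table(category, count, percent)`) and `pct_substantial`
#'   (percentage of values >= 0.35).
#' @export
categorize_stability <- function(values) {
  stopifnot(all(values >= 0 & values <= 1))
  category <- cut(values,
    breaks = c(-Inf, 0.35, 0.70, Inf), right = FALSE,
    labels = c("0-0.34", "0.35-0.69", "0.7-1")
  )
  counts <- table(category)
  list(
    category = category,
    summary = data.table(
      category = names(counts),
      count = as.integer(counts),
      percent = 100 * as.integer(counts) / max(length(values), 1L)
    ),
    pct_substantial = 100 * mean(values >= 0.35)
  )
}
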