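# Shared fixtures and independent oracles, built in code at test time.

library(data.table)

# Track for one fly from a vector of per-frame displacements (pure x
# motion, fixed y), sampled at 1 frame/s starting at t = 0.
track_from_displacements <- function(disp, fly_id = "f1", genotype = "g",
                                     t0 = 0) {
  x <- cumsum(c(0, disp))
  data.table(
    fly_id = fly_id, genotype = genotype,
    t = t0 + seq_along(x) - 1, x = x, y = 0
  )
}

# Annotation table on a 10-s grid from a logical immobility sequence.
annotations_from_immobility <- function(immobile, fly_id = "f1",
                                        genotype = "g", interval = 10) {
  n <- length(immobile)
  data.table(
    fly_id = fly_id, genotype = genotype,
    interval_start = (seq_len(n) - 1) * interval,
    n_frames = 10L,
    moving = !immobile,
    max_displacement = fifelse(immobile, 0.05, 1),
    sum_displacement = fifelse(immobile, 0.05, 5),
    corrected_velocity = fifelse(immobile, 0.05, 1) / 0.0042,
    missing_interval = FALSE,
    log_distance = NA_real_
  )
}

# Brute-force WPGMA: quadratic agglomeration with the McQuitty update
# d(new, k) = (d(i, k) + d(j, k)) / 2 and lexicographic tie-breaks.
# Returns merge heights and the partition after each merge.
wpgma_oracle <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n + (n - 1))
  d <- matrix(NA_real_, n + (n - 1), n + (n - 1))
  d[1:n, 1:n] <- D
  heights <- numeric(n - 1)
  partitions <- vector("list", n - 1)
  ids <- seq_len(n)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA)
    best_d <- Inf
    act <- which(active[seq_len(n + step - 1)])
    for (ii in seq_along(act)) {
      for (jj in seq_len(ii - 1L)) {
        i <- act[jj]
        j <- act[ii]
        if (d[i, j] < best_d - 1e-12) {
          best_d <- d[i, j]
          best <- c(i, j)
        }
      }
    }
    new_id <- n + step
    clusters[[new_id]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    for (k in act) {
      if (k %in% best) next
      d[new_id, k] <- d[k, new_id] <- (d[best[1], k] + d[best[2], k]) / 2
    }
    active[best] <- FALSE
    active[new_id] <- TRUE
    heights[step] <- best_d
    partitions[[step]] <- lapply(
      which(active[seq_len(new_id)]),
      function(id) clusters[[id]]
    )
  }
  list(heights = heights, partitions = partitions)
}

# Canonical form of a partition (list of index sets) for comparison.
canonical_partition <- function(sets) {
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, `[`, 0, 1))]
}

# Partition from cutree output (named or unnamed integer vector).
cutree_partition <- function(cl) {
  canonical_partition(unname(split(seq_along(cl), cl)))
}

# Direct O(n k) convolution oracle for the Gaussian blur.
blur_oracle <- function(x, sigma, edge = "reflect") {
  r <- ceiling(4 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(x)
  idx <- function(i) {
    if (edge == "periodic") {
      return(((i - 1) %% n) + 1)
    }
    # reflect (edge value not repeated is not required; mirror style ab|ba)
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq(-r, r)) {
      acc <- acc + k[j + r + 1] * x[idx(i + j)]
    }
    out[i] <- acc
  }
  out
}

# Exhaustive exceedance probability for the permutation test: enumerate
# all ordered draws of disjoint groups with the given sizes.
exact_exceedance <- function(behavior_group, gi_groups, universe) {
  sizes <- lengths(gi_groups)
  stopifnot(length(sizes) == 2) # enough for the oracle
  observed <- max(vapply(gi_groups, jaccard, 0, b = behavior_group))
  combos1 <- combn(universe, sizes[1], simplify = FALSE)
  total <- 0L
  exceed <- 0L
  for (g1 in combos1) {
    rest <- setdiff(universe, g1)
    combos2 <- combn(rest, sizes[2], simplify = FALSE)
    for (g2 in combos2) {
      total <- total + 1L
      best <- max(jaccard(g1, behavior_group), jaccard(g2, behavior_group))
      if (best > observed) exceed <- exceed + 1L
    }
  }
  exceed / total
}

# Best-match Jaccard agreement between two partitions given as named
# vectors genotype -> label: for every group of `truth`, the best Jaccard
# against any group of `found`; returns the minimum over truth groups.
partition_recovery <- function(found, truth) {
  fs <- split(names(found), found)
  ts <- split(names(truth), truth)
  min(vapply(
    ts,
    function(g) max(vapply(fs, jaccard, 0, b = g)),
    0
  ))
}
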