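#' Build a fly's 1440-bin temporal sleep vector
#'
#' For every 1-minute bin of clock time (24 h x 60 min = 1440 bins) the
#' vector holds the fraction of 10-s windows — aggregated over the retained
#' days — whose strictly preceding 5-min period was at least 99% immobile
#' ("Time Spent Sleeping" aggregation). With 30 windows of 10 s per 5-min
#' period, the 99% rule requires all 30 preceding windows immobile. The
#' first recording day (and any day excluded by QC) does not contribute to
#' the aggregation, although its windows may serve as preceding context.
#'
#' @param annotations Annotations for one fly from [annotate_intervals()].
#' @param zt0_offset Experiment time of lights-on, seconds.
#' @param exclude_days Integer day indices excluded from aggregation
#'   (default the first day).
#' @param interval Window length in seconds.
#' @return Numeric vector of length 1440 with values in `[0, 1]`.
#' @export
build_vector <- function(annotations, zt0_offset = 0, exclude_days = 1L,
                         interval = 10) {
  ann <- as.data.table(annotations)
  if (uniqueN(ann$fly_id) > 1L) stop("build_vector expects a single fly")
  setorder(ann, interval_start)
  w <- as.integer(300 / interval) # windows in the preceding 5 min
  immob <- as.numeric(!ann$moving & !ann$missing_interval)
  cs <- cumsum(immob)
  n <- length(immob)
  # all w preceding windows immobile (window i uses i-w .. i-1)
  ind <- rep(NA_real_, n)
  if (n > w) {
    ind[(w + 1):n] <- as.numeric((cs[(w + 1):n - 1] - c(0, cs)[(w + 1):n - w]) == w)
  }
  keep <- !ann$missing_interval & !is.na(ind) &
    !(floor((ann$interval_start - zt0_offset) / 86400) + 1L) %in% exclude_days
  minute_bin <- floor(((ann$interval_start - zt0_offset) %% 86400) / 60) + 1L
  v <- rep(0, 1440)
  agg <- tapply(ind[keep], minute_bin[keep], mean)
  v[as.integer(names(agg))] <- as.numeric(agg)
  v
}

#' Discrete Gaussian blur of a daily vector
#'
#' Convolution with a discretized Gaussian kernel (radius `4*sigma` bins).
#' Edges are handled by reflection by default, or periodically — clock time
#' wraps at midnight, so the periodic mode conserves total mass exactly.
#' `sigma = 0` returns the input unchanged.
#'
#' @param x Numeric vector (typically length 1440).
#' @param sigma Kernel standard deviation in bins (default 5).
#' @param edge `"reflect"` or `"periodic"`.
#' @return Blurred vector of the same length; non-negativity is preserved.
#' @export
gaussian_blur <- function(x, sigma = 5, edge = c("reflect", "periodic")) {
  edge <- match.arg(edge)
  if (sigma == 0) {
    return(x)
  }
  if (sigma < 0) stop("sigma must be >= 0")
  r <- ceiling(4 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(x)
  if (edge == "periodic") {
    pad <- c(tail(x, r), x, head(x, r))
  } else {
    pad <- c(rev(head(x, r)), x, rev(tail(x, r)))
  }
  out <- numeric(n)
  for (j in seq(-r, r)) {
    out <- out + k[j + r + 1] * pad[(1 + r + j):(n + r + j)]
  }
  out
}

#' Stack per-fly sleep vectors into a pattern matrix
#'
#' @param vectors Named list of 1440-vectors (names = fly ids), already
#'   blurred or raw.
#' @param genotypes Character vector of genotype labels, one per fly.
#' @return List with `M` (1440 x l non-negative matrix), `fly_ids`,
#'   `genotypes`.
#' @export
pattern_matrix <- function(vectors, genotypes) {
  stopifnot(length(vectors) == length(genotypes))
  M <- do.call(cbind, vectors)
  if (nrow(M) != 1440L) stop("vectors must have 1440 bins")
  if (any(M < 0)) stop("pattern matrix must be non-negative")
  colnames(M) <- names(vectors)
  list(M = M, fly_ids = names(vectors), genotypes = genotypes)
}

# NNDSVD initialization (Boutsidis & Gallopoulos): deterministic, based on
# the truncated SVD with negative parts zeroed.
nndsvd_init <- function(M, k) {
  s <- svd(M, nu = k, nv = k)
  W <- matrix(0, nrow(M), k)
  H <- matrix(0, k, ncol(M))
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  H[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (k > 1) {
    for (j in 2:k) {
      u <- s$u[, j]
      v <- s$v[, j]
      up <- pmax(u, 0)
      un <- pmax(-u, 0)
      vp <- pmax(v, 0)
      vn <- pmax(-v, 0)
      npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
      nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
      if (npos >= nneg) {
        W[, j] <- sqrt(s$d[j] * npos) * up / max(sqrt(sum(up^2)), 1e-12)
        H[j, ] <- sqrt(s$d[j] * npos) * vp / max(sqrt(sum(vp^2)), 1e-12)
      } else {
        W[, j] <- sqrt(s$d[j] * nneg) * un / max(sqrt(sum(un^2)), 1e-12)
        H[j, ] <- sqrt(s$d[j] * nneg) * vn / max(sqrt(sum(vn^2)), 1e-12)
      }
    }
  }
  eps <- mean(M) * 1e-4 + 1e-12
  W[W <= 0] <- eps
  H[H <= 0] <- eps
  list(W = W, H = H)
}

nmf_objective <- function(M, W, H) sum((M - W %*% H)^2)

# Lee-Seung multiplicative updates for the Frobenius objective.
nmf_run <- function(M, W, H, max_iter, tol) {
  eps <- 1e-12
  obj <- nmf_objective(M, W, H)
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, M)) / (crossprod(W) %*% H + eps)
    W <- W * (M %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10 == 0) {
      new_obj <- nmf_objective(M, W, H)
      if (obj - new_obj < tol * max(obj, eps)) {
        obj <- new_obj
        break
      }
      obj <- new_obj
    }
  }
  list(W = W, H = H, objective = nmf_objective(M, W, H))
}

#' Non-negative matrix factorization of a pattern matrix
#'
#' Approximates `M ~ W H` with `W >= 0` (1440 x k temporal components) and
#' `H >= 0` (k x l per-fly encodings) by multiplicative updates under the
#' Frobenius objective. Initialization is deterministic NNDSVD plus
#' `n_restarts` seeded random restarts; the best objective is kept, so the
#' fit is reproducible for a fixed seed.
#'
#' @param M Non-negative matrix (rows = time bins, columns = flies), or the
#'   list returned by [pattern_matrix()].
#' @param k Number of components, `1 <= k <= min(dim(M))`.
#' @param seed Integer seed for the random restarts.
#' @param n_restarts Random restarts in addition to NNDSVD (default 5).
#' @param max_iter,tol Update iterations and relative objective tolerance.
#' @return An object of class `nmf_decomposition`: `W`, `H`, `k`,
#'   `explained_variance` (1 - RSS / column-mean-centered TSS), `objective`,
#'   `seed`.
#' @export
fit_nmf <- function(M, k, seed = 1L, n_restarts = 5, max_iter = 500,
                    tol = 1e-6) {
  if (is.list(M) && !is.matrix(M)) M <- M$M
  if (!is.matrix(M) || !length(M)) stop("M must be a non-empty matrix")
  if (any(M < 0)) stop("M must be non-negative")
  if (k < 1 || k > min(dim(M))) stop("k must lie in [1, min(dim(M))]")
  best <- NULL
  with_preserved_rng({
    init <- nndsvd_init(M, k)
    best <- nmf_run(M, init$W, init$H, max_iter, tol)
    for (r in seq_len(n_restarts)) {
      set.seed(derive_seed(seed, r))
      W0 <- matrix(runif(nrow(M) * k, 0, max(M)), nrow(M), k)
      H0 <- matrix(runif(k * ncol(M), 0, 1), k, ncol(M))
      cand <- nmf_run(M, W0, H0, max_iter, tol)
      if (cand$objective < best$objective) best <- cand
    }
  })
  tss <- sum(sweep(M, 2, colMeans(M))^2)
  structure(
    list(
      W = best$W, H = best$H, k = as.integer(k),
      explained_variance = 1 - best$objective / max(tss, 1e-12),
      objective = best$objective, seed = as.integer(seed)
    ),
    class = "nmf_decomposition"
  )
}

#' @export
print.nmf_decomposition <- function(x, ...) {
  cat(
    "NMF decomposition: k =", x$k,
    sprintf("(explained variance %.3f)\n", x$explained_variance)
  )
  invisible(x)
}

#' Explained-variance curve over a range of k
#'
#' @inheritParams fit_nmf
#' @param ks Integer vector of component counts.
#' @return Named numeric vector of explained variances (names = k).
#' @export
nmf_variance_curve <- function(M, ks, seed = 1L, n_restarts = 2,
                               max_iter = 300, tol = 1e-5) {
  ev <- vapply(
    ks,
    function(k) {
      fit_nmf(M, k,
        seed = seed, n_restarts = n_restarts,
        max_iter = max_iter, tol = tol
      )$explained_variance
    },
    0
  )
  # best-of-restarts fits should not lose variance as k grows
  setNames(cummax(ev), ks)
}

#' Elbow selection of the component count
#'
#' Operationalizes the visual elbow as the k maximizing the curvature
#' (most negative discrete second difference) of the explained-variance
#' curve. For a near-linear curve with no elbow, falls back to the
#' smallest k whose marginal gain is below `gain_tol` (with a warning).
#'
#' @param variances Named numeric vector of explained variances for
#'   consecutive k (at least 3 values; names = k).
#' @param gain_tol Marginal-gain threshold for the fallback rule.
#' @return Selected k (integer).
#' @export
select_k_elbow <- function(variances, gain_tol = 0.02) {
  if (length(variances) < 3) stop("need variances for at least 3 k values")
  ks <- as.integer(names(variances))
  if (is.null(names(variances)) || anyNA(ks)) ks <- seq_along(variances)
  v <- as.numeric(variances)
  d2 <- diff(v, differences = 2) # at interior ks[2..(n-1)]
  if (min(d2) < -0.005) {
    return(ks[which.min(d2) + 1L])
  }
  warning("no elbow in the explained-variance curve; using marginal-gain rule")
  gains <- diff(v)
  small <- which(gains < gain_tol)
  if (length(small)) ks[small[1]] else ks[length(ks)]
}

#' Calinski-Harabasz index of the encoding-based clustering
#'
#' Flies are assigned to the component with the largest entry of their
#' encoding column, and the standard between/within dispersion ratio is
#' computed on the k-dimensional encoding vectors. A degenerate clustering
#' with zero within-cluster dispersion returns `Inf`.
#'
#' @param H k x l encoding matrix (columns = flies), or an
#'   `nmf_decomposition`.
#' @return CH score (single or fewer than two non-empty clusters give
#'   `NA` with a warning).
#' @export
ch_index <- function(H) {
  if (inherits(H, "nmf_decomposition")) H <- H$H
  X <- t(H) # flies x k
  cl <- apply(H, 2, which.max)
  ks <- unique(cl)
  n <- nrow(X)
  if (length(ks) < 2) {
    warning("fewer than two non-empty clusters; CH undefined")
    return(NA_real_)
  }
  centroid <- colMeans(X)
  bss <- 0
  wss <- 0
  for (g in ks) {
    Xg <- X[cl == g, , drop = FALSE]
    cg <- colMeans(Xg)
    bss <- bss + nrow(Xg) * sum((cg - centroid)^2)
    wss <- wss + sum(sweep(Xg, 2, cg)^2)
  }
  if (wss == 0) {
    return(Inf)
  }
  (bss / (length(ks) - 1)) / (wss / (n - length(ks)))
}

#' Mean encoding per genotype
#'
#' @param H k x l encoding matrix or `nmf_decomposition`.
#' @param genotypes Character vector of genotype labels, one per column.
#' @return `data.table` with `genotype` and one column per component
#'   (`comp_1 ... comp_k`): the arithmetic mean encoding over flies.
#' @export
genotype_component_means <- function(H, genotypes) {
  if (inherits(H, "nmf_decomposition")) H <- H$H
  stopifnot(ncol(H) == length(genotypes), !anyNA(genotypes))
  dt <- as.data.table(t(H))
  setnames(dt, paste0("comp_", seq_len(nrow(H))))
  dt[, genotype := genotypes]
  out <- dt[, lapply(.SD, mean), by = genotype]
  setcolorder(out, "genotype")
  out[]
}
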