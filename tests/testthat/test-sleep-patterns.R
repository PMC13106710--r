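test_that("sleep vectors have 1440 bins with the expected limits", {
  n_day <- 8640
  always <- annotations_from_immobility(rep(TRUE, 2 * n_day))
  v1 <- build_vector(always)
  expect_length(v1, 1440)
  expect_true(all(v1 == 1))

  never <- annotations_from_immobility(rep(FALSE, 2 * n_day))
  v0 <- build_vector(never)
  expect_length(v0, 1440)
  expect_true(all(v0 == 0))
})

test_that("the 5-min ramp-in delays the sleeping state after ZT0", {
  n_day <- 8640
  immob <- rep(FALSE, 2 * n_day)
  # immobile only ZT0-ZT1 on both days
  immob[1:360] <- TRUE
  immob[n_day + (1:360)] <- TRUE
  v <- build_vector(annotations_from_immobility(immob))
  expect_true(all(v[7:59] == 1)) # after the 5-min preceding window fills
  expect_true(all(v[1:5] == 0)) # ramp-in: preceding window still awake
  expect_true(all(v[70:1440] == 0))
})

test_that("gaussian blur matches a direct-convolution oracle", {
  set.seed(4)
  x <- runif(200)
  for (edge in c("reflect", "periodic")) {
    expect_equal(
      gaussian_blur(x, sigma = 5, edge = edge),
      blur_oracle(x, 5, edge),
      tolerance = 1e-12
    )
  }
  # constant vectors are fixed points; sigma 0 is the identity
  expect_equal(gaussian_blur(rep(0.3, 100), 5), rep(0.3, 100))
  expect_identical(gaussian_blur(x, 0), x)
  # unit impulse under periodic edges conserves mass to < 0.1%
  imp <- c(1, rep(0, 1439))
  b <- gaussian_blur(imp, 5, edge = "periodic")
  expect_lt(abs(sum(b) - 1), 1e-3)
  expect_true(all(b >= 0))
})

test_that("NMF recovers rank-1 structure essentially exactly", {
  set.seed(8)
  w <- abs(rnorm(1440)) + 0.1
  h <- abs(rnorm(40)) + 0.1
  M <- w %*% t(h)
  d <- fit_nmf(M, 1, seed = 1)
  expect_gt(d$explained_variance, 0.999)
  expect_true(min(d$W) >= 0 && min(d$H) >= 0)
  # columns reconstruct flies
  expect_lt(
    max(sqrt(colSums((M - d$W %*% d$H)^2)) / sqrt(colSums(M^2))),
    0.01
  )
})

test_that("NMF fits are deterministic for a fixed seed", {
  set.seed(10)
  M <- matrix(runif(200 * 20), 200, 20)
  d1 <- fit_nmf(M, 3, seed = 5)
  d2 <- fit_nmf(M, 3, seed = 5)
  expect_identical(d1$W, d2$W)
  expect_identical(d1$H, d2$H)
})

test_that("explained variance is non-decreasing in k (best of restarts)", {
  set.seed(12)
  W0 <- matrix(runif(300 * 3), 300, 3)
  H0 <- matrix(runif(3 * 30), 3, 30)
  M <- W0 %*% H0 + matrix(abs(rnorm(300 * 30, 0, 0.02)), 300)
  ev <- nmf_variance_curve(M, 1:5, seed = 2)
  expect_true(all(diff(ev) >= -1e-9))
  expect_error(fit_nmf(M, 0), "k must lie")
  expect_error(fit_nmf(M[, 0, drop = FALSE], 1), "non-empty|k must lie")
})

test_that("elbow selection maximizes curvature with a linear fallback", {
  v <- c(0.50, 0.80, 0.90, 0.92, 0.93)
  names(v) <- 1:5
  expect_equal(select_k_elbow(v), 2L)
  lin <- setNames(seq(0.1, 0.5, by = 0.1), 1:5)
  expect_warning(k <- select_k_elbow(lin), "no elbow")
  expect_equal(k, 5L) # no marginal gain below 0.02 either
  lin2 <- setNames(c(0.2, 0.4, 0.6, 0.61, 0.62), 1:5)
  expect_equal(select_k_elbow(lin2), 3L)
  expect_error(select_k_elbow(c(a = 1, b = 2)), "at least 3")
})

test_that("elbow rule identifies the planted component count", {
  set.seed(33)
  # three archetypal temporal profiles mixed over 60 flies
  basis <- cbind(
    exp(-((1:1440) - 200)^2 / 5000),
    exp(-((1:1440) - 800)^2 / 8000),
    c(rep(0.1, 720), rep(0.8, 720))
  )
  H <- matrix(runif(3 * 60, 0.2, 1), 3, 60)
  M <- basis %*% H + matrix(abs(rnorm(1440 * 60, 0, 0.01)), 1440)
  ev <- nmf_variance_curve(M, 1:6, seed = 3)
  expect_equal(select_k_elbow(ev), 3L)
})

test_that("CH index separates well-clustered encodings", {
  set.seed(14)
  # two well-separated groups in encoding space
  H2 <- cbind(
    rbind(rnorm(30, 5, 0.2), rnorm(30, 0.1, 0.05)),
    rbind(rnorm(30, 0.1, 0.05), rnorm(30, 5, 0.2))
  )
  ch2 <- ch_index(H2)
  expect_gt(ch2, 100)
  # random encodings score far lower
  H5 <- matrix(runif(5 * 60), 5, 60)
  expect_gt(ch2, ch_index(H5))
  # degenerate: two point-mass clusters, zero within dispersion
  Hd <- cbind(
    matrix(c(1, 0), 2, 15), matrix(c(0, 1), 2, 15)
  )
  expect_equal(ch_index(Hd), Inf)
  # a single cluster leaves the index undefined
  expect_warning(
    one <- ch_index(matrix(c(1, 0), 2, 10)),
    "fewer than two"
  )
  expect_true(is.na(one))
})

test_that("genotype component means aggregate encodings", {
  H <- cbind(c(1, 0), c(0, 1))
  colnames(H) <- c("f1", "f2")
  gm <- genotype_component_means(H, c("g", "g"))
  expect_equal(unlist(gm[, .(comp_1, comp_2)]), c(comp_1 = 0.5, comp_2 = 0.5))
  # single fly per genotype: profile equals the fly's encoding
  gm2 <- genotype_component_means(H, c("g1", "g2"))
  expect_equal(gm2[genotype == "g1"]$comp_1, 1)
  # permutation invariance
  perm <- c(2, 1)
  gm3 <- genotype_component_means(H[, perm], c("g2", "g1"))
  expect_equal(
    gm3[order(genotype)],
    gm2[order(genotype)]
  )
})

test_that("planted temporal archetypes are recovered by the components", {
  set.seed(77)
  profile_a <- exp(-((1:1440) - 300)^2 / 2e4)
  profile_b <- c(rep(0.05, 720), rep(0.9, 720))
  mix <- function(p) {
    w <- p / max(p)
    vapply(seq_len(25), function(i) {
      pmax(w * runif(1, 0.5, 1) + rnorm(1440, 0, 0.02), 0)
    }, numeric(1440))
  }
  M <- cbind(mix(profile_a), mix(profile_b))
  d <- fit_nmf(M, 2, seed = 4)
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  sims <- outer(
    seq_len(2), seq_len(2),
    Vectorize(function(i, j) {
      cosine(cbind(profile_a, profile_b)[, i], d$W[, j])
    })
  )
  # each planted profile matches some component closely
  expect_true(all(apply(sims, 1, max) > 0.9))
})
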