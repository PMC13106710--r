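#' Replicate data for one gene pair
#'
#' @param single_a,single_b,double Normalized (fraction-of-control)
#'   replicate amplitudes for the two single mutants and the double
#'   mutant; each needs at least 5 positive values.
#' @return An object of class `pair_data`.
#' @export
pair_data <- function(single_a, single_b, double) {
  for (v in list(single_a, single_b, double)) {
    if (length(v) < 5 || any(v <= 0)) {
      stop("each replicate list needs >= 5 values > 0")
    }
  }
  structure(
    list(single_a = single_a, single_b = single_b, double = double),
    class = "pair_data"
  )
}

#' Bayesian model for one gene pair (JAGS specification)
#'
#' The single-mutant fractions follow scaled-Beta priors,
#' `alpha, beta ~ 1.05 * Beta(2, 5)` (support just above 1 allows minor
#' increases; prior mean 0.30), and the additive interaction term follows
#' `iota ~ Normal(0, 1)`. The double mutant contributes
#' `alpha * beta + iota`. Replicate noise is Normal per genotype with
#' weakly-informative HalfNormal(0.2) scale priors on the normalized
#' scale.
#'
#' @param data A [pair_data()] object (validated; the model itself is a
#'   fixed specification).
#' @return JAGS model string.
#' @export
build_gi_model <- function(data) {
  stopifnot(inherits(data, "pair_data"))
  "model {
    a_raw ~ dbeta(2, 5)
    b_raw ~ dbeta(2, 5)
    alpha <- 1.05 * a_raw
    beta <- 1.05 * b_raw
    iota ~ dnorm(0, 1)
    sigma_a ~ dnorm(0, 25) T(0,)
    sigma_b ~ dnorm(0, 25) T(0,)
    sigma_d ~ dnorm(0, 25) T(0,)
    for (i in 1:na) { ya[i] ~ dnorm(alpha, pow(sigma_a, -2)) }
    for (i in 1:nb) { yb[i] ~ dnorm(beta, pow(sigma_b, -2)) }
    for (i in 1:nd) { yd[i] ~ dnorm(alpha * beta + iota, pow(sigma_d, -2)) }
  }"
}

#' Highest density interval of a posterior sample
#'
#' The narrowest interval containing the stated posterior mass, found by
#' sliding a window over the sorted draws.
#'
#' @param draws Numeric posterior sample.
#' @param mass Posterior mass (default 0.95).
#' @return Numeric `c(low, high)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  stopifnot(mass > 0, mass <= 1, length(draws) >= 2)
  s <- sort(draws)
  n <- length(s)
  m <- ceiling(mass * n)
  if (m >= n) {
    return(c(s[1], s[n]))
  }
  widths <- s[(m + 1):n] - s[1:(n - m)]
  i <- which.min(widths)
  c(s[i], s[i + m])
}

# Split-R-hat (Gelman et al.): chains split in half, between/within
# variance ratio.
split_rhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    h <- length(ch) %/% 2
    halves[[length(halves) + 1L]] <- ch[seq_len(h)]
    halves[[length(halves) + 1L]] <- ch[(h + 1):(2 * h)]
  }
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  b <- n * var(means)
  w <- mean(vars)
  if (w == 0) {
    return(1)
  }
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Sample the posterior for one gene pair
#'
#' Runs MCMC (JAGS) on the model of [build_gi_model()] and applies the
#' 95%-HDI decision rule to the interaction term: the pair is called
#' interacting when 0 lies outside the interval.
#'
#' @param data A [pair_data()] object.
#' @param draws Post-warmup draws per chain (default 2000).
#' @param warmup Warmup/adaptation iterations (default 1000).
#' @param chains Number of chains (default 4, >= 2).
#' @param seed Integer seed; chain seeds derive from it.
#' @param mass HDI mass (default 0.95).
#' @return An object of class `gi_posterior`: pooled `iota_draws`,
#'   `iota_mean`, `hdi_low`, `hdi_high`, `interacting`, `rhat`,
#'   `n_draws`, `seed`. A split-R-hat above 1.01 triggers a warning.
#' @export
fit_gi_bayes <- function(data, draws = 2000, warmup = 1000, chains = 4,
                         seed = 1L, mass = 0.95) {
  stopifnot(inherits(data, "pair_data"), chains >= 2, draws >= 1000)
  inits <- lapply(seq_len(chains), function(i) {
    list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = derive_seed(seed, i)
    )
  })
  model <- rjags::jags.model(
    textConnection(build_gi_model(data)),
    data = list(
      ya = data$single_a, yb = data$single_b, yd = data$double,
      na = length(data$single_a), nb = length(data$single_b),
      nd = length(data$double)
    ),
    inits = inits, n.chains = chains, n.adapt = warmup, quiet = TRUE
  )
  samp <- rjags::coda.samples(model, "iota",
    n.iter = draws,
    progress.bar = "none"
  )
  per_chain <- lapply(samp, function(ch) as.numeric(ch[, "iota"]))
  pooled <- unlist(per_chain, use.names = FALSE)
  rhat <- split_rhat(per_chain)
  if (is.finite(rhat) && rhat > 1.01) {
    warning(sprintf("split-R-hat %.3f > 1.01: chains may not have converged", rhat))
  }
  interval <- hdi(pooled, mass)
  structure(
    list(
      iota_draws = pooled, iota_mean = mean(pooled),
      hdi_low = interval[1], hdi_high = interval[2],
      interacting = interval[1] > 0 || interval[2] < 0,
      rhat = rhat, n_draws = length(pooled), seed = as.integer(seed),
      mass = mass
    ),
    class = "gi_posterior"
  )
}

#' @export
print.gi_posterior <- function(x, ...) {
  cat(sprintf(
    "iota = %.3f, %d%% HDI [%.3f, %.3f], %s (R-hat %.3f)\n",
    x$iota_mean, round(100 * x$mass), x$hdi_low, x$hdi_high,
    if (x$interacting) "interacting" else "not interacting", x$rhat
  ))
  invisible(x)
}

#' HDI decision rule
#'
#' @param posterior A `gi_posterior`.
#' @return `TRUE` iff 0 lies outside the HDI.
#' @export
call_interaction <- function(posterior) {
  stopifnot(inherits(posterior, "gi_posterior"))
  posterior$hdi_low > 0 || posterior$hdi_high < 0
}

#' Bayesian screen over all pairs of an ERG table
#'
#' @param erg ERG table (see [normalize_to_control()]).
#' @param draws,warmup,chains,seed Passed to [fit_gi_bayes()]; per-pair
#'   seeds derive from `seed`.
#' @return `data.table(gene_a, gene_b, iota_mean, hdi_low, hdi_high,
#'   interacting, rhat)`.
#' @export
bayes_gi_screen <- function(erg, draws = 2000, warmup = 1000, chains = 4,
                            seed = 1L) {
  dt <- normalize_to_control(erg)
  singles <- split(
    dt[is_control == FALSE & is.na(genotype_b)]$norm_amplitude,
    dt[is_control == FALSE & is.na(genotype_b)]$genotype_a
  )
  doubles <- dt[is_control == FALSE & !is.na(genotype_b)]
  doubles[, `:=`(
    gene_a = pmin(genotype_a, genotype_b),
    gene_b = pmax(genotype_a, genotype_b)
  )]
  pairs <- unique(doubles[, .(gene_a, gene_b)])
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pa <- pairs$gene_a[i]
    pb <- pairs$gene_b[i]
    pd <- pair_data(
      singles[[pa]], singles[[pb]],
      doubles[gene_a == pa & gene_b == pb]$norm_amplitude
    )
    fit <- fit_gi_bayes(pd,
      draws = draws, warmup = warmup, chains = chains,
      seed = derive_seed(seed, i)
    )
    rows[[i]] <- data.table(
      gene_a = pa, gene_b = pb, iota_mean = fit$iota_mean,
      hdi_low = fit$hdi_low, hdi_high = fit$hdi_high,
      interacting = fit$interacting, rhat = fit$rhat
    )
  }
  rbindlist(rows)
}
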