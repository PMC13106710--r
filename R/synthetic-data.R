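#' Behavioral archetype for the track generator
#'
#' An archetype parameterizes one simulated genotype: a per-minute target
#' sleep-occupancy curve over the 24-h day plus bout, latency, anticipation
#' and locomotion parameters. The generator realizes these targets with a
#' two-state (asleep/awake) semi-Markov process whose hazards are modulated
#' by clock time (see [generate_tracks()]).
#'
#' The process is over-determined if the occupancy curve, the mean bout
#' length and the bout rate are all chosen freely: the stationary sleep
#' fraction at clock minute `m` equals `lambda(m) / (lambda(m) + mu(m))`
#' with onset hazard `lambda(m) = r * c(m)` and wake hazard
#' `mu(m) = mu0 * (1 - c(m))`, so occupancy follows the curve exactly when
#' `r = mu0` while sleep bouts are longest where the curve is high. `mu0`
#' is set from the night-mean bout length; when `bout_rate_night` is left
#' `NULL` it is set to the consistent value `3600 * mu0 * mean(c_night)`
#' (bouts per awake-hour), so the realized occupancy converges to the
#' curve.
#'
#' @param genotype_label Genotype identifier.
#' @param sleep_intensity_curve Numeric vector of 1440 per-minute target
#'   sleep-occupancy values in `[0, 1]`, indexed by Zeitgeber minute
#'   (minute 0 = lights on).
#' @param mean_bout_length_night Mean sleep-bout duration in seconds (> 0).
#' @param bout_rate_night Sleep-onset rate at night in bouts per awake-hour,
#'   or `NULL` to derive the value consistent with the curve.
#' @param latency_lights_off Mean delay (seconds) from lights-off to the
#'   first possible sleep onset of each night.
#' @param anticipation_ramp Fraction in `[0, 1]`; strength of the activity
#'   ramp during the final 3 h of the night (0 = none).
#' @param awake_speed_mean,awake_speed_sd Speed of awake flies in mm/s.
#' @return An object of class `archetype_spec`.
#' @export
archetype <- function(genotype_label,
                      sleep_intensity_curve,
                      mean_bout_length_night = 20 * 60,
                      bout_rate_night = NULL,
                      latency_lights_off = 30 * 60,
                      anticipation_ramp = 0.3,
                      awake_speed_mean = 2,
                      awake_speed_sd = 1) {
  stopifnot(is.character(genotype_label), length(genotype_label) == 1L)
  if (length(sleep_intensity_curve) != 1440L) {
    stop("sleep_intensity_curve must have exactly 1440 entries")
  }
  if (any(sleep_intensity_curve < 0) || any(sleep_intensity_curve > 1)) {
    stop("sleep_intensity_curve values must lie in [0, 1]")
  }
  if (mean_bout_length_night <= 0 || latency_lights_off <= 0 ||
    awake_speed_mean <= 0 || awake_speed_sd <= 0) {
    stop("rates and durations must be strictly positive")
  }
  if (anticipation_ramp < 0 || anticipation_ramp > 1) {
    stop("anticipation_ramp must lie in [0, 1]")
  }
  if (is.null(bout_rate_night)) {
    # value consistent with the curve and bout length (see minute_hazards)
    night <- 721:1440 # ZT12-ZT24 at 12:12
    c_night <- sleep_intensity_curve[night]
    mu0 <- mean(1 / pmax(1 - c_night, 1e-3)) / mean_bout_length_night
    bout_rate_night <- max(3600 * mu0 * mean(c_night), 1e-6)
  }
  if (bout_rate_night <= 0) stop("bout_rate_night must be strictly positive")
  structure(
    list(
      genotype_label = genotype_label,
      sleep_intensity_curve = sleep_intensity_curve,
      mean_bout_length_night = mean_bout_length_night,
      bout_rate_night = bout_rate_night,
      latency_lights_off = latency_lights_off,
      anticipation_ramp = anticipation_ramp,
      awake_speed_mean = awake_speed_mean,
      awake_speed_sd = awake_speed_sd
    ),
    class = "archetype_spec"
  )
}


#' Canonical archetypes used throughout the examples and tests
#'
#' Three study conditions: a control-like sleeper, a "reduced sleep"
#' genotype (group-A-like: low sleep day and night), and a "morning sleep"
#' genotype (group-B-like: increased sleep with a morning bout, short
#' latency after lights-off and reduced morning anticipation).
#'
#' @param genotype_label Label for the returned archetype.
#' @return An `archetype_spec`.
#' @name archetype_presets
NULL

#' @rdname archetype_presets
#' @export
archetype_control <- function(genotype_label = "control") {
  zt <- (seq_len(1440) - 0.5) / 60 # hours
  day_siesta <- 0.35 * exp(-((zt - 7)^2) / 8)
  night <- ifelse(zt >= 12, 0.75 - 0.25 * pmax(0, (zt - 21) / 3), 0.05)
  curve <- pmin(1, pmax(0, day_siesta + night))
  archetype(genotype_label, curve,
    mean_bout_length_night = 20 * 60,
    latency_lights_off = 40 * 60, anticipation_ramp = 0.35
  )
}

#' @rdname archetype_presets
#' @export
archetype_reduced_sleep <- function(genotype_label = "reduced_sleep") {
  zt <- (seq_len(1440) - 0.5) / 60
  curve <- ifelse(zt >= 12, 0.35 - 0.15 * pmax(0, (zt - 21) / 3), 0.05)
  curve <- pmin(1, pmax(0, curve))
  archetype(genotype_label, curve,
    mean_bout_length_night = 8 * 60,
    latency_lights_off = 80 * 60, anticipation_ramp = 0.35
  )
}

#' @rdname archetype_presets
#' @export
archetype_morning_sleep <- function(genotype_label = "morning_sleep") {
  zt <- (seq_len(1440) - 0.5) / 60
  morning_bout <- 0.65 * exp(-((zt - 1.5)^2) / 2)
  day <- 0.30 * exp(-((zt - 8)^2) / 8)
  # strong early-night sleep declining toward dawn: the longest bout sits
  # right after lights-off, giving the short latency of this phenotype
  night <- ifelse(zt >= 12, 0.92 - 0.25 * (zt - 12) / 12, 0)
  curve <- pmin(1, pmax(0, morning_bout + day + night))
  archetype(genotype_label, curve,
    mean_bout_length_night = 35 * 60,
    latency_lights_off = 8 * 60, anticipation_ramp = 0
  )
}

#' Track-simulation configuration
#'
#' @param n_flies_per_genotype Flies simulated per archetype.
#' @param n_days Recording length in days (>= 2; the first day is meant to
#'   be discarded downstream as habituation).
#' @param fps Frames per second (default 2).
#' @param photoperiod Hours of light per 24 h, in `(0, 24)` (default 12).
#' @param seed Integer seed; all per-fly streams derive from it.
#' @param tube_length Tube length in mm (default 65).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_flies_per_genotype,
                              n_days = 6,
                              fps = 2,
                              photoperiod = 12,
                              seed = 1L,
                              tube_length = 65) {
  if (fps <= 0) stop("fps must be > 0")
  if (n_days < 2) stop("n_days must be >= 2")
  if (photoperiod <= 0 || photoperiod >= 24) {
    stop("photoperiod must lie in (0, 24)")
  }
  if (n_flies_per_genotype < 1) stop("need at least one fly per genotype")
  if (tube_length <= 0) stop("tube_length must be > 0")
  structure(
    list(
      n_flies_per_genotype = as.integer(n_flies_per_genotype),
      n_days = as.integer(n_days), fps = fps,
      photoperiod = photoperiod, seed = as.integer(seed),
      tube_length = tube_length
    ),
    class = "simulation_config"
  )
}

# Per-minute hazards for one fly-day cycle, before per-night latency gating.
# Occupancy c(m) is split as onset = r * c(m), wake = mu0 * (1 - c(m)), so
# the stationary occupancy is c(m) when r = mu0 while bouts are longest
# where the curve is high. mu0 comes from the night-mean bout length and r
# from bout_rate_night (equal to mu0 for a consistent archetype).
# Returns list(onset, wake): hazards per second, length 1440.
minute_hazards <- function(arch, photoperiod) {
  curve <- arch$sleep_intensity_curve
  night_min <- which((seq_len(1440) - 1) / 60 >= photoperiod)
  c_night <- curve[night_min]
  mu0 <- mean(1 / pmax(1 - c_night, 1e-3)) / arch$mean_bout_length_night
  r <- if (mean(c_night) > 0) {
    (arch$bout_rate_night / 3600) / mean(c_night)
  } else {
    mu0
  }
  onset <- r * curve
  # lower floor than in mu0: a curve at 1 is near-absorbing sleep, with
  # rare micro-arousals so terminal-immobility QC does not fire
  wake <- mu0 * pmax(1 - curve, 1e-4)
  # anticipation: ramping wake pressure and suppressed sleep onset over the
  # final 3 h of the night
  last3 <- which((seq_len(1440) - 0.5) / 60 >= 21 & (seq_len(1440) - 1) / 60 >= photoperiod)
  if (length(last3) && arch$anticipation_ramp > 0) {
    phi <- seq_along(last3) / length(last3)
    onset[last3] <- onset[last3] * (1 - arch$anticipation_ramp * phi)
    wake[last3] <- wake[last3] * (1 + 3 * arch$anticipation_ramp * phi)
  }
  list(onset = onset, wake = wake)
}

# Simulate the asleep/awake state sequence for one fly at 1-s resolution,
# returned run-length encoded as data.table(state, start, end).
simulate_states <- function(arch, config) {
  total <- config$n_days * 86400
  hz <- minute_hazards(arch, config$photoperiod)
  lights_off <- config$photoperiod * 3600
  # per-night latency after lights-off during which sleep onset is gated off
  latency <- rexp(config$n_days, rate = 1 / arch$latency_lights_off)
  onset_sec <- rep(hz$onset, times = config$n_days)[
    rep(seq_len(1440 * config$n_days), each = 60)[seq_len(total)]
  ]
  # gate: zero onset hazard in [lights_off, lights_off + latency) each day
  for (d in seq_len(config$n_days)) {
    from <- (d - 1) * 86400 + lights_off
    to <- min(from + latency[d], d * 86400)
    if (floor(to) > floor(from)) onset_sec[(floor(from) + 1):floor(to)] <- 0
  }
  wake_sec <- rep(hz$wake, times = config$n_days)[
    rep(seq_len(1440 * config$n_days), each = 60)[seq_len(total)]
  ]
  cum_onset <- cumsum(onset_sec)
  cum_wake <- cumsum(wake_sec)
  states <- integer(256)
  starts <- numeric(256)
  n_ev <- 0L
  cur <- 0
  state <- 0L # 0 awake, 1 asleep
  while (cur < total) {
    cum <- if (state == 0L) cum_onset else cum_wake
    idx0 <- floor(cur) + 1
    base <- if (idx0 > 1) cum[idx0 - 1] else 0
    # binary search: first second whose cumulative hazard reaches the
    # exponential target
    v <- base + rexp(1)
    if (cum[total] < v) {
      hit <- total + 1L
    } else {
      lo <- idx0
      hi <- total
      while (lo < hi) {
        mid <- (lo + hi) %/% 2L
        if (cum[mid] >= v) hi <- mid else lo <- mid + 1L
      }
      hit <- lo
    }
    nxt <- if (hit > total) total else hit
    n_ev <- n_ev + 1L
    if (n_ev > length(states)) {
      length(states) <- 2L * length(states)
      length(starts) <- 2L * length(starts)
    }
    states[n_ev] <- state
    starts[n_ev] <- cur
    cur <- nxt
    state <- 1L - state
  }
  states <- states[seq_len(n_ev)]
  starts <- starts[seq_len(n_ev)]
  data.table(
    state = states, start = starts,
    end = c(starts[-1], total)
  )
}

#' Generate a positional track for one fly
#'
#' @param config A [simulation_config()].
#' @param arch An [archetype()].
#' @param fly_index Integer index used (with `config$seed`) to derive this
#'   fly's private random stream, and to label the fly.
#' @return A `data.table` with columns `fly_id`, `genotype`, `t` (seconds),
#'   `x`, `y` (mm) at `1/fps` spacing.
#' @export
generate_fly_track <- function(config, arch, fly_index = 1L) {
  stopifnot(inherits(config, "simulation_config"), inherits(arch, "archetype_spec"))
  with_preserved_rng({
    set.seed(derive_seed(config$seed, fly_index))
    dt <- 1 / config$fps
    n_frames <- config$n_days * 86400 * config$fps
    runs <- simulate_states(arch, config)
    # per-frame state via run lengths in frames
    frame_counts <- round(runs$end * config$fps) - round(runs$start * config$fps)
    state <- rep(runs$state, times = frame_counts)
    length(state) <- n_frames # guard rounding
    state[is.na(state)] <- runs$state[nrow(runs)]
    # displacement magnitudes: awake ~ |N(mean*dt, sd*dt)|, asleep ~ U(0, 0.1)
    step <- numeric(n_frames)
    awake <- state == 0L
    step[awake] <- abs(rnorm(
      sum(awake),
      arch$awake_speed_mean * dt, arch$awake_speed_sd * dt
    ))
    step[!awake] <- runif(sum(!awake), 0, 0.1)
    dir <- sample(c(-1, 1), n_frames, replace = TRUE)
    z <- runif(1, 0, config$tube_length) + cumsum(step * dir)
    # reflecting boundary: fold onto [0, tube_length]
    l <- config$tube_length
    zm <- z %% (2 * l)
    x <- l - abs(zm - l)
    y <- 1.5 + rnorm(n_frames, 0, 0.01)
    data.table(
      fly_id = sprintf("%s|fly%03d", arch$genotype_label, fly_index),
      genotype = arch$genotype_label,
      t = (seq_len(n_frames) - 1) * dt,
      x = x, y = y
    )
  })
}

#' Generate positional tracks for a cohort
#'
#' Simulates `config$n_flies_per_genotype` flies for every archetype with a
#' two-state (asleep/awake) semi-Markov movement model whose hazards follow
#' each archetype's occupancy curve, latency and anticipation parameters.
#' Output is bit-identical for identical seeds and configurations.
#'
#' @inheritParams generate_fly_track
#' @param archetypes List of [archetype()] objects (at least one).
#' @return Long-format `data.table` with columns
#'   `fly_id, genotype, t, x, y`.
#' @export
generate_tracks <- function(config, archetypes) {
  if (inherits(archetypes, "archetype_spec")) archetypes <- list(archetypes)
  if (!length(archetypes)) stop("need at least one archetype")
  out <- vector("list", length(archetypes) * config$n_flies_per_genotype)
  i <- 0L
  for (a in seq_along(archetypes)) {
    for (f in seq_len(config$n_flies_per_genotype)) {
      i <- i + 1L
      out[[i]] <- generate_fly_track(
        config, archetypes[[a]],
        fly_index = (a - 1L) * config$n_flies_per_genotype + f
      )
    }
  }
  rbindlist(out)
}

#' Planted two-group cohort of genotype archetypes
#'
#' Builds a cohort of genotypes with known group structure for recovery
#' experiments: `n_a` genotypes derived from the reduced-sleep archetype
#' (group A-like) and `n_b` from the morning-sleep archetype (group
#' B-like), each with deterministic per-genotype perturbations of the
#' occupancy curve and bout length so genotypes within a group are
#' similar but not identical.
#'
#' @param n_a,n_b Genotypes per group.
#' @param jitter Relative spread of the per-genotype perturbations.
#' @return List with `archetypes` (length `n_a + n_b`) and `groups`
#'   (named character vector genotype -> "A"/"B").
#' @export
planted_cohort_archetypes <- function(n_a = 6, n_b = 6, jitter = 0.15) {
  scale_arch <- function(base, label, f) {
    archetype(
      label,
      pmin(1, base$sleep_intensity_curve * f),
      mean_bout_length_night = base$mean_bout_length_night * (2 - f),
      latency_lights_off = base$latency_lights_off,
      anticipation_ramp = base$anticipation_ramp,
      awake_speed_mean = base$awake_speed_mean,
      awake_speed_sd = base$awake_speed_sd
    )
  }
  fa <- if (n_a > 1) seq(1 - jitter, 1 + jitter, length.out = n_a) else 1
  fb <- if (n_b > 1) seq(1 - jitter, 1 + jitter, length.out = n_b) else 1
  base_a <- archetype_reduced_sleep()
  base_b <- archetype_morning_sleep()
  archs <- c(
    lapply(seq_len(n_a), function(i) {
      scale_arch(base_a, sprintf("A_gene%02d", i), fa[i])
    }),
    lapply(seq_len(n_b), function(i) {
      scale_arch(base_b, sprintf("B_gene%02d", i), fb[i])
    })
  )
  groups <- setNames(
    rep(c("A", "B"), c(n_a, n_b)),
    vapply(archs, function(a) a$genotype_label, "")
  )
  list(archetypes = archs, groups = groups)
}

#' ERG-simulation specification
#'
#' Ground-truth model for the electroretinogram screen: each genotype `g`
#' scales the control depolarization by `single_effect[g]`, a double mutant
#' of `A` and `B` realizes `effect_A * effect_B + interaction` (the
#' multiplicative non-interacting expectation plus an additive ground-truth
#' interaction term), and replicates add Gaussian noise. Batches carry their
#' own control level (5% CV) to exercise per-batch normalization.
#'
#' @param control_mean Control depolarization amplitude in mV.
#' @param single_effect Named numeric vector: genotype -> fraction of
#'   control in `(0, 1.05]`.
#' @param interaction_term Named numeric vector of additive interaction
#'   terms (fraction units); names are `"A:B"` unordered pairs. Pairs not
#'   listed default to 0.
#' @param replicate_sd Replicate noise sd in fraction-of-control units (> 0).
#' @param n_replicates_per_genotype Replicates per genotype/pair (>= 5).
#' @param n_batches Number of experiment batches.
#' @param seed Integer seed.
#' @param pairs Optional list/character of pairs to simulate (default: all
#'   unordered pairs of the singles).
#' @return An object of class `erg_sim_spec`.
#' @export
erg_sim_spec <- function(control_mean = 10,
                         single_effect,
                         interaction_term = numeric(0),
                         replicate_sd = 0.05,
                         n_replicates_per_genotype = 10,
                         n_batches = 3,
                         seed = 1L,
                         pairs = NULL) {
  stopifnot(
    is.numeric(single_effect), !is.null(names(single_effect)),
    all(nzchar(names(single_effect)))
  )
  if (any(single_effect <= 0) || any(single_effect > 1.05)) {
    stop("single effects must lie in (0, 1.05]")
  }
  if (replicate_sd <= 0) stop("replicate_sd must be > 0")
  if (n_replicates_per_genotype < 5) {
    stop("n_replicates_per_genotype must be >= 5")
  }
  genes <- names(single_effect)
  if (is.null(pairs)) {
    pairs <- enumerate_pairs(genes)
  } else if (is.character(pairs)) {
    pairs <- strsplit(pairs, ":", fixed = TRUE)
  }
  for (p in pairs) {
    if (!all(p %in% genes)) {
      stop(
        "pair references unknown genotype: ",
        paste(setdiff(p, genes), collapse = ", ")
      )
    }
  }
  it <- setNames(numeric(length(pairs)), vapply(pairs, pair_key, ""))
  if (length(interaction_term)) {
    keys <- vapply(
      strsplit(names(interaction_term), ":", fixed = TRUE), pair_key, ""
    )
    if (!all(keys %in% names(it))) {
      stop(
        "interaction_term references unknown pair: ",
        paste(setdiff(keys, names(it)), collapse = ", ")
      )
    }
    it[keys] <- unname(interaction_term)
  }
  structure(
    list(
      control_mean = control_mean, single_effect = single_effect,
      interaction_term = it, replicate_sd = replicate_sd,
      n_replicates = as.integer(n_replicates_per_genotype),
      n_batches = as.integer(n_batches), seed = as.integer(seed),
      pairs = pairs
    ),
    class = "erg_sim_spec"
  )
}

pair_key <- function(p) paste(sort(p), collapse = ":")

#' Generate an ERG replicate table
#'
#' @param spec An [erg_sim_spec()].
#' @return A `data.table` with columns `batch, genotype_a, genotype_b,
#'   amplitude, is_control` (`genotype_b` is `NA` for controls and single
#'   mutants). Every batch contains control rows; experimental units
#'   (singles and pairs) are distributed round-robin across batches.
#' @export
generate_erg <- function(spec) {
  stopifnot(inherits(spec, "erg_sim_spec"))
  with_preserved_rng({
    set.seed(spec$seed)
    n <- spec$n_replicates
    batch_ctrl <- rnorm(spec$n_batches, spec$control_mean, 0.05 * spec$control_mean)
    rows <- list()
    for (b in seq_len(spec$n_batches)) {
      rows[[length(rows) + 1L]] <- data.table(
        batch = sprintf("batch%02d", b),
        genotype_a = "control", genotype_b = NA_character_,
        amplitude = rnorm(n, batch_ctrl[b], spec$replicate_sd * spec$control_mean),
        is_control = TRUE
      )
    }
    units <- c(
      lapply(names(spec$single_effect), function(g) list(a = g, b = NA_character_)),
      lapply(spec$pairs, function(p) list(a = p[1], b = p[2]))
    )
    for (i in seq_along(units)) {
      u <- units[[i]]
      b <- (i - 1L) %% spec$n_batches + 1L
      frac <- if (is.na(u$b)) {
        spec$single_effect[[u$a]]
      } else {
        spec$single_effect[[u$a]] * spec$single_effect[[u$b]] +
          spec$interaction_term[[pair_key(c(u$a, u$b))]]
      }
      if (frac <= 0) {
        stop("implied mean amplitude is non-positive for unit ", u$a)
      }
      amp <- rnorm(n, batch_ctrl[b] * frac, spec$replicate_sd * spec$control_mean)
      rows[[length(rows) + 1L]] <- data.table(
        batch = sprintf("batch%02d", b),
        genotype_a = u$a, genotype_b = u$b,
        amplitude = pmax(amp, 1e-6), # amplitudes are physical, > 0
        is_control = FALSE
      )
    }
    rbindlist(rows)
  })
}

#' Ground truth attached to a simulation
#'
#' @param spec An [erg_sim_spec()].
#' @return `data.table(gene_a, gene_b, iota, class)` where `class` is the
#'   sign of the injected interaction (`alleviating` for positive,
#'   `aggravating` for negative, `none` for zero).
#' @export
erg_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "erg_sim_spec"))
  keys <- strsplit(names(spec$interaction_term), ":", fixed = TRUE)
  data.table(
    gene_a = vapply(keys, `[`, "", 1L),
    gene_b = vapply(keys, `[`, "", 2L),
    iota = unname(spec$interaction_term),
    class = ifelse(spec$interaction_term > 0, "alleviating",
      ifelse(spec$interaction_term < 0, "aggravating", "none")
    )
  )
}
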