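test_that("archetype and config validation rejects bad parameters", {
  curve <- rep(0.5, 1440)
  expect_error(archetype("g", rep(0.5, 100)), "1440")
  expect_error(archetype("g", curve - 1), "\\[0, 1\\]")
  expect_error(archetype("g", curve, mean_bout_length_night = 0), "positive")
  expect_error(archetype("g", curve, anticipation_ramp = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(5, n_days = 1), "n_days")
  expect_error(simulation_config(5, fps = 0), "fps")
  expect_error(simulation_config(5, photoperiod = 24), "photoperiod")
})

test_that("track generation is bit-identical for identical seeds", {
  cfg <- simulation_config(2, n_days = 2, seed = 11)
  a <- archetype_control()
  t1 <- generate_tracks(cfg, list(a))
  t2 <- generate_tracks(cfg, list(a))
  expect_identical(t1, t2)
  t3 <- generate_tracks(simulation_config(2, n_days = 2, seed = 12), list(a))
  expect_false(identical(t1$x, t3$x))
})

test_that("tracks respect the tube geometry and frame spacing", {
  cfg <- simulation_config(1, n_days = 2, seed = 3, tube_length = 65)
  tr <- generate_fly_track(cfg, archetype_control(), 1)
  expect_true(all(tr$x >= 0 & tr$x <= 65))
  expect_equal(unique(round(diff(tr$t), 9)), 0.5)
  expect_equal(nrow(tr), 2 * 86400 * 2)
})

test_that("always-asleep and never-immobile limits propagate to sleep", {
  cfg <- simulation_config(2, n_days = 2, seed = 5)
  asleep_arch <- archetype("sleeper", rep(1, 1440),
    bout_rate_night = 1e5, latency_lights_off = 1
  )
  res <- fly_features(generate_tracks(cfg, list(asleep_arch)),
    sleep_vector = FALSE
  )
  expect_true(all(res$features$sleep_fraction_day > 0.95))
  expect_true(all(res$features$sleep_fraction_night > 0.95))

  awake_arch <- archetype("waker", rep(0, 1440))
  res0 <- fly_features(generate_tracks(cfg, list(awake_arch)),
    sleep_vector = FALSE
  )
  expect_true(all(res0$features$sleep_fraction_day == 0))
  expect_true(all(res0$features$sleep_fraction_night == 0))
})

test_that("planted group archetypes separate in the generating direction", {
  # group-B-like (morning sleep, short latency) vs group-A-like (low sleep)
  cfg <- simulation_config(20, n_days = 2, seed = 21)
  res <- fly_features(
    generate_tracks(cfg, list(archetype_reduced_sleep(), archetype_morning_sleep())),
    sleep_vector = FALSE
  )
  m <- res$features[, .(
    sf = mean(sleep_fraction_night),
    lat = mean(latency_longest_bout)
  ), by = genotype]
  expect_gt(
    m[genotype == "morning_sleep"]$sf,
    m[genotype == "reduced_sleep"]$sf
  )
  expect_lt(
    m[genotype == "morning_sleep"]$lat,
    m[genotype == "reduced_sleep"]$lat
  )
})

test_that("realized sleep occupancy converges to the archetype curve", {
  zt <- (seq_len(1440) - 0.5) / 60
  curve <- ifelse(zt >= 12, 0.6, 0.2)
  a <- archetype("clean", curve,
    mean_bout_length_night = 30 * 60,
    latency_lights_off = 120, anticipation_ramp = 0
  )
  cfg <- simulation_config(50, n_days = 2, seed = 7)
  res <- fly_features(generate_tracks(cfg, list(a)), sleep_vector = FALSE)
  realized <- res$features[, mean(
    (sleep_fraction_day * 12 + sleep_fraction_night * 12) / 24
  )]
  expect_lt(abs(realized - mean(curve)), 0.05)
  expect_lt(abs(res$features[, mean(sleep_fraction_night)] - 0.6), 0.05)
  expect_lt(abs(res$features[, mean(sleep_fraction_day)] - 0.2), 0.05)
})

test_that("erg spec validation enforces the replicate and pair rules", {
  eff <- c(a = 0.5, b = 0.5)
  expect_error(
    erg_sim_spec(single_effect = eff, n_replicates_per_genotype = 4),
    ">= 5"
  )
  expect_error(
    erg_sim_spec(single_effect = eff, replicate_sd = 0),
    "replicate_sd"
  )
  expect_error(
    erg_sim_spec(single_effect = eff, interaction_term = c("a:zz" = 0.5)),
    "unknown pair"
  )
  expect_error(
    erg_sim_spec(single_effect = c(a = 1.2, b = 0.5)),
    "\\(0, 1.05\\]"
  )
})

test_that("erg tables are seed-reproducible with per-batch controls", {
  spec <- erg_sim_spec(
    single_effect = c(a = 0.5, b = 0.5, c = 0.9),
    seed = 13, n_batches = 2
  )
  e1 <- generate_erg(spec)
  expect_identical(e1, generate_erg(spec))
  expect_true(all(e1$amplitude > 0))
  ctrl_batches <- unique(e1[is_control == TRUE]$batch)
  expect_setequal(ctrl_batches, unique(e1$batch))
})

test_that("double-mutant means follow the multiplicative model", {
  # two 50% singles with no interaction give a double at ~25% of control
  spec <- erg_sim_spec(
    single_effect = c(a = 0.5, b = 0.5),
    replicate_sd = 0.02, n_replicates_per_genotype = 200,
    n_batches = 1, seed = 2
  )
  erg <- generate_erg(spec)
  norm <- normalize_to_control(erg)
  dbl <- norm[is_control == FALSE & !is.na(genotype_b)]
  expect_equal(mean(dbl$norm_amplitude), 0.25, tolerance = 0.02)
  # |mean(double)/control - eA*eB| < 3 sd / sqrt(n)
  expect_lt(
    abs(mean(dbl$norm_amplitude) - 0.25),
    3 * 0.02 / sqrt(200)
  )
})

test_that("exact multiplicative null gives vanishing GI strength", {
  spec <- erg_sim_spec(
    single_effect = c(a = 0.5, b = 0.5, c = 0.8),
    replicate_sd = 1e-4, n_replicates_per_genotype = 10,
    n_batches = 1, seed = 4
  )
  rec <- gi_table(generate_erg(spec))
  expect_true(all(abs(rec$strength) < 0.01))
  expect_true(all(rec$class == "none"))
})

test_that("injected interactions are recovered downstream", {
  spec <- erg_sim_spec(
    single_effect = c(a = 0.5, b = 0.5, c = 0.9, d = 0.9),
    interaction_term = c("a:b" = 0.5, "c:d" = -0.5),
    replicate_sd = 0.05, n_replicates_per_genotype = 10, seed = 17
  )
  rec <- gi_table(generate_erg(spec))
  expect_identical(rec[gene_a == "a" & gene_b == "b"]$class, "alleviating")
  expect_identical(rec[gene_a == "c" & gene_b == "d"]$class, "aggravating")
  truth <- erg_ground_truth(spec)
  expect_setequal(
    truth[class != "none", paste(gene_a, gene_b)],
    c("a b", "c d")
  )
})

test_that("track and erg tables round-trip through their text formats", {
  cfg <- simulation_config(1, n_days = 2, seed = 31)
  tr <- generate_fly_track(cfg, archetype_control(), 1)[1:100]
  f <- tempfile(fileext = ".tsv")
  write_tracks(tr, f)
  expect_equal(read_tracks(f), tr, tolerance = 1e-12)
  spec <- erg_sim_spec(single_effect = c(a = 0.5, b = 0.4), seed = 1)
  erg <- generate_erg(spec)
  f2 <- tempfile(fileext = ".tsv")
  write_erg(erg, f2)
  back <- read_erg(f2)
  expect_equal(back$amplitude, erg$amplitude, tolerance = 1e-12)
  expect_identical(back$genotype_b, erg$genotype_b)
})
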