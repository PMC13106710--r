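#' Corrected velocity
#'
#' Rescales a frame-to-frame displacement into the dimensionless corrected
#' velocity used to call movement: `10^(d/1000) / (dt * fps * a)` with
#' `d = 1000 * log10(displacement)`, which reduces to
#' `displacement / (dt * fps * a)`. The correction factor `a = 0.0042` was
#' calibrated so that a displacement at the 0.25 mm immobility threshold
#' maps to a corrected velocity of about 60. A zero displacement returns 0
#' by convention (the log-distance is undefined for a stationary fly).
#'
#' @param displacement Non-negative displacement(s) in mm.
#' @param dt Time between frames in seconds (> 0).
#' @param fps Frames per second.
#' @param a Velocity correction factor (default 0.0042).
#' @return Dimensionless corrected velocity, vectorized over `displacement`.
#' @export
corrected_velocity <- function(displacement, dt = 1, fps = 1, a = 0.0042) {
  if (any(displacement < 0)) stop("displacement must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  ifelse(displacement == 0, 0, displacement / (dt * fps * a))
}

#' Annotate a track on a 10-s grid
#'
#' Splits each fly's positional trace into contiguous 10-s windows anchored
#' at `t = 0` and scores each window as moving if any frame-to-frame
#' Euclidean displacement within it is at least `move_threshold` (the
#' immobility rule is "less than 0.25 mm"). Windows with no frames (gaps
#' longer than one interval) are marked missing, never interpolated.
#'
#' @param track `data.table`/`data.frame` with columns
#'   `fly_id, genotype, t, x, y` (one or many flies).
#' @param move_threshold Immobility threshold in mm (default 0.25).
#' @param interval Window length in seconds (default 10).
#' @param fps Frames per second of the recording; used for the corrected
#'   velocity. If `NULL` it is estimated from the median frame spacing.
#' @param a Velocity correction factor passed to [corrected_velocity()].
#' @return A `data.table` with one row per window and fly:
#'   `fly_id, genotype, interval_start, n_frames, moving, max_displacement,
#'   sum_displacement, corrected_velocity, log_distance, missing_interval`.
#' @export
annotate_intervals <- function(track, move_threshold = 0.25, interval = 10,
                               fps = NULL, a = 0.0042) {
  tr <- if (is.data.table(track)) track else as.data.table(track)
  stopifnot(all(c("fly_id", "t", "x", "y") %in% names(tr)))
  if (!"genotype" %in% names(tr)) {
    tr <- copy(tr)[, genotype := NA_character_]
  }
  # sort only when needed (generator output is already ordered)
  if (tr[, is.unsorted(t), by = fly_id][, any(V1)]) {
    tr <- tr[order(fly_id, t)]
  }
  if (is.null(fps)) {
    dts <- tr[, diff(t[seq_len(min(.N, 100L))]), by = fly_id]$V1
    fps <- 1 / stats::median(dts)
  }
  dt_frame <- 1 / fps
  fpw <- round(interval * fps)
  ann <- tr[, {
    # t strictly increasing with total span (N-1)*dt implies uniform spacing
    regular <- .N >= 2L && fpw >= 1L &&
      abs((t[.N] - t[1]) - (.N - 1L) * dt_frame) < 1e-6 &&
      .N %% fpw == 0L && abs(t[1] %% interval) < 1e-9
    if (regular) {
      # gap-free fixed-rate recording: windows have exactly fpw frames
      disp <- c(0, sqrt(diff(x)^2 + diff(y)^2))
      dm <- matrix(disp, nrow = fpw)
      nwin <- ncol(dm)
      mx <- do.call(pmax, lapply(seq_len(fpw), function(i) dm[i, ]))
      nf <- rep(fpw, nwin)
      nf[1] <- fpw - 1L # the first frame has no incoming displacement
      data.table(
        interval_start = t[1] + (seq_len(nwin) - 1) * interval,
        n_frames = as.integer(nf),
        moving = colSums(dm >= move_threshold) > 0L,
        max_displacement = mx,
        sum_displacement = colSums(dm),
        corrected_velocity = corrected_velocity(mx,
          dt = dt_frame,
          fps = fps, a = a
        )
      )
    } else if (.N < 2L) {
      data.table(
        interval_start = numeric(0), n_frames = integer(0),
        moving = logical(0), max_displacement = numeric(0),
        sum_displacement = numeric(0), corrected_velocity = numeric(0)
      )
    } else {
      disp <- sqrt(diff(x)^2 + diff(y)^2) # displacement into frame i+1
      win <- floor(t[-1] / interval)
      g <- data.table(win = win, disp = disp)[, .(
        n_frames = .N,
        moving = any(disp >= move_threshold),
        max_displacement = max(disp),
        sum_displacement = sum(disp)
      ), by = win]
      full <- data.table(win = seq(min(g$win), max(g$win)))
      g <- g[full, on = "win"]
      g[, .(
        interval_start = win * interval,
        n_frames = fifelse(is.na(n_frames), 0L, n_frames),
        moving = fifelse(is.na(moving), FALSE, moving),
        max_displacement = fifelse(is.na(max_displacement), 0, max_displacement),
        sum_displacement = fifelse(is.na(sum_displacement), 0, sum_displacement),
        corrected_velocity = corrected_velocity(
          fifelse(is.na(max_displacement), 0, max_displacement),
          dt = dt_frame, fps = fps, a = a
        )
      )]
    }
  }, by = .(fly_id, genotype)]
  ann[, missing_interval := n_frames == 0L]
  ann[, log_distance := fifelse(
    max_displacement > 0, 1000 * log10(max_displacement), NA_real_
  )]
  ann[]
}

#' Score sleep with the 5-min rule
#'
#' Maximal runs of immobile (non-moving, non-missing) 10-s windows whose
#' total duration exceeds `min_sleep` seconds are sleep bouts; all their
#' windows, including the first five minutes, are flagged asleep.
#'
#' @param annotations Output of [annotate_intervals()].
#' @param min_sleep Minimum immobility run length counted as sleep, in
#'   seconds (default 300; the rule is "longer than 5 min").
#' @param interval Window length in seconds (must match the annotations).
#' @return A list with `annotations` (input plus logical `asleep`) and
#'   `bouts`: `data.table(fly_id, onset, duration)` in seconds.
#' @export
score_sleep <- function(annotations, min_sleep = 300, interval = 10) {
  ann <- copy(as.data.table(annotations))
  setorder(ann, fly_id, interval_start)
  ann[, asleep := {
    immob <- !moving & !missing_interval
    r <- rle(immob)
    keep <- r$values & (r$lengths * interval > min_sleep)
    rep(keep, r$lengths)
  }, by = fly_id]
  bouts <- ann[, {
    immob <- !moving & !missing_interval
    r <- rle(immob)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & (r$lengths * interval > min_sleep)
    data.table(
      onset = interval_start[starts[keep]],
      duration = r$lengths[keep] * interval
    )
  }, by = fly_id]
  list(annotations = ann[], bouts = bouts[])
}

#' Death detection and day-level quality control
#'
#' A fly is flagged dead when it is immobile continuously from some onset
#' until the end of the recording for at least `window` seconds; data from
#' the onset onward are censored. The first recording day is always
#' excluded (habituation).
#'
#' @param annotations Output of [annotate_intervals()] (with or without
#'   sleep scoring).
#' @param window Minimum terminal immobility to call death, in seconds
#'   (default 24 h).
#' @param interval Window length in seconds.
#' @return `data.table(fly_id, dead, death_onset, excluded_days)`;
#'   `excluded_days` is a list column of 1-based day indices.
#' @export
detect_death <- function(annotations, window = 24 * 3600, interval = 10) {
  ann <- as.data.table(annotations)
  setorder(ann, fly_id, interval_start)
  ann[, {
    immob <- !moving & !missing_interval
    r <- rle(immob)
    n <- length(r$values)
    dead <- FALSE
    onset <- NA_real_
    if (n && r$values[n] && r$lengths[n] * interval >= window) {
      dead <- TRUE
      onset <- interval_start[length(immob) - r$lengths[n] + 1L]
    }
    last_day <- floor(max(interval_start) / 86400) + 1
    excl <- 1L
    if (dead) {
      excl <- sort(unique(c(1L, seq.int(floor(onset / 86400) + 1L, last_day))))
    }
    .(dead = dead, death_onset = onset, excluded_days = list(excl))
  }, by = fly_id]
}

# ZT in hours for interval starts.
zt_hours <- function(t, zt0_offset = 0) ((t - zt0_offset) %% 86400) / 3600

# Clip bouts to dark periods, one row per (bout x night) segment.
# Night d covers [day_start + photoperiod*3600, day_start + 86400).
clip_bouts_to_nights <- function(bouts, zt0_offset, photoperiod, t_max) {
  if (!nrow(bouts)) {
    return(data.table(
      fly_id = character(0), night = integer(0),
      onset = numeric(0), duration = numeric(0)
    ))
  }
  out <- list()
  n_days <- ceiling((t_max - zt0_offset) / 86400)
  for (d in seq_len(n_days)) {
    ns <- zt0_offset + (d - 1) * 86400 + photoperiod * 3600
    ne <- zt0_offset + d * 86400
    seg <- bouts[onset < ne & onset + duration > ns]
    if (nrow(seg)) {
      seg <- seg[, .(
        fly_id,
        night = d,
        onset = pmax(onset, ns),
        duration = pmin(onset + duration, ne) - pmax(onset, ns)
      )]
      out[[length(out) + 1L]] <- seg
    }
  }
  if (length(out)) rbindlist(out) else {
    data.table(
      fly_id = character(0), night = integer(0),
      onset = numeric(0), duration = numeric(0)
    )
  }
}

#' Morning anticipation index
#'
#' Per night, activity (count of moving 10-s windows) during the final 3 h
#' of darkness divided by activity during the final 6 h; averaged over
#' nights. 0.5 indicates flat activity, values above 0.5 an anticipatory
#' ramp toward lights-on. Nights with no activity in the final 6 h are
#' undefined and skipped; if no night is defined the result is `NA`.
#'
#' @param annotations Annotations for one fly (or many; computed per fly).
#' @param zt0_offset Experiment time of lights-on, seconds.
#' @param photoperiod Hours of light per 24 h.
#' @param exclude_days Integer day indices to drop (default first day).
#' @return `data.table(fly_id, morning_anticipation)`.
#' @export
morning_anticipation <- function(annotations, zt0_offset = 0,
                                 photoperiod = 12, exclude_days = 1L) {
  ann <- as.data.table(annotations)
  ann <- ann[missing_interval == FALSE]
  ann[, day := floor((interval_start - zt0_offset) / 86400) + 1L]
  ann <- ann[!day %in% exclude_days]
  ann[, zt := zt_hours(interval_start, zt0_offset)]
  dark <- ann[zt >= photoperiod]
  dark[, night := day]
  per_night <- dark[zt >= 18, .(
    last6 = sum(moving),
    last3 = sum(moving & zt >= 21)
  ), by = .(fly_id, night)]
  per_night <- per_night[last6 > 0]
  res <- per_night[, .(morning_anticipation = mean(last3 / last6)), by = fly_id]
  all_flies <- unique(ann[, .(fly_id)])
  res[all_flies, on = "fly_id"][]
}

#' Extract per-fly behavioral features
#'
#' Computes the sleep-architecture and activity features used in the
#' screen, pooled over the retained light and dark cycles (first day and
#' post-death data excluded). Night-level quantities use bouts clipped to
#' each dark period, so a bout spanning several nights contributes one
#' segment per night.
#'
#' @param annotations Annotations with `asleep` flags (from [score_sleep()]).
#' @param bouts Sleep bouts from [score_sleep()].
#' @param qc Output of [detect_death()]; `NULL` to compute it here.
#' @param zt0_offset Experiment time of lights-on, seconds.
#' @param photoperiod Hours of light per 24 h.
#' @param interval Window length in seconds.
#' @return One row per retained fly: `fly_id, genotype,
#'   sleep_fraction_day, sleep_fraction_night, latency_longest_bout
#'   (minutes from lights-off), mean_bout_length_night (minutes),
#'   n_bouts_night, morning_anticipation, velocity_if_awake (mm/s),
#'   total_distance (mm/day)`. Flies with zero retained days are dropped.
#' @export
extract_features <- function(annotations, bouts, qc = NULL, zt0_offset = 0,
                             photoperiod = 12, interval = 10) {
  ann <- as.data.table(annotations)
  stopifnot("asleep" %in% names(ann))
  if (is.null(qc)) qc <- detect_death(ann, interval = interval)
  ann <- ann[missing_interval == FALSE]
  ann[, day := floor((interval_start - zt0_offset) / 86400) + 1L]
  # censor excluded days per fly
  excl <- qc[, .(day = excluded_days[[1]]), by = fly_id]
  all_ids <- unique(ann$fly_id)
  ann <- ann[!excl, on = c("fly_id", "day")]
  dropped <- setdiff(all_ids, unique(ann$fly_id))
  if (length(dropped)) {
    message(
      "dropped ", length(dropped),
      " fly/flies with zero retained days: ",
      paste(head(dropped, 5), collapse = ", ")
    )
  }
  if (!nrow(ann)) {
    return(data.table())
  }
  ann[, zt := zt_hours(interval_start, zt0_offset)]
  ann[, is_light := zt < photoperiod]

  base <- ann[, .(
    genotype = genotype[1],
    sleep_fraction_day = if (any(is_light)) mean(asleep[is_light]) else NA_real_,
    sleep_fraction_night = if (any(!is_light)) mean(asleep[!is_light]) else NA_real_,
    total_distance = sum(sum_displacement) / (.N * interval / 86400),
    n_retained_days = uniqueN(day)
  ), by = fly_id]
  # mm/s over moving windows: summed path length divided by window duration
  vel <- ann[moving == TRUE, .(
    velocity_if_awake = mean(sum_displacement / interval)
  ), by = fly_id]
  base <- vel[base, on = "fly_id"]
  base[is.na(velocity_if_awake), velocity_if_awake := 0]

  t_max <- max(ann$interval_start) + interval
  segs <- clip_bouts_to_nights(as.data.table(bouts), zt0_offset, photoperiod, t_max)
  segs <- segs[!excl, on = c(fly_id = "fly_id", night = "day")]
  retained_nights <- ann[is_light == FALSE, .(n_nights = uniqueN(day)),
    by = fly_id
  ]
  night_stats <- segs[, .(
    mean_bout_length_night = mean(duration) / 60,
    n_bouts_total = .N
  ), by = fly_id]
  lat <- segs[, .(lat_night = min_latency_longest(onset, duration, zt0_offset, photoperiod)),
    by = .(fly_id, night)
  ][, .(latency_longest_bout = mean(lat_night)), by = fly_id]

  out <- merge(base, night_stats, by = "fly_id", all.x = TRUE)
  out <- merge(out, retained_nights, by = "fly_id", all.x = TRUE)
  out[is.na(n_bouts_total), n_bouts_total := 0L]
  out[, n_bouts_night := n_bouts_total / pmax(n_nights, 1L)]
  out[is.na(mean_bout_length_night), mean_bout_length_night := 0]
  out[is.na(n_bouts_night), n_bouts_night := 0]
  out <- merge(out, lat, by = "fly_id", all.x = TRUE)
  # never-sleeping nights: censor latency at the full night length
  out[is.na(latency_longest_bout),
    latency_longest_bout := (24 - photoperiod) * 60
  ]
  ma <- morning_anticipation(ann, zt0_offset, photoperiod, exclude_days = integer(0))
  out <- ma[out, on = "fly_id"]
  out[, c("n_bouts_total", "n_nights", "n_retained_days") := NULL]
  setcolorder(out, c(
    "fly_id", "genotype", "sleep_fraction_day", "sleep_fraction_night",
    "latency_longest_bout", "mean_bout_length_night", "n_bouts_night",
    "morning_anticipation", "velocity_if_awake", "total_distance"
  ))
  out[]
}

# Latency (minutes) from lights-off to the onset of the longest bout
# segment of one night.
min_latency_longest <- function(onset, duration, zt0_offset, photoperiod) {
  i <- which.max(duration)
  night_start <- zt0_offset +
    floor((onset[i] - zt0_offset) / 86400) * 86400 + photoperiod * 3600
  (onset[i] - night_start) / 60
}
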