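## Synthetic-data generator: cohorts of males with per-cell sperm morphology,
## per-male CASA track sets with known motility classes, and aligned
## mitochondrial haplotype sequences with a known mutational topology.
## Every downstream stage of the package is testable against the ground
## truth retained here.

#' Default island/sampling-event table
#'
#' Five island populations with per-event male counts (morphology and
#' motility subsets), mean swimming speed, motile fraction, and a small shift
#' of mean midpiece length so island mean total lengths differ slightly
#' (about 114.1-114.9 micrometres).
#'
#' @return Data frame with columns `island`, `year`, `n_males`, `n_motility`,
#'   `speed_mean`, `motile_fraction`, `total_shift`.
#' @export
default_islands <- function() {
  data.frame(
    island = c("ElHierro", "GranCanaria", "LaGomera", "LaPalma", "Tenerife"),
    year = c("2010", "2011", "2010", "2011", "2009"),
    n_males = c(23L, 30L, 11L, 22L, 19L),
    n_motility = c(21L, 13L, 9L, 22L, 8L),
    speed_mean = c(106.77, 105.99, 106.22, 96.41, 111.44),
    motile_fraction = c(0.83, 0.82, 0.81, 0.75, 0.81),
    total_shift = c(0.09, 0.42, 0.75, 0.09, 0.00),
    stringsAsFactors = FALSE)
}

#' Default haplotype network topology
#'
#' A 22-haplotype tree for 49 individuals: a large star-like cluster shared
#' among four islands and a separate cluster, six mutational steps away,
#' private to one island (mirroring the observed mitochondrial split of the
#' Gran Canaria population).
#'
#' @return List with `edges` (data frame `from`, `to`, `steps`), `freq`
#'   (named haplotype frequencies summing to 49) and `island_pool` (named
#'   list: candidate islands per haplotype).
#' @export
default_haplotype_topology <- function() {
  hap <- sprintf("H%02d", 1:22)
  edges <- data.frame(
    from = c("H01","H01","H01","H01","H01","H01","H01","H02","H03","H01",
             "H11","H01","H01","H05","H01","H01","H17","H17","H17","H18","H17"),
    to   = c("H02","H03","H04","H05","H06","H07","H08","H09","H10","H11",
             "H12","H13","H14","H15","H16","H17","H18","H19","H20","H21","H22"),
    steps = c(1L,1L,1L,1L,2L,1L,1L,1L,1L,1L,1L,2L,1L,1L,1L,6L,1L,1L,2L,1L,1L),
    stringsAsFactors = FALSE)
  freq <- c(14L,2L,2L,1L,1L,1L,1L,1L,1L,1L,1L,1L,1L,1L,1L,1L,
            6L,4L,2L,2L,2L,2L)
  names(freq) <- hap
  shared <- c("ElHierro", "LaPalma", "LaGomera", "Tenerife")
  island_pool <- c(rep(list(shared), 16L), rep(list("GranCanaria"), 6L))
  names(island_pool) <- hap
  list(edges = edges, freq = freq, island_pool = island_pool)
}

#' Build and validate a simulation configuration
#'
#' The defaults are the study conditions the generator emulates: five island
#' populations, a frame rate of 50 Hz with 25 tracked frames per cell, mean
#' total sperm length about 114 micrometres with among-male SD about 2
#' micrometres and within-male CV about 1.45 percent, mean curvilinear
#' velocities of roughly 96-111 micrometres/s by island, motile fractions of
#' 0.75-0.83, a male-level total-length-to-speed slope of -1.88
#' (micrometres/s per micrometre), and 49 haplotype sequences on a known
#' 22-node mutational topology.
#'
#' @param seed root integer seed; all outputs are pure functions of
#'   (config, seed). Per-male substreams are derived from it so one male's
#'   data is stable under cohort-size changes.
#' @param islands island/event table, see [default_islands()].
#' @param frame_rate recording frame rate, Hz.
#' @param frames_per_track tracked frames per cell (>= 2).
#' @param tracks_per_male tracked objects per male recording.
#' @param cells_per_male measured spermatozoa per male (morphology).
#' @param class_mix probabilities over track classes `motile`, `static`,
#'   `drifting`, `non_sperm`, `jump_error`; must sum to 1. The per-island
#'   `motile_fraction` overrides the motile share among sperm-class objects;
#'   `class_mix` then sets the debris rate, the jump-artefact share of motile
#'   tracks, and the static:drifting split.
#' @param morph_means,morph_sd_among,morph_sd_within named (head, midpiece,
#'   tail) means and among-/within-male SDs, micrometres.
#' @param speed_slope_total male-level change in true speed per micrometre of
#'   (event-centred) mean total length, micrometres/s.
#' @param speed_slope_mp same for mean midpiece length, with island-specific
#'   additions in `speed_slope_mp_island` (named vector).
#' @param speed_sd_male,speed_sd_cell residual SDs of true speed among males
#'   and among a male's cells, micrometres/s.
#' @param motility_slope_fh log-odds change in motile fraction per
#'   (event-centred) unit of mean flagellum:head ratio; island-specific
#'   additions in `motility_slope_fh_island`.
#' @param wobble_amp,wobble_period amplitude (micrometres) and period
#'   (frames) of the sinusoidal perpendicular wobble that stands in for the
#'   drill-like spin of passerine sperm in 2-D projection.
#' @param noise_sd Gaussian positional jitter SD, micrometres.
#' @param n_haplotype_seqs,seq_length number and aligned length (bp) of
#'   haplotype sequences.
#' @param haplotype_topology see [default_haplotype_topology()].
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              islands = default_islands(),
                              frame_rate = 50,
                              frames_per_track = 25L,
                              tracks_per_male = 170L,
                              cells_per_male = 12L,
                              class_mix = c(motile = 0.80, static = 0.07,
                                            drifting = 0.06, non_sperm = 0.04,
                                            jump_error = 0.03),
                              morph_means = c(head = 16.6, midpiece = 85.6,
                                              tail = 11.9),
                              morph_sd_among = c(head = 0.40, midpiece = 1.85,
                                                 tail = 0.65),
                              morph_sd_within = c(head = 0.30, midpiece = 1.50,
                                                  tail = 0.60),
                              speed_slope_total = -1.88,
                              speed_slope_mp = 0,
                              speed_slope_mp_island = numeric(0),
                              speed_sd_male = 6,
                              speed_sd_cell = 10,
                              motility_slope_fh = 0,
                              motility_slope_fh_island = numeric(0),
                              wobble_amp = 1.0,
                              wobble_period = 5,
                              noise_sd = 0.15,
                              n_haplotype_seqs = 49L,
                              seq_length = 655L,
                              haplotype_topology = default_haplotype_topology()) {
  req_cols <- c("island", "year", "n_males", "speed_mean", "motile_fraction")
  miss <- setdiff(req_cols, names(islands))
  if (length(miss)) stopf("islands table missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (nrow(islands) == 0L) stopf("islands table is empty")
  if (!"n_motility" %in% names(islands)) islands$n_motility <- islands$n_males
  if (!"total_shift" %in% names(islands)) islands$total_shift <- 0
  if (any(islands$n_males < 1L)) stopf("each island event needs n_males >= 1")
  if (any(islands$n_motility > islands$n_males))
    stopf("n_motility cannot exceed n_males")
  if (any(islands$motile_fraction < 0 | islands$motile_fraction > 1))
    stopf("motile_fraction must lie in [0, 1]")
  check_number(frame_rate, "frame_rate", min = 0, strict_min = TRUE)
  if (frames_per_track < 2L) stopf("frames_per_track must be >= 2")
  cls <- c("motile", "static", "drifting", "non_sperm", "jump_error")
  if (!all(cls %in% names(class_mix)))
    stopf("class_mix must name all of: %s", paste(cls, collapse = ", "))
  class_mix <- class_mix[cls]
  if (any(class_mix < 0) || any(class_mix > 1) ||
      abs(sum(class_mix) - 1) > 1e-9)
    stopf("class_mix probabilities must lie in [0,1] and sum to 1")
  seg <- c("head", "midpiece", "tail")
  for (v in list(morph_means = morph_means, morph_sd_among = morph_sd_among,
                 morph_sd_within = morph_sd_within)) {
    if (!all(seg %in% names(v))) stopf("morphology vectors need names %s",
                                       paste(seg, collapse = ", "))
  }
  if (any(morph_means[seg] <= 0)) stopf("morph_means must be positive")
  if (any(morph_sd_among[seg] < 0)) stopf("morph_sd_among must be >= 0")
  if (any(morph_sd_within[seg] < 0)) stopf("morph_sd_within must be >= 0")
  for (nm in c("speed_sd_male", "speed_sd_cell", "wobble_amp", "noise_sd"))
    check_number(get(nm), nm, min = 0)
  check_number(wobble_period, "wobble_period", min = 0, strict_min = TRUE)
  if (n_haplotype_seqs < 1L) stopf("n_haplotype_seqs must be >= 1")
  if (seq_length < 1L) stopf("seq_length must be >= 1")
  structure(list(
    seed = as.integer(seed), islands = islands, frame_rate = frame_rate,
    frames_per_track = as.integer(frames_per_track),
    tracks_per_male = as.integer(tracks_per_male),
    cells_per_male = as.integer(cells_per_male), class_mix = class_mix,
    morph_means = morph_means[seg], morph_sd_among = morph_sd_among[seg],
    morph_sd_within = morph_sd_within[seg],
    speed_slope_total = speed_slope_total, speed_slope_mp = speed_slope_mp,
    speed_slope_mp_island = speed_slope_mp_island,
    speed_sd_male = speed_sd_male, speed_sd_cell = speed_sd_cell,
    motility_slope_fh = motility_slope_fh,
    motility_slope_fh_island = motility_slope_fh_island,
    wobble_amp = wobble_amp, wobble_period = wobble_period,
    noise_sd = noise_sd, n_haplotype_seqs = as.integer(n_haplotype_seqs),
    seq_length = as.integer(seq_length),
    haplotype_topology = haplotype_topology), class = "sim_config")
}

#' Simulate a cohort of males with per-cell sperm morphology
#'
#' Male mean segment lengths are drawn around the configured means with the
#' among-male SDs (midpiece shifted by the event's `total_shift`); cell
#' lengths are drawn around the male means with the within-male SDs. Each
#' male's true swimming speed is the event speed mean plus the configured
#' male-level slopes applied to his event-centred mean morphology, plus
#' Gaussian residual; his true motile fraction follows the event fraction on
#' the log-odds scale with the configured flagellum:head slopes.
#'
#' @param config a [simulation_config()].
#' @return List of class `sim_cohort`: `males` (one row per male with labels,
#'   true mean lengths, `true_speed`, `true_motile_p`, `measurer`) and
#'   `cells` (one row per measured cell: `male_id`, `island`, `year`,
#'   `cell_id`, `head_um`, `midpiece_um`, `tail_um`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  isl <- config$islands
  males <- list(); cells <- list(); midx <- 0L
  for (e in seq_len(nrow(isl))) {
    ev <- isl[e, ]
    slope_mp_extra <- config$speed_slope_mp_island[ev$island]
    if (is.na(slope_mp_extra) || !length(slope_mp_extra)) slope_mp_extra <- 0
    slope_fh_extra <- config$motility_slope_fh_island[ev$island]
    if (is.na(slope_fh_extra) || !length(slope_fh_extra)) slope_fh_extra <- 0
    mu <- config$morph_means
    mu["midpiece"] <- mu["midpiece"] + ev$total_shift
    ref_total <- sum(mu)
    ref_mp <- mu[["midpiece"]]
    ref_fh <- (mu[["midpiece"]] + mu[["tail"]]) / mu[["head"]]
    for (m in seq_len(ev$n_males)) {
      midx <- midx + 1L
      male_id <- sprintf("M%03d", midx)
      s_morph <- child_seed(config$seed, midx, stream = 1L)
      draws <- with_seed(s_morph, {
        mm <- mu + stats::rnorm(3, 0, config$morph_sd_among)
        mm <- pmax(mm, 0.1)
        resid_speed <- stats::rnorm(1, 0, config$speed_sd_male)
        cell_dev <- matrix(stats::rnorm(config$cells_per_male * 3, 0,
                                        rep(config$morph_sd_within,
                                            each = config$cells_per_male)),
                           ncol = 3)
        list(mm = mm, resid_speed = resid_speed, cell_dev = cell_dev)
      })
      mm <- draws$mm
      m_total <- sum(mm); m_mp <- mm[["midpiece"]]
      m_fh <- (mm[["midpiece"]] + mm[["tail"]]) / mm[["head"]]
      true_speed <- ev$speed_mean +
        config$speed_slope_total * (m_total - ref_total) +
        (config$speed_slope_mp + slope_mp_extra) * (m_mp - ref_mp) +
        draws$resid_speed
      logit_p <- stats::qlogis(min(max(ev$motile_fraction, 1e-6), 1 - 1e-6)) +
        (config$motility_slope_fh + slope_fh_extra) * (m_fh - ref_fh)
      males[[midx]] <- data.frame(
        male_id = male_id, island = ev$island, year = as.character(ev$year),
        event = paste(ev$island, ev$year, sep = "_"),
        measurer = if ("measurer" %in% names(ev)) ev$measurer else "M1",
        mean_head = mm[["head"]], mean_midpiece = mm[["midpiece"]],
        mean_tail = mm[["tail"]], true_total = m_total, true_fh = m_fh,
        true_speed = true_speed, true_motile_p = stats::plogis(logit_p),
        has_motility = m <= ev$n_motility, stringsAsFactors = FALSE)
      cl <- sweep(draws$cell_dev, 2, mm, `+`)
      cl <- pmax(cl, 0.1)
      cells[[midx]] <- data.frame(
        male_id = male_id, island = ev$island, year = as.character(ev$year),
        cell_id = sprintf("%s_c%02d", male_id, seq_len(config$cells_per_male)),
        head_um = cl[, 1], midpiece_um = cl[, 2], tail_um = cl[, 3],
        stringsAsFactors = FALSE)
    }
  }
  structure(list(males = do.call(rbind, males), cells = do.call(rbind, cells),
                 config = config), class = "sim_cohort")
}

## Calibrate forward per-frame spacing so that the mean step length of a
## wobbled path equals target_speed / frame_rate (exact when wobble_amp = 0).
calibrate_spacing <- function(target_step, dw) {
  if (all(dw == 0)) return(target_step)
  f <- function(d) mean(sqrt(d^2 + dw^2)) - target_step
  if (f(0) >= 0) return(0)  # wobble alone already covers the target
  stats::uniroot(f, c(0, target_step), tol = 1e-12)$root
}

## Build one track's coordinates for a given class. Returns list(x, y).
build_track_points <- function(class, target_speed, config, n) {
  fr <- config$frame_rate
  t_idx <- seq_len(n) - 1L
  origin <- stats::runif(2, 0, 500)
  theta <- stats::runif(1, 0, 2 * pi)
  u <- c(cos(theta), sin(theta)); v <- c(-sin(theta), cos(theta))
  jitter <- function(sd) matrix(stats::rnorm(2L * n, 0, sd), ncol = 2L)
  if (class == "static") {
    pts <- matrix(origin, n, 2, byrow = TRUE) + jitter(0.12)
    return(list(x = pts[, 1], y = pts[, 2]))
  }
  if (class == "drifting") {
    speed <- stats::runif(1, 5, 20)
    base <- outer(t_idx * speed / fr, u) +
      matrix(origin, n, 2, byrow = TRUE)
    pts <- base + jitter(min(config$noise_sd, 0.05))
    return(list(x = pts[, 1], y = pts[, 2]))
  }
  ## motile-style path (also used for non_sperm debris and jump_error)
  phase <- stats::runif(1, 0, 2 * pi)
  w <- config$wobble_amp * sin(2 * pi * t_idx / config$wobble_period + phase)
  d <- calibrate_spacing(target_speed / fr, diff(w))
  fwd <- t_idx * d
  base <- outer(fwd, u) + outer(w, v) + matrix(origin, n, 2, byrow = TRUE)
  pts <- base + jitter(config$noise_sd)
  if (class == "jump_error") {
    j <- sample(5:(n - 5), 1L)
    steps <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
    jump <- 6 * mean(steps[-j])
    extra <- (jump - steps[j]) * u
    pts[(j + 1L):n, ] <- sweep(pts[(j + 1L):n, , drop = FALSE], 2, extra, `+`)
  }
  list(x = pts[, 1], y = pts[, 2])
}

#' Simulate one male's CASA track set
#'
#' Track classes: `motile` (straight heading with sinusoidal perpendicular
#' wobble and Gaussian jitter, path speed calibrated to the male's true
#' speed), `static` (jitter about a fixed point; VAP < 30 and VSL < 25 by
#' construction), `drifting` (slow linear translation below both velocity
#' floors), `non_sperm` (motile-like but with elongation > 50), and
#' `jump_error` (motile with one injected step exceeding the other steps'
#' mean by far more than 4 SD). True class labels are retained.
#'
#' @param male one row of a [simulate_cohort()] `males` table (needs
#'   `male_id`, `island`, `year`, `true_speed`, `true_motile_p`).
#' @param config a [simulation_config()].
#' @param seed integer seed for this male's substream; defaults to a child of
#'   the config seed keyed by the male id.
#' @return List with `tracks` (list of [sperm_track()]) and `truth` (data
#'   frame: `track_id`, `true_class`, `target_speed`).
#' @export
simulate_tracks <- function(male, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$frames_per_track < 2L) stopf("frames_per_track must be >= 2")
  if (is.null(seed)) {
    idx <- as.integer(sub("^M", "", male$male_id))
    if (is.na(idx)) idx <- sum(utf8ToInt(male$male_id))
    seed <- child_seed(config$seed, idx, stream = 2L)
  }
  n <- config$frames_per_track
  mix <- config$class_mix
  p_ns <- mix[["non_sperm"]]
  p_jump_given_motile <- mix[["jump_error"]] /
    max(mix[["motile"]] + mix[["jump_error"]], 1e-12)
  p_static_given_nm <- mix[["static"]] /
    max(mix[["static"]] + mix[["drifting"]], 1e-12)
  with_seed(seed, {
    classes <- character(config$tracks_per_male)
    for (i in seq_along(classes)) {
      if (stats::runif(1) < p_ns) { classes[i] <- "non_sperm"; next }
      if (stats::runif(1) < male$true_motile_p) {
        classes[i] <- if (stats::runif(1) < p_jump_given_motile)
          "jump_error" else "motile"
      } else {
        classes[i] <- if (stats::runif(1) < p_static_given_nm)
          "static" else "drifting"
      }
    }
    tracks <- vector("list", length(classes))
    truth <- data.frame(track_id = character(length(classes)),
                        true_class = classes,
                        target_speed = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_along(classes)) {
      cl <- classes[i]
      tsp <- switch(cl,
        motile = , jump_error =
          max(male$true_speed + stats::rnorm(1, 0, config$speed_sd_cell), 40),
        non_sperm = stats::runif(1, 40, 80),
        NA_real_)
      pts <- build_track_points(cl, tsp, config, n)
      elong <- if (cl == "non_sperm") stats::runif(1, 55, 95)
               else stats::runif(1, 10, 45)
      tid <- sprintf("%s_t%03d", male$male_id, i)
      tracks[[i]] <- sperm_track(tid, male$male_id, male$island, male$year,
                                 frame = seq_len(n), x = pts$x, y = pts$y,
                                 elongation = elong)
      truth$track_id[i] <- tid
      truth$target_speed[i] <- tsp
    }
    list(tracks = tracks, truth = truth)
  })
}

#' Simulate aligned haplotype sequences with a known mutational topology
#'
#' A random root sequence is generated, then each edge of the configured
#' topology mutates its number of steps at sites never used by any other
#' edge, so pairwise differences are additive along the tree and the minimum
#' spanning network of the resulting haplotypes is exactly the configured
#' topology. Individuals are assigned to haplotypes by the configured
#' frequencies and to islands from each haplotype's island pool.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed (defaults to a child of the config seed).
#' @return List with `sequences` (named character vector, names
#'   `ind<k>_<island>`), `haplotype_of` (haplotype id per individual),
#'   `topology` (the edge list used), `hap_sequences` (named character
#'   vector per haplotype).
#' @export
simulate_haplotypes <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- child_seed(config$seed, 0L, stream = 3L)
  topo <- config$haplotype_topology
  edges <- topo$edges
  haps <- unique(c(edges$from, edges$to))
  if (length(haps) == 0L) haps <- names(topo$freq)
  if (length(haps) == 0L) stopf("topology defines no haplotypes")
  if (is.null(topo$freq)) {
    freq <- stats::setNames(rep(1L, length(haps)), haps)
  } else freq <- topo$freq
  total_steps <- sum(edges$steps)
  if (total_steps > config$seq_length)
    stopf("topology needs %d mutated sites but sequences have only %d",
          total_steps, config$seq_length)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    root_name <- haps[1L]
    root <- sample(bases, config$seq_length, replace = TRUE)
    ## allocate disjoint site sets to edges
    sites <- sample.int(config$seq_length, total_steps)
    site_of <- split(sites, rep(seq_len(nrow(edges)), edges$steps))
    seqs <- list(); seqs[[root_name]] <- root
    remaining <- edges
    remaining$done <- rep(FALSE, nrow(edges))
    while (any(!remaining$done)) {
      progressed <- FALSE
      for (k in which(!remaining$done)) {
        a <- remaining$from[k]; b <- remaining$to[k]
        have_a <- !is.null(seqs[[a]]); have_b <- !is.null(seqs[[b]])
        if (have_a == have_b) next  # need exactly one endpoint resolved
        parent <- if (have_a) a else b
        childh <- if (have_a) b else a
        s <- seqs[[parent]]
        for (pos in site_of[[k]])
          s[pos] <- sample(setdiff(bases, s[pos]), 1L)
        seqs[[childh]] <- s
        remaining$done[k] <- TRUE
        progressed <- TRUE
      }
      if (!progressed) stopf("haplotype topology is not a connected tree")
    }
    hap_seq <- vapply(seqs[haps], paste, "", collapse = "")
    ## individuals
    freq <- freq[haps]
    ids <- character(0); hap_of <- character(0); isl_of <- character(0)
    k <- 0L
    for (h in haps) {
      pool <- topo$island_pool[[h]]
      if (is.null(pool)) pool <- unique(config$islands$island)
      nh <- freq[[h]]
      for (i in seq_len(nh)) {
        k <- k + 1L
        isl <- pool[((i - 1L) %% length(pool)) + 1L]
        ids <- c(ids, sprintf("ind%02d_%s", k, isl))
        hap_of <- c(hap_of, h); isl_of <- c(isl_of, isl)
      }
    }
    sequences <- stats::setNames(hap_seq[hap_of], ids)
    list(sequences = sequences,
         haplotype_of = stats::setNames(hap_of, ids),
         islands = stats::setNames(isl_of, ids),
         topology = edges, hap_sequences = hap_seq)
  })
}

#' Simulate a full study: cohort, track sets and haplotypes
#'
#' @param config a [simulation_config()].
#' @return List of class `sim_study`: `cohort`, `tracks` (flat list of
#'   [sperm_track()]s for males in the motility subset), `truth` (row-bound
#'   per-track class labels), `haplotypes`.
#' @export
simulate_study <- function(config) {
  cohort <- simulate_cohort(config)
  mot <- cohort$males[cohort$males$has_motility, ]
  tracks <- list(); truth <- list()
  for (i in seq_len(nrow(mot))) {
    ts <- simulate_tracks(mot[i, ], config)
    tracks <- c(tracks, ts$tracks)
    truth[[i]] <- cbind(male_id = mot$male_id[i], ts$truth,
                        stringsAsFactors = FALSE)
  }
  structure(list(cohort = cohort, tracks = tracks,
                 truth = do.call(rbind, truth),
                 haplotypes = simulate_haplotypes(config)),
            class = "sim_study")
}
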