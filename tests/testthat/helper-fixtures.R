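# Fixtures built in code: small configs and hand-constructed tracks.

straight_track <- function(n = 26L, spacing = 2, elongation = 20) {
  sperm_track("straight", "M1", "A", "2010", frame = seq_len(n),
              x = (seq_len(n) - 1) * spacing, y = rep(0, n),
              elongation = elongation)
}

zigzag_track <- function(n = 25L) {
  k <- seq_len(n) - 1L
  sperm_track("zigzag", "M1", "A", "2010", frame = seq_len(n),
              x = k, y = k %% 2, elongation = 20)
}

# 25 steps: 24 of `base` micrometres and one jump, appended collinearly.
jump_track <- function(base = 2, jump = 10) {
  x <- cumsum(c(0, rep(base, 24), jump))
  sperm_track("jump", "M1", "A", "2010", frame = seq_along(x),
              x = x, y = rep(0, length(x)), elongation = 20)
}

# A small but statistically workable simulation: 2-3 islands, few males.
small_config <- function(seed = 1L, n_islands = 3L, n_males = 8L,
                         tracks_per_male = 40L, ...) {
  isl <- default_islands()[seq_len(n_islands), ]
  isl$n_males <- rep(as.integer(n_males), n_islands)
  isl$n_motility <- isl$n_males
  simulation_config(seed = seed, islands = isl,
                    tracks_per_male = as.integer(tracks_per_male), ...)
}

# Analysis dataset fabricated directly from a cohort's true male speeds:
# each male's eligible VCLs are his true speed plus cell-level Gaussian
# noise, and motility counts are binomial draws at his true motile fraction.
# Exercises the model-selection machinery without the track-level stages.
make_model_dataset <- function(config, cells_per_male = 15L,
                               tracks_recorded = 120L) {
  cohort <- simulate_cohort(config)
  males <- cohort$males
  ms <- do.call(rbind, lapply(seq_len(nrow(males)), function(i) {
    m <- males[i, ]
    vcls <- m$true_speed + stats::rnorm(cells_per_male, 0,
                                        config$speed_sd_cell)
    n_mot <- stats::rbinom(1L, tracks_recorded, m$true_motile_p)
    out <- data.frame(male_id = m$male_id, island = m$island, year = m$year,
                      n_sperm_objects = tracks_recorded, n_motile = n_mot,
                      proportion_motile = n_mot / tracks_recorded,
                      mean_vcl = mean(vcls), stringsAsFactors = FALSE)
    out$eligible_vcls <- I(list(vcls))
    out
  }))
  morph <- summarize_cohort_morphology(cohort$cells)
  build_analysis_dataset(ms, morph)
}
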