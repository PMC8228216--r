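kin_stub <- function(vap, vsl, vcl = max(vap, vsl), n_points = 25L,
                     continuous = TRUE, steps = rep(2, n_points - 1L)) {
  structure(list(track_id = "stub", vcl = vcl, vsl = vsl, vap = vap,
                 str_score = if (vap > 0) vsl / vap * 100 else NA_real_,
                 lin_score = if (vcl > 0) vsl / vcl * 100 else NA_real_,
                 n_points = n_points, duration = (n_points - 1L) / 50,
                 step_mean = mean(steps), step_sd = stats::sd(steps),
                 step_max = max(steps), continuous = continuous),
            class = "kinematics_result")
}

test_that("elongation rule separates sperm from debris with strict inequality", {
  tr <- function(e) sperm_track("t", frame = 1:2, x = c(0, 1), y = c(0, 0),
                                elongation = e)
  expect_equal(classify_object(tr(60)), "non_sperm")
  expect_equal(classify_object(tr(50)), "sperm")
  expect_equal(classify_object(tr(10)), "sperm")
  expect_error(classify_object(tr(NA)), "elongation")
})

test_that("non-motile rule is a strict-less conjunction, with an OR switch", {
  expect_equal(classify_motility(kin_stub(vap = 25, vsl = 20)), "non_motile")
  expect_equal(classify_motility(kin_stub(vap = 30, vsl = 25)), "motile")
  expect_equal(classify_motility(kin_stub(vap = 50, vsl = 10)), "motile")
  expect_equal(classify_motility(kin_stub(vap = 50, vsl = 10),
                                 motile_rule = "or"), "non_motile")
})

test_that("speed-eligibility cascade records the first failure in fixed order", {
  short <- kin_stub(vap = 100, vsl = 100, n_points = 9L,
                    steps = rep(2, 8))
  expect_equal(speed_eligibility(short)$reason, "short_track")
  crooked <- kin_stub(vap = 100, vsl = 85)  # STR 85, LIN above floor
  expect_false(speed_eligibility(crooked)$eligible)
  expect_equal(speed_eligibility(crooked)$reason, "low_straightness")
  bendy <- kin_stub(vap = 100, vsl = 95, vcl = 170)  # STR 95, LIN ~55.9
  expect_equal(speed_eligibility(bendy)$reason, "low_linearity")
  gappy <- kin_stub(vap = 100, vsl = 100, continuous = FALSE)
  expect_equal(speed_eligibility(gappy)$reason, "discontinuous")
  ok <- kin_stub(vap = 100, vsl = 100)
  expect_true(speed_eligibility(ok)$eligible)
  expect_equal(speed_eligibility(ok)$reason, "none")
})

test_that("jump rule uses all steps with sample SD: 24 steps of 2 plus one of 10", {
  k <- compute_kinematics(jump_track(base = 2, jump = 10), 50)
  expect_equal(k$step_mean, 2.32)
  expect_equal(k$step_sd, 1.6, tolerance = 1e-12)
  # threshold mean + 4 SD = 8.72 < 10, so the track is excluded
  expect_equal(k$step_mean + 4 * k$step_sd, 8.72, tolerance = 1e-12)
  el <- speed_eligibility(k)
  expect_false(el$eligible)
  expect_equal(el$reason, "jump_outlier")
})

test_that("per-male aggregation reproduces the hand-counted 10-track fixture", {
  # 1 non-sperm, 3 non-motile, 6 motile of which 1 too short:
  # proportion motile 6/9, 5 eligible VCLs
  mk <- function(id, type) {
    if (type == "debris")
      return(sperm_track(id, "M1", "A", "2010", frame = 1:25,
                         x = (0:24) * 2, y = rep(0, 25), elongation = 70))
    if (type == "static")
      return(sperm_track(id, "M1", "A", "2010", frame = 1:25,
                         x = rep(0, 25) + 0.01 * (0:24 %% 2),
                         y = rep(0, 25), elongation = 20))
    if (type == "short")
      return(sperm_track(id, "M1", "A", "2010", frame = 1:9,
                         x = (0:8) * 2, y = rep(0, 9), elongation = 20))
    sperm_track(id, "M1", "A", "2010", frame = 1:25, x = (0:24) * 2,
                y = rep(0, 25), elongation = 20)  # clean motile
  }
  tracks <- c(list(mk("t01", "debris")),
              lapply(sprintf("t%02d", 2:4), mk, type = "static"),
              list(mk("t05", "short")),
              lapply(sprintf("t%02d", 6:10), mk, type = "motile"))
  qc <- qc_track_set(tracks)
  expect_equal(qc$males$n_sperm_objects, 9L)
  expect_equal(qc$males$n_motile, 6L)
  expect_equal(qc$males$proportion_motile, 6 / 9)
  expect_equal(qc$males$n_eligible, 5L)
  expect_equal(sum(qc$cell_table$exclusion_reason == "short_track"), 1L)
})

test_that("degenerate male summaries behave per contract", {
  static <- sperm_track("s", "M1", "A", "2010", frame = 1:25,
                        x = rep(0, 25) + 0.01 * (0:24 %% 2), y = rep(0, 25),
                        elongation = 20)
  rec <- qc_track(static)
  s <- summarize_male(list(rec))
  expect_equal(s$proportion_motile, 0)
  expect_true(is.na(s$mean_vcl))
  expect_equal(length(s$eligible_vcls[[1L]]), 0L)
  debris <- sperm_track("d", "M1", "A", "2010", frame = 1:25, x = (0:24) * 2,
                        y = rep(0, 25), elongation = 80)
  expect_error(summarize_male(list(qc_track(debris))), "no sperm-class")
})

test_that("QC recovers simulator ground truth and partitions counts", {
  cfg <- small_config(seed = 5L, n_islands = 2L, n_males = 3L,
                      tracks_per_male = 60L)
  st <- simulate_study(cfg)
  qc <- qc_track_set(st$tracks)
  tab <- merge(st$truth, qc$cell_table, by = "track_id")
  expect_equal(nrow(tab), nrow(st$truth))
  # object class
  expect_true(all((tab$true_class == "non_sperm") ==
                    (tab$object_class == "non_sperm")))
  # motility class of sperm objects
  sperm <- tab[tab$object_class == "sperm", ]
  expect_true(all((sperm$true_class %in% c("static", "drifting")) ==
                    (sperm$motility_class == "non_motile")))
  # all jump-error tracks fail the 4-SD speed filter
  jumps <- tab[tab$true_class == "jump_error", ]
  expect_gt(nrow(jumps), 0L)
  expect_true(all(jumps$exclusion_reason == "jump_outlier"))
  # partition invariant per male
  with(qc$males, expect_equal(n_sperm_objects - n_motile,
                              n_sperm_objects - n_motile))
  agg <- aggregate(cbind(sperm = object_class == "sperm",
                         motile = motility_class == "motile",
                         nonmot = motility_class == "non_motile") ~ male_id,
                   data = qc$cell_table, FUN = sum)
  expect_equal(agg$sperm, agg$motile + agg$nonmot)
})

test_that("relaxing any single threshold never shrinks the eligible count", {
  cfg <- small_config(seed = 9L, n_islands = 2L, n_males = 3L,
                      tracks_per_male = 50L, noise_sd = 0.4)
  st <- simulate_study(cfg)
  base <- qc_track_set(st$tracks, qc_thresholds())
  n0 <- sum(base$cell_table$speed_eligible)
  relaxed <- list(qc_thresholds(min_points = 5L),
                  qc_thresholds(str_min = 70),
                  qc_thresholds(lin_min = 30),
                  qc_thresholds(jump_k = 8),
                  qc_thresholds(elongation_max = 80))
  for (th in relaxed) {
    n1 <- sum(qc_track_set(st$tracks, th)$cell_table$speed_eligible)
    expect_gte(n1, n0)
  }
})
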