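test_that("within-event centring zeroes every event mean", {
  expect_equal(center_within_event(c(10, 12, 14), rep("a", 3)), c(-2, 0, 2))
  expect_equal(center_within_event(5, "a"), 0)
  expect_equal(center_within_event(c(1, 3, 10), c("A", "A", "B")),
               c(-1, 1, 0))
  expect_error(center_within_event(1:2, c("A", NA)), "missing event")
  set.seed(10)
  v <- rnorm(40); e <- sample(letters[1:5], 40, TRUE)
  cv <- center_within_event(v, e)
  expect_true(all(abs(tapply(cv, e, mean)) < 1e-12))
})

test_that("within/between decomposition has exactly zero per-male deviation means", {
  d <- within_between_decomposition(c(110, 114), c("M1", "M1"))
  expect_equal(d$male_mean, c(112, 112))
  expect_equal(d$deviation, c(-2, 2))
  set.seed(2)
  v <- rnorm(60, 114, 2); m <- sample(paste0("M", 1:10), 60, TRUE)
  dec <- within_between_decomposition(v, m)
  expect_true(all(abs(tapply(dec$deviation, m, mean)) < 1e-12))
  expect_equal(dec$male_mean + dec$deviation, v)
})

test_that("speed model recovers a configured male-level total-length slope", {
  isl <- default_islands()
  isl$n_males <- c(15L, 15L, 14L, 13L, 13L); isl$n_motility <- isl$n_males
  cfg <- simulation_config(seed = 101L, islands = isl)
  set.seed(101)
  ds <- make_model_dataset(cfg, cells_per_male = 40L)
  m <- fit_speed_model(ds)
  co <- m$coefficients
  est <- co$Estimate[co$term == "c_total"]
  se <- co$`Std. Error`[co$term == "c_total"]
  expect_lt(abs(est - (-1.88)), 2 * se)
  # selection log reproduces deterministically
  m2 <- fit_speed_model(ds)
  expect_identical(m$selection_log, m2$selection_log)
})

test_that("null speed simulations eliminate all interactions and centre on zero", {
  cfg <- small_config(seed = 55L, n_islands = 3L, n_males = 10L,
                      speed_slope_total = 0)
  set.seed(55)
  ds <- make_model_dataset(cfg, cells_per_male = 20L)
  m <- fit_speed_model(ds)
  co <- m$coefficients
  expect_false(any(grepl(":", co$term)))  # all interactions eliminated
  est <- co$Estimate[co$term == "c_total"]
  se <- co$`Std. Error`[co$term == "c_total"]
  expect_lt(abs(est), 2 * se)
})

test_that("an island-specific midpiece slope is detected by backward selection", {
  # generous effect: the focal island's midpiece slope is shifted far beyond
  # the collinearity-inflated SE of the interaction contrast
  hits <- 0L
  for (s in 1:10) {
    cfg <- small_config(seed = 300L + s, n_islands = 3L, n_males = 15L,
                        speed_slope_mp_island = c(GranCanaria = -25))
    set.seed(300L + s)
    ds <- make_model_dataset(cfg, cells_per_male = 25L)
    m <- fit_speed_model(ds)
    if (any(grepl("c_mp", m$coefficients$term) &
            grepl(":", m$coefficients$term)))
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("motility GLMM forward selection finds an island-specific F:H effect", {
  isl <- default_islands()
  isl$n_males <- c(15L, 15L, 14L, 13L, 13L); isl$n_motility <- isl$n_males
  cfg <- simulation_config(seed = 71L, islands = isl,
                           motility_slope_fh_island = c(GranCanaria = 10))
  set.seed(71)
  ds <- make_model_dataset(cfg, tracks_recorded = 170L)
  g <- fit_motility_glmm(ds)
  expect_true(any(g$selection_log$action == "added" &
                    grepl("c_fh", g$selection_log$term)))
  co <- g$coefficients
  gc_fh <- co$Estimate[grepl("GranCanaria", co$term) & grepl("c_fh", co$term)]
  expect_gt(gc_fh, 0)
})

test_that("GLMM likelihood-ratio screening has calibrated type-I error", {
  # single-candidate LRT (the unit the forward step repeats) under the null
  reps <- 200L
  retained <- 0L
  for (s in seq_len(reps)) {
    cfg <- small_config(seed = 4000L + s, n_islands = 3L, n_males = 10L,
                        speed_slope_total = 0)
    set.seed(4000L + s)
    ds <- make_model_dataset(cfg, tracks_recorded = 80L)
    d <- ds$males
    d$island <- factor(d$island)
    d$n_immotile <- d$n_sperm_objects - d$n_motile
    m0 <- suppressWarnings(lme4::glmer(
      cbind(n_motile, n_immotile) ~ c_fh + island + (1 | male_id),
      data = d, family = binomial))
    m1 <- suppressWarnings(lme4::glmer(
      cbind(n_motile, n_immotile) ~ c_fh + island + island:c_fh +
        (1 | male_id), data = d, family = binomial))
    p <- anova(m0, m1)$`Pr(>Chisq)`[2L]
    if (is.finite(p) && p < 0.05) retained <- retained + 1L
  }
  band <- qbinom(c(0.005, 0.995), reps, 0.05)
  expect_gte(retained, band[1L])
  expect_lte(retained, band[2L])
})

test_that("weighted log-proportion model obeys the weighting identities", {
  cfg <- small_config(seed = 99L, n_islands = 3L, n_males = 8L)
  set.seed(99)
  ds <- make_model_dataset(cfg)
  m1 <- fit_motility_lm_weighted(ds)
  # equal weights coincide with the unweighted fit
  ds_eq <- ds
  ds_eq$males$n_sperm_objects <- 100L
  m_eq <- fit_motility_lm_weighted(ds_eq)
  mf <- model.frame(m_eq$model)
  un <- lm(formula(m_eq$model), data = mf)  # same terms, no weights
  expect_equal(unname(coef(m_eq$model)), unname(coef(un)), tolerance = 1e-8)
  # doubling all weights changes nothing
  ds2 <- ds
  ds2$males$n_sperm_objects <- ds$males$n_sperm_objects * 2L
  m2 <- fit_motility_lm_weighted(ds2)
  expect_equal(coef(m1$model), coef(m2$model), tolerance = 1e-8)
})

test_that("an island shift in motile fraction is detected with the right sign", {
  isl <- default_islands()[c(1, 4), ]  # second island has the lower fraction
  isl$n_males <- c(20L, 20L); isl$n_motility <- isl$n_males
  cfg <- simulation_config(seed = 111L, islands = isl)
  set.seed(111)
  ds <- make_model_dataset(cfg, tracks_recorded = 170L)
  m <- fit_motility_lm_weighted(ds)
  co <- m$coefficients
  est <- co$Estimate[grepl("^island", co$term) & !grepl(":", co$term)]
  expect_lt(est, 0)  # LaPalma (0.75) below ElHierro (0.83)
})

test_that("zero motile proportions get the logged continuity correction", {
  cfg <- small_config(seed = 43L, n_islands = 2L, n_males = 5L)
  set.seed(43)
  ds <- make_model_dataset(cfg, tracks_recorded = 30L)
  ds$males$n_motile[1L] <- 0L
  ds$males$proportion_motile[1L] <- 0
  m <- fit_motility_lm_weighted(ds)
  expect_true(any(grepl("continuity correction", m$notes)))
})

test_that("Levene's test matches a brute-force ANOVA on absolute deviations", {
  g1 <- c(1, 2, 3); g2 <- c(11, 12, 13)
  lt <- levene_among_males(c(g1, g2), rep(c("A", "B"), each = 3))
  expect_equal(lt$statistic, 0)
  x <- c(0, 0, 10, 10, 4, 5, 5, 6)
  isl <- rep(c("A", "B"), each = 4)
  lt2 <- levene_among_males(x, isl, center = "median")
  dev <- abs(x - ave(x, isl, FUN = median))
  brute <- anova(lm(dev ~ factor(isl)))
  expect_equal(lt2$statistic, brute$`F value`[1L])
  expect_equal(lt2$p_value, brute$`Pr(>F)`[1L])
  expect_error(levene_among_males(g1, rep("A", 3)), ">= 2 islands")
  expect_error(levene_among_males(c(1, 2, 3), c("A", "A", "B")), "single male")
})

test_that("midpiece model recovers distinct between- and within-male slopes", {
  # among-male SDs chosen so cov(mp,total)/var(total) = 0.47 between and
  # 0.55 within
  isl <- default_islands()[1:3, ]
  isl$n_males <- c(20L, 20L, 20L); isl$n_motility <- 0L
  cfg <- simulation_config(seed = 202L, islands = isl,
                           cells_per_male = 20L,
                           morph_sd_among = c(head = 1.40, midpiece = 1.40,
                                              tail = 0.50),
                           morph_sd_within = c(head = 1.25, midpiece = 1.50,
                                               tail = 0.53))
  cells <- simulate_cohort(cfg)$cells
  m <- fit_midpiece_model(cells)
  co <- m$coefficients
  b <- co[co$term == "male_mean_total", ]
  w <- co[co$term == "dev_total", ]
  expect_lt(abs(b$Estimate - 0.47), 2 * b$`Std. Error`)
  expect_lt(abs(w$Estimate - 0.55), 2 * w$`Std. Error`)
})

test_that("degenerate within-male variation is reported as inestimable", {
  cells <- data.frame(
    male_id = rep(paste0("M", 1:6), each = 2),
    island = rep(c("A", "B"), each = 6), year = "2010",
    cell_id = paste0("c", 1:12),
    head_um = 16, midpiece_um = rep(seq(84, 89, 1), each = 2), tail_um = 12)
  m <- suppressWarnings(fit_midpiece_model(cells))
  expect_true(any(grepl("inestimable", m$notes)))
})

test_that("SD model falls back to fixed effects with one measurer and runs with two", {
  cfg <- small_config(seed = 121L, n_islands = 3L, n_males = 8L)
  summ <- summarize_cohort_morphology(simulate_cohort(cfg)$cells)
  m1 <- fit_sd_model(summ)
  expect_true(grepl("fallback", m1$method))
  summ$measurer <- rep(c("TL", "XX"), length.out = nrow(summ))
  m2 <- fit_sd_model(summ)
  expect_true(grepl("lmer", m2$method))
  # all-zero SDs: island effects vanish
  summ0 <- summ; summ0$sd_total <- 0
  m0 <- fit_sd_model(summ0)
  est <- m0$coefficients$Estimate[grepl("^island", m0$coefficients$term)]
  expect_true(all(abs(est) < 1e-8))
})
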