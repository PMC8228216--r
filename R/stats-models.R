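## Model-building procedures around a delegated mixed-model backend
## (lme4/lmerTest): within-event centring of male-level predictors,
## backward/forward interaction selection, variance comparisons, and the
## within-/between-male decomposition of cell-level predictors.

#' Centre values within sampling events
#'
#' Subtracts the event mean (events are island-year combinations), so
#' island- and time-level confounds are removed from male-level predictors
#' before cross-level regressions. Per-event centred means are exactly 0.
#'
#' @param values numeric vector (typically one value per male).
#' @param events event label per value; no missing labels allowed.
#' @return Centred numeric vector.
#' @export
center_within_event <- function(values, events) {
  if (length(values) != length(events))
    stopf("values and events must have equal length")
  if (any(is.na(events))) stopf("missing event label at position %d",
                                which(is.na(events))[1L])
  values - stats::ave(values, events, FUN = mean)
}

#' Assemble the analysis dataset
#'
#' Joins cell-level eligible VCL observations to male-level mean morphology
#' (centred within sampling events) and carries the per-male motility counts.
#'
#' @param male_summary per-male QC summary from [qc_track_set()] (needs
#'   `male_id`, `island`, `year`, `n_sperm_objects`, `n_motile`, `mean_vcl`,
#'   list column `eligible_vcls`).
#' @param morph_summary per-male morphology from
#'   [summarize_cohort_morphology()].
#' @return List of class `analysis_dataset`: `cells` (one row per eligible
#'   VCL: `male_id`, `island`, `year`, `event`, `vcl`, centred predictors
#'   `c_total`, `c_fh`, `c_mp`) and `males` (one row per male with counts,
#'   centred predictors and centred mean VCL `c_vcl`).
#' @export
build_analysis_dataset <- function(male_summary, morph_summary) {
  keep <- intersect(male_summary$male_id, morph_summary$male_id)
  if (length(keep) < 2L)
    stopf("need >= 2 males present in both motility and morphology tables")
  ms <- male_summary[match(keep, male_summary$male_id), ]
  mo <- morph_summary[match(keep, morph_summary$male_id), ]
  males <- data.frame(
    male_id = keep, island = ms$island, year = as.character(ms$year),
    event = paste(ms$island, ms$year, sep = "_"),
    n_sperm_objects = ms$n_sperm_objects, n_motile = ms$n_motile,
    proportion_motile = ms$proportion_motile,
    mean_vcl = ms$mean_vcl,
    mean_total = mo$mean_total, mean_fh_ratio = mo$mean_fh_ratio,
    mean_midpiece = mo$mean_midpiece, stringsAsFactors = FALSE)
  males$c_total <- center_within_event(males$mean_total, males$event)
  males$c_fh <- center_within_event(males$mean_fh_ratio, males$event)
  males$c_mp <- center_within_event(males$mean_midpiece, males$event)
  vcl_for_centering <- males$mean_vcl
  if (any(is.na(vcl_for_centering)))
    vcl_for_centering[is.na(vcl_for_centering)] <-
      mean(vcl_for_centering, na.rm = TRUE)
  males$c_vcl <- center_within_event(vcl_for_centering, males$event)
  cells <- do.call(rbind, lapply(seq_along(keep), function(i) {
    v <- ms$eligible_vcls[[i]]
    if (length(v) == 0L) return(NULL)
    data.frame(male_id = keep[i], island = males$island[i],
               year = males$year[i], event = males$event[i], vcl = v,
               c_total = males$c_total[i], c_fh = males$c_fh[i],
               c_mp = males$c_mp[i], stringsAsFactors = FALSE)
  }))
  structure(list(cells = cells, males = males), class = "analysis_dataset")
}

new_model_result <- function(model, method, selection_log, notes = character(0)) {
  co <- tryCatch({
    s <- suppressWarnings(summary(model))
    cf <- as.data.frame(stats::coef(s))
    cf$term <- rownames(cf); rownames(cf) <- NULL
    cf[, c(ncol(cf), seq_len(ncol(cf) - 1L))]
  }, error = function(e) NULL)
  structure(list(model = model, coefficients = co, method = method,
                 selection_log = selection_log, notes = notes),
            class = "sf_model_result")
}

#' @export
print.sf_model_result <- function(x, ...) {
  cat(sprintf("<model result> method: %s\n", x$method))
  if (!is.null(x$coefficients)) print(x$coefficients, digits = 4)
  if (nrow(x$selection_log))
    cat(sprintf("selection: %d step(s), final terms after %s\n",
                nrow(x$selection_log),
                x$selection_log$action[nrow(x$selection_log)]))
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

## Interaction labels are order-sensitive in R ("a:b" vs "b:a"); match terms
## by their sorted component sets.
match_term <- function(term, table) {
  canon <- function(x) vapply(strsplit(x, ":", fixed = TRUE),
                              function(p) paste(sort(p), collapse = ":"), "")
  match(canon(term), canon(table))
}

empty_log <- function() {
  data.frame(step = integer(0), action = character(0), term = character(0),
             statistic = numeric(0), p_value = numeric(0),
             stringsAsFactors = FALSE)
}

log_row <- function(step, action, term, statistic, p) {
  data.frame(step = step, action = action, term = term,
             statistic = statistic, p_value = p, stringsAsFactors = FALSE)
}

## Backward elimination of interaction terms from an lmerTest fit.
## Tests use Satterthwaite type-III F; one least-significant interaction with
## p > alpha is removed per step (or all at once when simultaneous = TRUE).
backward_eliminate_lmm <- function(response, main_terms, interactions,
                                   random_term, data, alpha,
                                   simultaneous = FALSE) {
  sel_log <- empty_log(); step <- 0L
  current <- interactions
  repeat {
    fml <- stats::reformulate(c(main_terms, current, random_term),
                              response = response)
    fit <- lmerTest::lmer(fml, data = data, REML = TRUE)
    if (length(current) == 0L) break
    an <- suppressMessages(stats::anova(fit, type = 3))
    an_terms <- rownames(an)
    hits <- match_term(current, an_terms)
    ip <- ifelse(is.na(hits), NA_real_, an[hits, "Pr(>F)"])
    istat <- ifelse(is.na(hits), NA_real_, an[hits, "F value"])
    removable <- which(!is.na(ip) & ip > alpha)
    if (length(removable) == 0L) break
    step <- step + 1L
    if (simultaneous) {
      for (k in removable)
        sel_log <- rbind(sel_log, log_row(step, "removed", current[k],
                                          istat[k], ip[k]))
      current <- current[-removable]
    } else {
      worst <- removable[which.max(ip[removable])]
      sel_log <- rbind(sel_log, log_row(step, "removed", current[worst],
                                        istat[worst], ip[worst]))
      current <- current[-worst]
    }
  }
  list(fit = fit, retained = current, log = sel_log)
}

#' Mixed model of sperm swimming speed on male mean morphology
#'
#' Cell-level VCL is regressed on the male's event-centred mean total length,
#' flagellum:head ratio and midpiece length, with island as a fixed effect,
#' a random intercept per male, and island-by-morphology interactions subject
#' to backward elimination at `alpha` (main effects are never removed).
#' Inference uses Satterthwaite degrees of freedom.
#'
#' @param dataset an [build_analysis_dataset()] result.
#' @param alpha retention threshold for interactions (default 0.05).
#' @param simultaneous drop all non-significant interactions at once instead
#'   of one per step.
#' @return An `sf_model_result` with coefficients, Satterthwaite tests and a
#'   `selection_log` that reconstructs the elimination path.
#' @export
fit_speed_model <- function(dataset, alpha = 0.05, simultaneous = FALSE) {
  stopifnot(inherits(dataset, "analysis_dataset"))
  d <- dataset$cells
  if (is.null(d) || length(unique(d$island)) < 2L)
    stopf("speed model needs eligible VCL cells from >= 2 islands")
  d$island <- factor(d$island)
  res <- backward_eliminate_lmm(
    response = "vcl",
    main_terms = c("c_total", "c_fh", "c_mp", "island"),
    interactions = c("island:c_total", "island:c_fh", "island:c_mp"),
    random_term = "(1 | male_id)", data = d, alpha = alpha,
    simultaneous = simultaneous)
  new_model_result(res$fit, "lmer (REML), Satterthwaite df", res$log,
                   notes = if (length(res$retained))
                     sprintf("retained interaction(s): %s",
                             paste(res$retained, collapse = ", "))
                   else "no interactions retained")
}

#' Binomial mixed model of the motile proportion
#'
#' The per-male (motile, non-motile) counts are the response; fixed effects
#' are the three event-centred morphology predictors, event-centred male mean
#' VCL, and island; male identity is a random intercept. Island-by-predictor
#' interactions are added by forward selection with likelihood ratio tests:
#' each remaining candidate is added singly, the best with LRT p < `alpha`
#' is kept, until no addition qualifies. Candidates that fail to converge are
#' skipped and logged.
#'
#' @param dataset an [build_analysis_dataset()] result.
#' @param alpha forward-selection threshold (default 0.05).
#' @return An `sf_model_result`; inference is Wald z (the backend does not
#'   provide denominator df for binomial mixed models).
#' @export
fit_motility_glmm <- function(dataset, alpha = 0.05) {
  stopifnot(inherits(dataset, "analysis_dataset"))
  d <- dataset$males
  if (any(d$n_sperm_objects < 1L)) stopf("male with 0 sperm objects")
  if (length(unique(d$island)) < 2L) stopf("need >= 2 islands")
  d$island <- factor(d$island)
  d$n_immotile <- d$n_sperm_objects - d$n_motile
  main <- c("c_total", "c_fh", "c_mp", "c_vcl", "island")
  candidates <- c("island:c_total", "island:c_fh", "island:c_mp",
                  "island:c_vcl")
  selected <- character(0)
  sel_log <- empty_log(); step <- 0L
  fit_g <- function(terms) {
    fml <- stats::reformulate(c(terms, "(1 | male_id)"),
                              response = "cbind(n_motile, n_immotile)")
    lme4::glmer(fml, data = d, family = stats::binomial,
                control = lme4::glmerControl(check.conv.singular =
                                               "ignore"))
  }
  base <- fit_g(main)
  repeat {
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0L) break
    best <- NULL; best_p <- Inf; best_chi <- NA_real_; best_fit <- NULL
    for (cand in remaining) {
      res <- tryCatch({
        m1 <- suppressWarnings(fit_g(c(main, selected, cand)))
        lrt <- stats::anova(base, m1)
        list(p = lrt$`Pr(>Chisq)`[2L], chi = lrt$Chisq[2L], fit = m1)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        step <- step + 1L
        sel_log <- rbind(sel_log, log_row(step, "skipped_nonconvergence",
                                          cand, NA_real_, NA_real_))
        next
      }
      if (is.finite(res$p) && res$p < best_p) {
        best <- cand; best_p <- res$p; best_chi <- res$chi; best_fit <- res$fit
      }
    }
    if (is.null(best) || best_p >= alpha) break
    step <- step + 1L
    sel_log <- rbind(sel_log, log_row(step, "added", best, best_chi, best_p))
    selected <- c(selected, best)
    base <- best_fit
  }
  new_model_result(base, "glmer binomial (Laplace), Wald z; LRT selection",
                   sel_log,
                   notes = if (length(selected))
                     sprintf("selected interaction(s): %s",
                             paste(selected, collapse = ", "))
                   else "no interactions selected")
}

#' Weighted fixed-effects model of the log motile proportion
#'
#' A simpler companion to [fit_motility_glmm()]: ordinary least squares on
#' the log-transformed motile proportion, observations weighted by the
#' number of sperm objects in the recording, all island-by-predictor
#' interactions in the initial model and backward removal at `alpha`.
#' Zero proportions are continuity-corrected by adding 0.5 to both counts
#' for that row (logged in the notes).
#'
#' @param dataset an [build_analysis_dataset()] result.
#' @param alpha backward-removal threshold.
#' @return An `sf_model_result`.
#' @export
fit_motility_lm_weighted <- function(dataset, alpha = 0.05) {
  stopifnot(inherits(dataset, "analysis_dataset"))
  d <- dataset$males
  if (length(unique(d$island)) < 2L) stopf("need >= 2 islands")
  d$island <- factor(d$island)
  notes <- character(0)
  zero <- d$proportion_motile == 0
  p <- d$proportion_motile
  if (any(zero)) {
    p[zero] <- (d$n_motile[zero] + 0.5) / (d$n_sperm_objects[zero] + 1)
    notes <- c(notes, sprintf("continuity correction applied to %d male(s): %s",
                              sum(zero), paste(d$male_id[zero], collapse = ", ")))
  }
  d$log_prop <- log(p)
  d$w <- d$n_sperm_objects
  main <- c("c_total", "c_fh", "c_mp", "c_vcl", "island")
  current <- c("island:c_total", "island:c_fh", "island:c_mp", "island:c_vcl")
  sel_log <- empty_log(); step <- 0L
  repeat {
    fml <- stats::reformulate(c(main, current), response = "log_prop")
    fit <- stats::lm(fml, data = d, weights = w)
    if (length(current) == 0L) break
    # marginality: only interactions can drop; near-saturated fits warn
    dr <- suppressWarnings(stats::drop1(fit, test = "F"))
    dr <- dr[!is.na(match_term(rownames(dr), current)), , drop = FALSE]
    terms_dr <- rownames(dr)
    pvals <- dr$`Pr(>F)`
    fstat <- dr$`F value`
    removable <- which(!is.na(pvals) & pvals > alpha)
    if (length(removable) == 0L) break
    worst <- removable[which.max(pvals[removable])]
    step <- step + 1L
    sel_log <- rbind(sel_log, log_row(step, "removed", terms_dr[worst],
                                      fstat[worst], pvals[worst]))
    current <- current[-match_term(terms_dr[worst], current)]
  }
  new_model_result(fit, "weighted lm on log proportion", sel_log, notes)
}

#' Levene's test of among-male variance across islands
#'
#' One-way comparison of the absolute deviations of male mean total lengths
#' from their island centre (median by default, the Brown-Forsythe form;
#' switchable to the mean).
#'
#' @param male_mean_totals numeric vector, one value per male.
#' @param islands island label per male; every island needs >= 2 males.
#' @param center `"median"` or `"mean"`.
#' @return List with `statistic` (F), `df` (numerator, denominator) and
#'   `p_value`.
#' @export
levene_among_males <- function(male_mean_totals, islands,
                               center = c("median", "mean")) {
  center <- match.arg(center)
  islands <- factor(islands)
  if (nlevels(islands) < 2L) stopf("Levene's test needs >= 2 islands")
  counts <- table(islands)
  if (any(counts < 2L))
    stopf("island(s) with a single male: %s",
          paste(names(counts)[counts < 2L], collapse = ", "))
  lt <- car::leveneTest(male_mean_totals ~ islands,
                        center = if (center == "median") stats::median else mean)
  list(statistic = lt$`F value`[1L], df = c(lt$Df[1L], lt$Df[2L]),
       p_value = lt$`Pr(>F)`[1L])
}

#' Within-/between-male decomposition of a cell-level predictor
#'
#' Splits each cell's value into the male's mean and the cell's deviation
#' from that mean; per-male deviation means are exactly 0.
#'
#' @param values cell-level numeric vector.
#' @param male_ids male label per cell.
#' @return Data frame with `male_mean` and `deviation` (same length as
#'   `values`).
#' @export
within_between_decomposition <- function(values, male_ids) {
  if (length(values) != length(male_ids))
    stopf("values and male_ids must have equal length")
  mm <- stats::ave(values, male_ids, FUN = mean)
  data.frame(male_mean = mm, deviation = values - mm)
}

#' Mixed model separating between- and within-male midpiece-total allometry
#'
#' Cell midpiece length is regressed on the male's mean total length
#' (between-male slope) and the cell's deviation from that mean (within-male
#' slope), with island as a fixed effect, a random intercept per male, and
#' island interactions tested and removed at `alpha`. Males with fewer than
#' 2 cells are dropped with a warning.
#'
#' @param cells morphology cell table with derived columns (or raw; derived
#'   on the fly). Needs `male_id`, `island`, `midpiece_um`, `total_um`.
#' @param alpha interaction retention threshold.
#' @return An `sf_model_result`.
#' @export
fit_midpiece_model <- function(cells, alpha = 0.05) {
  if (!"total_um" %in% names(cells)) cells <- derive_lengths_table(cells)
  counts <- table(cells$male_id)
  drop <- names(counts)[counts < 2L]
  if (length(drop)) {
    warning(sprintf("dropping %d male(s) with < 2 cells", length(drop)),
            call. = FALSE)
    cells <- cells[!cells$male_id %in% drop, ]
  }
  if (length(unique(cells$island)) < 2L) stopf("need >= 2 islands")
  dec <- within_between_decomposition(cells$total_um, cells$male_id)
  d <- data.frame(midpiece = cells$midpiece_um, male_id = cells$male_id,
                  island = factor(cells$island),
                  male_mean_total = dec$male_mean,
                  dev_total = dec$deviation, stringsAsFactors = FALSE)
  if (all(abs(d$dev_total) < 1e-12)) {
    res <- backward_eliminate_lmm(
      "midpiece", c("male_mean_total", "island"),
      c("island:male_mean_total"), "(1 | male_id)", d, alpha)
    return(new_model_result(res$fit, "lmer (REML), Satterthwaite df", res$log,
                            notes = "within-male slope inestimable: no within-male variation in total length"))
  }
  res <- backward_eliminate_lmm(
    "midpiece", c("male_mean_total", "dev_total", "island"),
    c("island:male_mean_total", "island:dev_total"),
    "(1 | male_id)", d, alpha)
  new_model_result(res$fit, "lmer (REML), Satterthwaite df", res$log,
                   notes = if (length(res$retained))
                     sprintf("retained interaction(s): %s",
                             paste(res$retained, collapse = ", "))
                   else "no interactions retained")
}

#' Model of within-male SD of total sperm length across islands
#'
#' Per-male SD of total length is the response, island the predictor, male
#' mean total length a covariate, and measurer a random intercept. With a
#' single measurer the model degrades to a fixed-effects fit, noted in the
#' result.
#'
#' @param male_summaries per-male morphology table (needs `sd_total`,
#'   `mean_total`, `island`; computed from >= 2 cells each).
#' @param measurer optional measurer label per male (defaults to a
#'   `measurer` column, else a single level).
#' @return An `sf_model_result`.
#' @export
fit_sd_model <- function(male_summaries, measurer = NULL) {
  d <- male_summaries
  if (is.null(measurer))
    measurer <- if ("measurer" %in% names(d)) d$measurer
                else rep("M1", nrow(d))
  d$measurer <- measurer
  d$island <- factor(d$island)
  if (length(unique(d$measurer)) >= 2L) {
    fit <- tryCatch(
      suppressWarnings(
        lmerTest::lmer(sd_total ~ island + mean_total + (1 | measurer),
                       data = d, REML = TRUE)),
      error = function(e) e)
    if (!inherits(fit, "error"))
      return(new_model_result(fit, "lmer (REML), Satterthwaite df",
                              empty_log()))
    msg <- conditionMessage(fit)
    fit <- stats::lm(sd_total ~ island + mean_total, data = d)
    new_model_result(fit, "lm (degenerate mixed fit: fixed-effects fallback)",
                     empty_log(),
                     notes = sprintf("mixed model failed (%s); random effect dropped",
                                     msg))
  } else {
    fit <- stats::lm(sd_total ~ island + mean_total, data = d)
    new_model_result(fit, "lm (single measurer: fixed-effects fallback)",
                     empty_log(),
                     notes = "single measurer; random effect dropped")
  }
}
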