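## Object / motility / speed-eligibility quality-control cascade.
##
## 1. Objects with tracker elongation above a threshold are debris, not sperm,
##    and leave every downstream count.
## 2. Sperm with both a low average-path and a low straight-line velocity are
##    static or drifting, hence non-motile.
## 3. Motile sperm contribute a speed observation only if the track is long,
##    straight, linear, continuous, and free of jump artefacts.

#' Default QC thresholds
#'
#' @param elongation_max elongation above which a motile object is debris.
#' @param vap_min,vsl_min velocity floors (micrometres/s) of the non-motile
#'   rule.
#' @param motile_rule `"and"`: non-motile iff VAP < `vap_min` AND
#'   VSL < `vsl_min` (literal reading); `"or"`: either suffices (common CASA
#'   practice).
#' @param min_points minimum tracked points for a speed observation.
#' @param str_min,lin_min minimum straightness / linearity scores (percent).
#' @param jump_k a track is a tracking artefact when its maximum step exceeds
#'   the mean step by `jump_k` sample SDs (all steps included).
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(elongation_max = 50, vap_min = 30, vsl_min = 25,
                          motile_rule = c("and", "or"), min_points = 10L,
                          str_min = 90, lin_min = 60, jump_k = 4) {
  motile_rule <- match.arg(motile_rule)
  for (nm in c("elongation_max", "vap_min", "vsl_min", "str_min", "lin_min",
               "jump_k"))
    check_number(get(nm), nm, min = 0)
  list(elongation_max = elongation_max, vap_min = vap_min, vsl_min = vsl_min,
       motile_rule = motile_rule, min_points = as.integer(min_points),
       str_min = str_min, lin_min = lin_min, jump_k = jump_k)
}

#' Classify a tracked object as sperm or non-sperm debris
#'
#' Debris iff elongation is strictly greater than the threshold.
#'
#' @param track a [sperm_track()] with a finite elongation score.
#' @param elongation_max threshold (default 50).
#' @return `"sperm"` or `"non_sperm"`.
#' @export
classify_object <- function(track, elongation_max = 50) {
  stopifnot(inherits(track, "sperm_track"))
  e <- track$elongation
  if (is.null(e) || length(e) != 1L || !is.finite(e))
    stopf("track '%s': elongation missing or non-finite", track$track_id)
  if (e > elongation_max) "non_sperm" else "sperm"
}

#' Classify motility of a sperm track
#'
#' @param kin a [compute_kinematics()] result.
#' @param vap_min,vsl_min velocity floors in micrometres/s.
#' @param motile_rule `"and"` (both below => non-motile) or `"or"`.
#' @return `"motile"` or `"non_motile"`.
#' @export
classify_motility <- function(kin, vap_min = 30, vsl_min = 25,
                              motile_rule = c("and", "or")) {
  stopifnot(inherits(kin, "kinematics_result"))
  motile_rule <- match.arg(motile_rule)
  low_vap <- kin$vap < vap_min
  low_vsl <- kin$vsl < vsl_min
  non_motile <- if (motile_rule == "and") low_vap && low_vsl else low_vap || low_vsl
  if (non_motile) "non_motile" else "motile"
}

#' Speed-eligibility of a motile track
#'
#' Checks are applied in a fixed order and the first failure is recorded, so
#' exclusion counts are auditable: short track, low straightness, low
#' linearity, discontinuous (frame-index gaps), jump outlier (max step >
#' mean step + `jump_k` sample SDs, the suspect step included in both).
#'
#' @param kin a [compute_kinematics()] result for a motile track.
#' @param min_points,str_min,lin_min,jump_k thresholds, see [qc_thresholds()].
#' @return List with `eligible` (logical) and `reason` (one of `"none"`,
#'   `"short_track"`, `"low_straightness"`, `"low_linearity"`,
#'   `"discontinuous"`, `"jump_outlier"`).
#' @export
speed_eligibility <- function(kin, min_points = 10L, str_min = 90,
                              lin_min = 60, jump_k = 4) {
  stopifnot(inherits(kin, "kinematics_result"))
  reason <- "none"
  if (kin$n_points < min_points) {
    reason <- "short_track"
  } else if (is.na(kin$str_score) || kin$str_score < str_min) {
    reason <- "low_straightness"
  } else if (is.na(kin$lin_score) || kin$lin_score < lin_min) {
    reason <- "low_linearity"
  } else if (!kin$continuous) {
    reason <- "discontinuous"
  } else if (kin$step_max > kin$step_mean + jump_k * kin$step_sd) {
    reason <- "jump_outlier"
  }
  list(eligible = reason == "none", reason = reason)
}

#' Run the full QC cascade on one track
#'
#' @param track a [sperm_track()].
#' @param thresholds a [qc_thresholds()] list.
#' @param frame_rate,vap_window kinematics settings.
#' @return A `cell_record`: list with `track_id`, `male_id`, `island`, `year`,
#'   `object_class`, `motility_class` (`"n/a"` for debris), `speed_eligible`,
#'   `exclusion_reason` and the `kinematics` result.
#' @export
qc_track <- function(track, thresholds = qc_thresholds(), frame_rate = 50,
                     vap_window = 5L) {
  object_class <- classify_object(track, thresholds$elongation_max)
  kin <- compute_kinematics(track, frame_rate, vap_window)
  if (object_class == "non_sperm") {
    motility <- "n/a"; eligible <- FALSE; reason <- "none"
  } else {
    motility <- classify_motility(kin, thresholds$vap_min, thresholds$vsl_min,
                                  thresholds$motile_rule)
    if (motility == "motile") {
      el <- speed_eligibility(kin, thresholds$min_points, thresholds$str_min,
                              thresholds$lin_min, thresholds$jump_k)
      eligible <- el$eligible; reason <- el$reason
    } else {
      eligible <- FALSE; reason <- "none"
    }
  }
  structure(list(track_id = track$track_id, male_id = track$male_id,
                 island = track$island, year = track$year,
                 object_class = object_class, motility_class = motility,
                 speed_eligible = eligible, exclusion_reason = reason,
                 kinematics = kin),
            class = "cell_record")
}

#' Aggregate QC records into a per-male motility summary
#'
#' Non-sperm objects are excluded from both numerator and denominator of the
#' motile proportion; eligible VCLs come from speed-eligible tracks only.
#'
#' @param records list of `cell_record`s from [qc_track()], all one male.
#' @param male_id,island,year labels; taken from the first record if omitted.
#' @return A one-row data frame plus an `eligible_vcls` attribute-free list
#'   column: `male_id`, `island`, `year`, `n_tracks`, `n_sperm_objects`,
#'   `n_motile`, `proportion_motile`, `n_eligible`, `mean_vcl` (`NA` when no
#'   eligible track), and list column `eligible_vcls`.
#' @export
summarize_male <- function(records, male_id = NULL, island = NULL, year = NULL) {
  stopifnot(length(records) >= 1L,
            all(vapply(records, inherits, TRUE, "cell_record")))
  if (is.null(male_id)) male_id <- records[[1L]]$male_id
  if (is.null(island)) island <- records[[1L]]$island
  if (is.null(year)) year <- records[[1L]]$year
  sperm <- Filter(function(r) r$object_class == "sperm", records)
  if (length(sperm) == 0L)
    stopf("male '%s': no sperm-class objects among %d tracks", male_id,
          length(records))
  motile <- Filter(function(r) r$motility_class == "motile", sperm)
  eligible <- Filter(function(r) r$speed_eligible, motile)
  vcls <- vapply(eligible, function(r) r$kinematics$vcl, 0)
  out <- data.frame(
    male_id = male_id, island = island, year = year,
    n_tracks = length(records),
    n_sperm_objects = length(sperm),
    n_motile = length(motile),
    proportion_motile = length(motile) / length(sperm),
    n_eligible = length(eligible),
    mean_vcl = if (length(vcls)) mean(vcls) else NA_real_,
    stringsAsFactors = FALSE)
  out$eligible_vcls <- I(list(vcls))
  out
}

#' QC a whole track set and summarise per male
#'
#' @param tracks list of [sperm_track()]s (possibly several males).
#' @param thresholds a [qc_thresholds()] list.
#' @param frame_rate,vap_window kinematics settings.
#' @return List with `records` (per-track `cell_record`s), `cell_table`
#'   (one row per track: classes, reason, VCL/VSL/VAP/STR/LIN) and `males`
#'   (row-bound per-male summaries).
#' @export
qc_track_set <- function(tracks, thresholds = qc_thresholds(), frame_rate = 50,
                         vap_window = 5L) {
  records <- lapply(tracks, qc_track, thresholds = thresholds,
                    frame_rate = frame_rate, vap_window = vap_window)
  cell_table <- do.call(rbind, lapply(records, function(r) {
    k <- r$kinematics
    data.frame(track_id = r$track_id, male_id = r$male_id, island = r$island,
               year = r$year, object_class = r$object_class,
               motility_class = r$motility_class,
               speed_eligible = r$speed_eligible,
               exclusion_reason = r$exclusion_reason,
               vcl = k$vcl, vsl = k$vsl, vap = k$vap,
               str_score = k$str_score, lin_score = k$lin_score,
               n_points = k$n_points, stringsAsFactors = FALSE)
  }))
  by_male <- split(records, vapply(records, `[[`, "", "male_id"))
  males <- do.call(rbind, lapply(by_male, summarize_male))
  rownames(males) <- NULL
  list(records = records, cell_table = cell_table, males = males)
}
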