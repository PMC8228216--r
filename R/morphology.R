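## Sperm morphology: per-cell derived lengths and small-sample-corrected
## coefficients of variation within and among males.

#' Derive flagellum, total length and ratios for one sperm cell
#'
#' Flagellum = midpiece + tail; total = head + flagellum;
#' F:H ratio = flagellum / head; midpiece ratio = midpiece / total.
#'
#' @param head,midpiece,tail segment lengths in micrometres, all > 0.
#' @return A one-row data frame with `head`, `midpiece`, `tail`, `flagellum`,
#'   `total`, `fh_ratio`, `mp_ratio`.
#' @export
derive_lengths <- function(head, midpiece, tail) {
  for (nm in c("head", "midpiece", "tail")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stopf("'%s' must be a single positive length, got %s", nm, format(v))
  }
  flagellum <- midpiece + tail
  total <- head + flagellum
  data.frame(head = head, midpiece = midpiece, tail = tail,
             flagellum = flagellum, total = total,
             fh_ratio = flagellum / head, mp_ratio = midpiece / total)
}

#' Derive lengths for a whole morphology table
#'
#' @param cells data frame with columns `head_um`, `midpiece_um`, `tail_um`
#'   (plus any id columns, preserved).
#' @return The input with `flagellum_um`, `total_um`, `fh_ratio`, `mp_ratio`
#'   appended.
#' @export
derive_lengths_table <- function(cells) {
  req <- c("head_um", "midpiece_um", "tail_um")
  miss <- setdiff(req, names(cells))
  if (length(miss)) stopf("morphology table missing column(s): %s",
                          paste(miss, collapse = ", "))
  for (nm in req) {
    bad <- which(!is.finite(cells[[nm]]) | cells[[nm]] <= 0)
    if (length(bad)) stopf("column '%s': non-positive value at row %d", nm, bad[1L])
  }
  cells$flagellum_um <- cells$midpiece_um + cells$tail_um
  cells$total_um <- cells$head_um + cells$flagellum_um
  cells$fh_ratio <- cells$flagellum_um / cells$head_um
  cells$mp_ratio <- cells$midpiece_um / cells$total_um
  cells
}

#' Small-sample-corrected coefficient of variation
#'
#' `CV = (SD / mean) * 100 * (1 + 1 / (4 n))`, with the sample (n-1) SD; the
#' correction factor removes the downward bias of the CV at small n.
#'
#' @param values numeric vector of at least 2 positive-mean measurements.
#' @return CV in percent.
#' @export
cv_corrected <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stopf("cv_corrected needs at least 2 values, got %d", n)
  if (any(!is.finite(values))) stopf("cv_corrected: non-finite values")
  m <- mean(values)
  if (m <= 0) stopf("cv_corrected: mean must be positive, got %g", m)
  stats::sd(values) / m * 100 * (1 + 1 / (4 * n))
}

#' Per-male morphology summary
#'
#' Means of all measured and derived lengths, the SD of total length, and the
#' within-male coefficient of variation of total length (small-sample
#' corrected, n = cells for that male).
#'
#' @param cells data frame of one male's cells, with derived columns as from
#'   [derive_lengths_table()]; needs >= 2 cells.
#' @param male_id,island,year labels; from the table if present.
#' @return One-row data frame with `n_cells`, `mean_*` columns, `sd_total`
#'   and `cv_wm`.
#' @export
summarize_male_morphology <- function(cells, male_id = NULL, island = NULL,
                                      year = NULL) {
  if (!"total_um" %in% names(cells)) cells <- derive_lengths_table(cells)
  if (nrow(cells) < 2L)
    stopf("male '%s': need >= 2 cells to summarise, got %d",
          male_id %||% cells$male_id[1L], nrow(cells))
  grab <- function(arg, col) {
    if (!is.null(arg)) arg
    else if (col %in% names(cells)) as.character(cells[[col]][1L])
    else NA_character_
  }
  data.frame(
    male_id = grab(male_id, "male_id"), island = grab(island, "island"),
    year = grab(year, "year"), n_cells = nrow(cells),
    mean_head = mean(cells$head_um), mean_midpiece = mean(cells$midpiece_um),
    mean_tail = mean(cells$tail_um), mean_flagellum = mean(cells$flagellum_um),
    mean_total = mean(cells$total_um), mean_fh_ratio = mean(cells$fh_ratio),
    mean_mp_ratio = mean(cells$mp_ratio),
    sd_total = stats::sd(cells$total_um),
    cv_wm = cv_corrected(cells$total_um),
    stringsAsFactors = FALSE)
}

#' Summarise morphology for every male in a cell table
#'
#' @param cells morphology cell table with a `male_id` column.
#' @return Row-bound per-male summaries, one row per male with >= 2 cells;
#'   males with fewer cells are dropped with a warning.
#' @export
summarize_cohort_morphology <- function(cells) {
  if (!"male_id" %in% names(cells)) stopf("cell table needs a 'male_id' column")
  cells <- derive_lengths_table(cells)
  by_male <- split(cells, cells$male_id)
  small <- names(by_male)[vapply(by_male, nrow, 0L) < 2L]
  if (length(small)) {
    warning(sprintf("dropping %d male(s) with < 2 cells: %s", length(small),
                    paste(small, collapse = ", ")), call. = FALSE)
    by_male <- by_male[setdiff(names(by_male), small)]
  }
  out <- do.call(rbind, lapply(by_male, summarize_male_morphology))
  rownames(out) <- NULL
  out
}

#' Among-male coefficient of variation of total sperm length
#'
#' The small-sample-corrected CV applied to male mean total lengths
#' (n = number of males).
#'
#' @param male_summaries per-male summary table from
#'   [summarize_cohort_morphology()], or a numeric vector of male means.
#' @return CV in percent.
#' @export
cohort_cv_am <- function(male_summaries) {
  means <- if (is.data.frame(male_summaries)) male_summaries$mean_total
           else as.numeric(male_summaries)
  if (length(means) < 2L) stopf("cohort_cv_am needs >= 2 males")
  cv_corrected(means)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
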