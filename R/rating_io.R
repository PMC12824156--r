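# Reading, validating, resampling and writing tidy rating tables.

RATING_CONDITIONS <- c("context_only", "character_only", "ground_truth")
RATING_COLUMNS <- c("observer_id", "video_id", "condition",
                    "time_s", "valence", "arousal")

#' Read a tidy rating table
#'
#' Reads a CSV of valence/arousal ratings, one row per
#' (observer, video, condition, timepoint), validates every row against the
#' rating-record contract and returns a canonical `rating_table` data frame.
#' Ratings are bounded continuous values on \eqn{[-1, 1]}; `condition` must
#' be one of `context_only`, `character_only`, `ground_truth`. Extra columns
#' in the file are ignored.
#'
#' @param path Path to a CSV file with header.
#' @param schema Optional named character vector mapping canonical column
#'   names (`observer_id`, `video_id`, `condition`, `time_s`, `valence`,
#'   `arousal`) to the column names used in the file.
#' @return A data frame of class `rating_table` with the canonical columns.
#' @seealso [write_ratings()], [resample_to_grid()]
#' @export
read_ratings <- function(path, schema = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(df))
        stopf("schema column '%s' (for '%s') missing from %s",
              schema[[canon]], canon, path)
      names(df)[names(df) == schema[[canon]]] <- canon
    }
  }
  missing <- setdiff(RATING_COLUMNS, names(df))
  if (length(missing))
    stopf("missing required column(s): %s", paste(missing, collapse = ", "))
  df <- df[RATING_COLUMNS]
  validate_ratings(df)
}

#' Validate a rating table
#'
#' Checks the rating-record invariants: valence and arousal within
#' \eqn{[-1, 1]}, condition among the three recognized levels, nonnegative
#' numeric times. Errors name the first offending row.
#'
#' @param df Data frame with the canonical rating columns.
#' @return The validated data frame, classed `rating_table`, invisibly
#'   usable in pipelines.
#' @export
validate_ratings <- function(df) {
  missing <- setdiff(RATING_COLUMNS, names(df))
  if (length(missing))
    stopf("missing required column(s): %s", paste(missing, collapse = ", "))
  df$observer_id <- as.character(df$observer_id)
  df$video_id <- as.character(df$video_id)
  df$condition <- as.character(df$condition)
  df$time_s <- as.numeric(df$time_s)
  df$valence <- as.numeric(df$valence)
  df$arousal <- as.numeric(df$arousal)
  bad <- which(!df$condition %in% RATING_CONDITIONS)
  if (length(bad))
    stopf("row %d: unknown condition '%s'", bad[1], df$condition[bad[1]])
  for (dim in c("valence", "arousal")) {
    v <- df[[dim]]
    bad <- which(!is.finite(v) | v < -1 | v > 1)
    if (length(bad))
      stopf("row %d: %s = %s outside [-1, 1]", bad[1], dim,
            format(v[bad[1]]))
  }
  bad <- which(!is.finite(df$time_s) | df$time_s < 0)
  if (length(bad))
    stopf("row %d: time_s must be a nonnegative number", bad[1])
  class(df) <- c("rating_table", "data.frame")
  df
}

#' Resample one observer's ratings onto a uniform time grid
#'
#' Continuous ratings are step functions between input updates: the rating
#' holds until the next one. `hold_last` fills every grid point with the
#' most recent rating at or before it (grid points before the first rating
#' are back-filled with the first rating); `drop_leading` instead drops
#' grid points that precede the first rating. The grid runs from 0 to the
#' last rating time, rounded up to the next multiple of `dt_s`.
#'
#' @param records `rating_table` rows for a single
#'   observer/video/condition.
#' @param dt_s Grid step in seconds (e.g. 0.5, 0.1 or 0.04).
#' @param gap_policy `"hold_last"` (default) or `"drop_leading"`.
#' @return A `rating_series` object: list with `observer_id`, `video_id`,
#'   `condition`, `dt_s`, `times`, and a `values` data frame with
#'   `valence` and `arousal` columns.
#' @examples
#' recs <- data.frame(observer_id = "o1", video_id = "v1",
#'                    condition = "ground_truth", time_s = c(0, 0.25),
#'                    valence = c(0.2, 0.4), arousal = c(0, 0))
#' resample_to_grid(validate_ratings(recs), dt_s = 0.1)$values$valence
#' @export
resample_to_grid <- function(records, dt_s,
                             gap_policy = c("hold_last", "drop_leading")) {
  gap_policy <- match.arg(gap_policy)
  if (nrow(records) == 0L) stopf("no records to resample")
  if (length(unique(records$observer_id)) != 1L ||
      length(unique(records$video_id)) != 1L ||
      length(unique(records$condition)) != 1L)
    stopf("records must belong to one observer/video/condition")
  if (!is.numeric(dt_s) || dt_s <= 0) stopf("dt_s must be positive")
  ord <- order(records$time_s)
  records <- records[ord, ]
  t_max <- max(records$time_s)
  k <- ceiling(round(t_max / dt_s, 9) - 1e-9)
  times <- (0:max(k, 0)) * dt_s
  idx <- findInterval(times + dt_s * 1e-6, records$time_s)
  if (gap_policy == "hold_last") {
    idx[idx == 0L] <- 1L
  } else {
    keep <- idx > 0L
    times <- times[keep]
    idx <- idx[keep]
    if (!length(times)) stopf("all grid points precede the first rating")
  }
  structure(
    list(observer_id = records$observer_id[1],
         video_id = records$video_id[1],
         condition = records$condition[1],
         dt_s = dt_s,
         times = times,
         values = data.frame(valence = records$valence[idx],
                             arousal = records$arousal[idx])),
    class = "rating_series"
  )
}

#' @export
print.rating_series <- function(x, ...) {
  cat(sprintf("<rating_series> %s / %s / %s: %d points, dt = %g s\n",
              x$observer_id, x$video_id, x$condition,
              length(x$times), x$dt_s))
  invisible(x)
}

#' Write rating data to a tidy CSV
#'
#' Serializes a `rating_table` (or a list of `rating_series`) to the
#' canonical tidy CSV dialect: header
#' `observer_id,video_id,condition,time_s,valence,arousal`, UTF-8, `.`
#' decimal separator, rows sorted by (observer, video, condition, time).
#' Numbers are written with enough digits that reading the file back
#' reproduces the values bit for bit.
#'
#' @param x A `rating_table` data frame or a list of `rating_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(x, path) {
  df <- as_rating_table(x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(RATING_COLUMNS, collapse = ","), con)
  if (nrow(df)) {
    ord <- order(df$observer_id, df$video_id, df$condition, df$time_s)
    df <- df[ord, ]
    lines <- paste(df$observer_id, df$video_id, df$condition,
                   fmt_num(df$time_s), fmt_num(df$valence),
                   fmt_num(df$arousal), sep = ",")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Coerce rating containers to the canonical long table
#'
#' @param x A `rating_table`, a data frame with the canonical columns, a
#'   single `rating_series`, a list of `rating_series`, or a `cue_cohort`.
#' @return A `rating_table` data frame.
#' @export
as_rating_table <- function(x) UseMethod("as_rating_table")

#' @export
as_rating_table.rating_table <- function(x) x

#' @export
as_rating_table.data.frame <- function(x) validate_ratings(x)

#' @export
as_rating_table.rating_series <- function(x) {
  validate_ratings(data.frame(
    observer_id = x$observer_id, video_id = x$video_id,
    condition = x$condition, time_s = x$times,
    valence = x$values$valence, arousal = x$values$arousal,
    stringsAsFactors = FALSE))
}

#' @export
as_rating_table.list <- function(x) {
  if (!length(x)) {
    df <- data.frame(observer_id = character(), video_id = character(),
                     condition = character(), time_s = numeric(),
                     valence = numeric(), arousal = numeric())
    class(df) <- c("rating_table", "data.frame")
    return(df)
  }
  parts <- lapply(x, as_rating_table)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("rating_table", "data.frame")
  out
}
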