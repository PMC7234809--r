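#' @keywords internal
"_PACKAGE"

# Columns every trial table must carry, with their storage modes.
.trial_schema <- c(
  subject_id = "character", session_index = "integer", trial_index = "integer",
  video_duration_s = "double", boundary_frame = "integer", n_frames = "integer",
  frame_rate_hz = "double", probe_early_frame = "integer",
  probe_late_frame = "integer", chosen_frame = "integer", correct = "logical",
  rt_s = "double", boundary_condition = "character", play_order = "character",
  td_level = "integer", exposure = "integer", category = "character",
  touch_side = "character", elapsed_time_s = "double"
)

.boundary_levels <- c("within_clip1", "within_clip2", "across")

#' Construct a TOJ trial table
#'
#' A trial table is a tibble with one row per temporal-order-judgement (TOJ)
#' trial and a `filter_log` attribute recording exclusion rules applied to
#' it. Frame indices are stored 0-based; the two probe frames satisfy
#' `0 <= probe_early_frame < probe_late_frame < n_frames`, and a trial is
#' `correct` exactly when the earlier probe was chosen.
#'
#' @param trials data frame holding all trial columns (see
#'   [trial_columns()]).
#' @param filter_log optional data frame with columns `rule`, `n_removed`,
#'   `fraction_removed`.
#' @param validate if `TRUE` (default), invariant violations raise an error.
#' @return A `toj_trials` tibble.
#' @export
trial_table <- function(trials, filter_log = NULL, validate = TRUE) {
  trials <- tibble::as_tibble(trials)
  missing <- setdiff(names(.trial_schema), names(trials))
  if (length(missing) > 0L) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in names(.trial_schema)) {
    trials[[col]] <- switch(.trial_schema[[col]],
      character = as.character(trials[[col]]),
      integer   = as.integer(trials[[col]]),
      double    = as.double(trials[[col]]),
      logical   = as.logical(trials[[col]])
    )
  }
  if (is.null(filter_log)) {
    filter_log <- tibble::tibble(rule = character(), n_removed = integer(),
                                 fraction_removed = double())
  } else {
    filter_log <- tibble::as_tibble(filter_log)
  }
  if (validate) {
    bad <- validate_trials(trials)
    if (nrow(bad) > 0L) {
      stop("trial invariant violations in ", length(unique(bad$row)),
           " row(s); first: row ", bad$row[1L], ": ", bad$violation[1L],
           call. = FALSE)
    }
  }
  structure(trials, filter_log = filter_log,
            class = c("toj_trials", class(tibble::tibble())))
}

#' Names of the columns of a trial table
#' @return Character vector of required column names.
#' @export
trial_columns <- function() names(.trial_schema)

#' Exclusion log of a trial table
#' @param table a trial table.
#' @return Tibble with columns `rule`, `n_removed`, `fraction_removed`.
#' @export
filter_log <- function(table) {
  fl <- attr(table, "filter_log")
  if (is.null(fl)) {
    fl <- tibble::tibble(rule = character(), n_removed = integer(),
                         fraction_removed = double())
  }
  fl
}

#' Check trial invariants row by row
#'
#' Verifies, per row: probe ordering and bounds, the consistency of
#' `boundary_condition` with the probe/boundary geometry, frame-count
#' consistency with duration and frame rate, the `correct` flag, and
#' positive reaction time.
#'
#' @param trials data frame of trials.
#' @return Tibble with columns `row` and `violation`; zero rows when all
#'   invariants hold.
#' @export
validate_trials <- function(trials) {
  n <- nrow(trials)
  rows <- integer(0); msgs <- character(0)
  note <- function(bad, msg) {
    idx <- which(bad)
    rows <<- c(rows, idx); msgs <<- c(msgs, rep(msg, length(idx)))
  }
  note(!(trials$probe_early_frame >= 0L &
           trials$probe_early_frame < trials$probe_late_frame &
           trials$probe_late_frame < trials$n_frames),
       "probe frames must satisfy 0 <= early < late < n_frames")
  is_across <- trials$probe_early_frame < trials$boundary_frame &
    trials$boundary_frame <= trials$probe_late_frame
  note((trials$boundary_condition == "across") != is_across,
       "boundary_condition inconsistent with probe/boundary geometry")
  note(trials$n_frames !=
         as.integer(round(trials$video_duration_s * trials$frame_rate_hz)),
       "n_frames != round(video_duration_s * frame_rate_hz)")
  note(trials$correct != (trials$chosen_frame == trials$probe_early_frame),
       "correct flag inconsistent with chosen frame")
  note(!(trials$chosen_frame == trials$probe_early_frame |
           trials$chosen_frame == trials$probe_late_frame),
       "chosen_frame must be one of the probe frames")
  note(!(trials$rt_s > 0), "rt_s must be positive")
  ord <- order(rows)
  tibble::tibble(row = rows[ord], violation = msgs[ord])
}

#' Read a trial table from delimited text
#'
#' Expects a comma-delimited file with a header row naming every trial
#' column, `.` as decimal point, UTF-8 encoded. A JSON sidecar
#' `<path>.filter_log.json`, if present, restores the exclusion log.
#'
#' @param path file path.
#' @param one_based if `TRUE`, frame-index columns in the file are 1-based
#'   (ordinal numbering) and are shifted to the package's 0-based internal
#'   representation on read.
#' @return A `toj_trials` tibble.
#' @export
load_trials <- function(path, one_based = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  missing <- setdiff(names(.trial_schema), names(raw))
  if (length(missing) > 0L) {
    stop("schema error: file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_rt <- which(is.na(suppressWarnings(as.numeric(raw$rt_s))))
  if (length(bad_rt) > 0L) {
    stop("parse error: non-numeric rt_s in row(s) ",
         paste(bad_rt, collapse = ", "), call. = FALSE)
  }
  frame_cols <- c("boundary_frame", "probe_early_frame", "probe_late_frame",
                  "chosen_frame")
  if (one_based) for (col in frame_cols) raw[[col]] <- raw[[col]] - 1L
  sidecar <- paste0(path, ".filter_log.json")
  fl <- if (file.exists(sidecar)) {
    tibble::as_tibble(jsonlite::fromJSON(sidecar))
  } else NULL
  trial_table(raw, filter_log = fl)
}

#' Write a trial table to delimited text
#'
#' Inverse of [load_trials()]; the exclusion log is written to a JSON
#' sidecar `<path>.filter_log.json`.
#'
#' @param table a trial table.
#' @param path output file path.
#' @param one_based write frame indices as 1-based ordinals.
#' @return `path`, invisibly.
#' @export
write_trials <- function(table, path, one_based = FALSE) {
  out <- as.data.frame(table)[, names(.trial_schema)]
  if (one_based) {
    for (col in c("boundary_frame", "probe_early_frame", "probe_late_frame",
                  "chosen_frame")) {
      out[[col]] <- out[[col]] + 1L
    }
  }
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  fl <- filter_log(table)
  if (nrow(fl) > 0L) {
    jsonlite::write_json(as.data.frame(fl), paste0(path, ".filter_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Exclude implausibly fast and slow trials
#'
#' Retains trials with `lo_s <= rt_s <= hi_s` (bounds inclusive) and
#' appends two entries (`rt_slow`, `rt_fast`) to the exclusion log with
#' counts and fractions relative to the input size.
#'
#' @param table a trial table.
#' @param lo_s lower reaction-time bound in seconds (default 0.7).
#' @param hi_s upper bound in seconds (default 10).
#' @return Filtered `toj_trials` tibble.
#' @export
filter_rt <- function(table, lo_s = 0.7, hi_s = 10) {
  stopifnot(lo_s < hi_s)
  n0 <- nrow(table)
  slow <- table$rt_s > hi_s
  fast <- table$rt_s < lo_s
  keep <- !(slow | fast)
  frac <- function(k) if (n0 == 0L) 0 else k / n0
  fl <- rbind(
    as.data.frame(filter_log(table)),
    data.frame(rule = c("rt_slow", "rt_fast"),
               n_removed = c(sum(slow), sum(fast)),
               fraction_removed = c(frac(sum(slow)), frac(sum(fast))))
  )
  trial_table(as.data.frame(table)[keep, , drop = FALSE], filter_log = fl,
              validate = FALSE)
}

#' Label the context condition of trials
#'
#' A trial is `across` when the clip boundary lies strictly between the two
#' probe frames (`probe_early_frame < boundary_frame <= probe_late_frame`),
#' `within_clip1` when both probes precede the boundary, and `within_clip2`
#' otherwise.
#'
#' @param trials a trial table or data frame with probe and boundary
#'   columns.
#' @return Character vector of labels, one per row.
#' @export
label_condition <- function(trials) {
  if (any(trials$probe_early_frame == trials$probe_late_frame)) {
    stop("degenerate trial: equal probe frames", call. = FALSE)
  }
  across <- trials$probe_early_frame < trials$boundary_frame &
    trials$boundary_frame <= trials$probe_late_frame
  within1 <- trials$probe_late_frame < trials$boundary_frame
  ifelse(across, "across", ifelse(within1, "within_clip1", "within_clip2"))
}

#' Temporal similarity of the two probe frames
#'
#' TS = delay2 / delay1, where delay1 and delay2 are the retention
#' intervals of the earlier and later probe frame at the moment of testing
#' (delay2 < delay1). TS lies strictly in (0, 1); values near 1 mean the
#' two memory traces are nearly equally old and hence hard to discriminate.
#'
#' @param trials a trial table or data frame.
#' @param test_time_s time of testing measured from video onset; defaults
#'   to `video_duration_s + retention_delay_s` per trial.
#' @param retention_delay_s retention delay used for the default test
#'   clock (seconds, default 2).
#' @return Numeric vector of TS values in (0, 1).
#' @export
temporal_similarity <- function(trials, test_time_s = NULL,
                                retention_delay_s = 2) {
  if (any(trials$probe_early_frame == trials$probe_late_frame)) {
    stop("degenerate trial: equal probe frames", call. = FALSE)
  }
  t_early <- trials$probe_early_frame / trials$frame_rate_hz
  t_late <- trials$probe_late_frame / trials$frame_rate_hz
  if (is.null(test_time_s)) {
    test_time_s <- trials$video_duration_s + retention_delay_s
  }
  if (any(test_time_s <= t_late)) {
    stop("test time must lie strictly after both probe frames",
         call. = FALSE)
  }
  (test_time_s - t_late) / (test_time_s - t_early)
}

#' Normalized chosen-frame location
#'
#' Maps `chosen_frame` to the unit interval as
#' `chosen_frame / (n_frames - 1)`, making regression slopes comparable
#' across videos of different length (8-12 s).
#'
#' @param trials a trial table or data frame.
#' @return Numeric vector in `[0, 1]`.
#' @export
chosen_frame_location <- function(trials) {
  trials$chosen_frame / (trials$n_frames - 1)
}

#' @export
print.toj_trials <- function(x, ...) {
  cat("<toj_trials> ", nrow(x), " trials, ",
      length(unique(x$subject_id)), " subject(s)\n", sep = "")
  fl <- filter_log(x)
  if (nrow(fl) > 0L) {
    cat("filters applied:\n")
    for (i in seq_len(nrow(fl))) {
      cat(sprintf("  %-10s removed %d (%.2f%%)\n", fl$rule[i],
                  fl$n_removed[i], 100 * fl$fraction_removed[i]))
    }
  }
  NextMethod()
}
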