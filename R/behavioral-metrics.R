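# Derived behavioral statistics: replay compression factor, clip-wise RT
# contrast, trial-type ANOVA, sliding-window curves, inverse efficiency.

#' Replay compression factor
#'
#' From the fitted reaction-time span between the first and last frame of
#' a video: `scan_ms_per_s = 1000 * rt_span_s / video_duration_s` is the
#' replay time needed per second of encoded video, and
#' `factor = video_duration_s / rt_span_s` the compression factor; a
#' factor above 1 means replay runs faster than perception did.
#'
#' @param rt_span_s RT difference (seconds) between the very first and
#'   very last chosen-frame location, e.g. from [estimate_rt_span()].
#' @param video_duration_s nominal video duration in seconds (default 10,
#'   the design mean).
#' @return List with `scan_ms_per_s` and `factor`.
#' @export
compression_factor <- function(rt_span_s, video_duration_s = 10) {
  if (rt_span_s <= 0) {
    stop("non-positive RT span: no forward compression interpretable",
         call. = FALSE)
  }
  list(scan_ms_per_s = 1000 * rt_span_s / video_duration_s,
       factor = video_duration_s / rt_span_s)
}

#' Fitted first-to-last-frame reaction-time span
#'
#' Linear fit of RT on the normalized chosen-frame location over
#' within-context trials; the span is the fitted RT difference between
#' location 1 and location 0 (the regression slope).
#'
#' @param table a trial table.
#' @param within_only restrict to within-context trials (default TRUE).
#' @return Scalar span in seconds.
#' @export
estimate_rt_span <- function(table, within_only = TRUE) {
  if (within_only) {
    table <- table[table$boundary_condition != "across", , drop = FALSE]
  }
  loc <- chosen_frame_location(table)
  unname(stats::coef(stats::lm(table$rt_s ~ loc))[2L])
}

#' Clip 1 versus Clip 2 reaction-time contrast
#'
#' Compares, over subjects, the mean RT for chosen frames in Clip 1
#' against Clip 2 (within-context trials), with a one-tailed paired t-test
#' (alternative: Clip 1 faster), Cohen's d on the paired differences, and
#' a one-sided 95% CI. A log(RT) variant is included. Subjects lacking
#' trials in either clip are excluded and listed in `excluded`.
#'
#' @param table a trial table.
#' @return List with `per_subject` tibble, `mean_rt_clip1`,
#'   `mean_rt_clip2`, `t`, `df`, `p_value`, `cohens_d`, `ci_upper`,
#'   `log_rt` (same statistics on log RT), `excluded`.
#' @export
clip_rt_contrast <- function(table) {
  table <- table[table$boundary_condition != "across", , drop = FALSE]
  in_clip2 <- table$chosen_frame >= table$boundary_frame
  per <- lapply(split(seq_len(nrow(table)), table$subject_id), function(idx) {
    c2 <- in_clip2[idx]
    c(clip1 = mean(table$rt_s[idx][!c2]), clip2 = mean(table$rt_s[idx][c2]),
      log1 = mean(log(table$rt_s[idx][!c2])),
      log2 = mean(log(table$rt_s[idx][c2])))
  })
  per_subject <- tibble::tibble(
    subject_id = names(per),
    rt_clip1 = vapply(per, `[[`, numeric(1), "clip1"),
    rt_clip2 = vapply(per, `[[`, numeric(1), "clip2"),
    log_rt_clip1 = vapply(per, `[[`, numeric(1), "log1"),
    log_rt_clip2 = vapply(per, `[[`, numeric(1), "log2")
  )
  excluded <- per_subject$subject_id[!is.finite(per_subject$rt_clip1) |
                                       !is.finite(per_subject$rt_clip2)]
  per_subject <- per_subject[!(per_subject$subject_id %in% excluded), ]
  if (nrow(per_subject) < 2L) {
    stop("need at least 2 subjects with trials in both clips", call. = FALSE)
  }
  paired <- function(a, b) {
    tt <- stats::t.test(a, b, paired = TRUE, alternative = "less")
    d <- a - b
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, cohens_d = mean(d) / stats::sd(d),
         ci_upper = unname(tt$conf.int[2L]))
  }
  raw <- paired(per_subject$rt_clip1, per_subject$rt_clip2)
  logv <- paired(per_subject$log_rt_clip1, per_subject$log_rt_clip2)
  c(list(per_subject = per_subject,
         mean_rt_clip1 = mean(per_subject$rt_clip1),
         mean_rt_clip2 = mean(per_subject$rt_clip2)),
    raw, list(log_rt = logv, excluded = excluded))
}

#' One-way ANOVA over the three trial types
#'
#' Subject-level mean RTs for across, within-Clip-1 and within-Clip-2
#' trials, analysed as a one-way between-cells ANOVA (3 groups x
#' n subjects; 6 subjects give F(2, 15)). Subjects missing a condition
#' are excluded and listed.
#'
#' @param table a trial table.
#' @return List with `means` tibble (subject x condition), `F`, `df`,
#'   `p_value`, `excluded`.
#' @export
trial_type_anova <- function(table) {
  agg <- stats::aggregate(rt_s ~ subject_id + boundary_condition,
                          data = as.data.frame(table)[c(
                            "subject_id", "boundary_condition", "rt_s")],
                          FUN = mean)
  counts <- table(agg$subject_id)
  excluded <- names(counts)[counts < 3L]
  agg <- agg[!(agg$subject_id %in% excluded), ]
  if (length(unique(agg$subject_id)) < 2L) {
    stop("need at least 2 subjects with all three trial types",
         call. = FALSE)
  }
  fit <- stats::aov(rt_s ~ boundary_condition, data = agg)
  s <- summary(fit)[[1L]]
  list(means = tibble::as_tibble(agg), F = s[["F value"]][1L],
       df = c(s[["Df"]][1L], s[["Df"]][2L]), p_value = s[["Pr(>F)"]][1L],
       excluded = excluded)
}

#' Sliding-window accuracy and reciprocal-latency curves
#'
#' Windowed means over frame location: accuracy is indexed by the target
#' (earlier-probe) frame, reciprocal RT by the chosen frame. Windows with
#' no trials are reported as `NA` gaps, not interpolated.
#'
#' @param table a trial table.
#' @param window_frames window width in frames (default 25, ~1 s of
#'   video).
#' @param step step between window centers in frames (default 1).
#' @return List with tibbles `accuracy` and `reciprocal_rt` (columns
#'   `center_frame`, `value`, `n`), plus `chance` (0.5) and
#'   `mean_boundary_frame`.
#' @export
sliding_accuracy <- function(table, window_frames = 25L, step = 1L) {
  stopifnot(window_frames >= 1L, step >= 1L)
  half <- window_frames / 2
  curve <- function(frame, value) {
    centers <- seq(min(frame), max(frame), by = step)
    rows <- lapply(centers, function(ctr) {
      idx <- frame >= ctr - half & frame <= ctr + half
      n <- sum(idx)
      tibble::tibble(center_frame = ctr,
                     value = if (n > 0L) mean(value[idx]) else NA_real_,
                     n = n)
    })
    do.call(rbind, rows)
  }
  list(accuracy = curve(table$probe_early_frame, as.numeric(table$correct)),
       reciprocal_rt = curve(table$chosen_frame, 1 / table$rt_s),
       chance = 0.5, mean_boundary_frame = mean(table$boundary_frame))
}

#' Inverse efficiency scores over video segments
#'
#' Segments each video by target-frame location (default 4 segments: two
#' per clip, split at the midpoint of each clip) and computes, per subject
#' and segment, IES = mean RT in ms / percent correct (0-100 scale); a
#' speed-accuracy composite. A one-way ANOVA across segments over subjects
#' follows (6 subjects x 4 segments give F(3, 20)).
#'
#' @param table a trial table.
#' @param n_segments number of segments (default 4; must be even so each
#'   clip is halved).
#' @return List with `ies` tibble (`subject_id`, `segment`, `mean_rt_ms`,
#'   `percent_correct`, `ies`), `F`, `df`, `p_value`, `flagged`
#'   (zero-accuracy cells).
#' @export
inverse_efficiency <- function(table, n_segments = 4L) {
  stopifnot(n_segments %% 2L == 0L)
  half <- n_segments %/% 2L
  # position of the target frame within its clip, then segment index
  target <- table$probe_early_frame
  in_clip2 <- target >= table$boundary_frame
  rel <- ifelse(in_clip2,
                (target - table$boundary_frame) /
                  (table$n_frames - table$boundary_frame),
                target / table$boundary_frame)
  seg <- pmin(floor(rel * half) + 1L, half) + ifelse(in_clip2, half, 0L)
  key <- split(seq_len(nrow(table)),
               list(table$subject_id, seg), drop = TRUE, sep = "\r")
  rows <- lapply(names(key), function(k) {
    idx <- key[[k]]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    pc <- 100 * mean(table$correct[idx])
    tibble::tibble(subject_id = parts[1L], segment = as.integer(parts[2L]),
                   mean_rt_ms = 1000 * mean(table$rt_s[idx]),
                   percent_correct = pc,
                   ies = if (pc > 0) 1000 * mean(table$rt_s[idx]) / pc
                         else NA_real_)
  })
  ies <- do.call(rbind, rows)
  ies <- ies[order(ies$subject_id, ies$segment), ]
  flagged <- ies[is.na(ies$ies), c("subject_id", "segment")]
  ok <- ies[!is.na(ies$ies), ]
  n_groups <- length(unique(ok$segment))
  if (nrow(ok) - n_groups < 1L) {
    # no residual degrees of freedom (e.g. a single subject)
    return(list(ies = ies, F = NA_real_,
                df = c(n_groups - 1L, nrow(ok) - n_groups),
                p_value = NA_real_, flagged = flagged))
  }
  fit <- stats::aov(ies ~ factor(segment), data = ok)
  s <- summary(fit)[[1L]]
  list(ies = ies, F = s[["F value"]][1L],
       df = c(s[["Df"]][1L], s[["Df"]][2L]), p_value = s[["Pr(>F)"]][1L],
       flagged = flagged)
}
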