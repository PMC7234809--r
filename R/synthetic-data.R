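# Synthetic TOJ trial generator. Reproduces the factorial task design
# (Boundary x Play order x Temporal distance x Exposure) and draws choices
# and reaction times from a LATER-style promptness process with a
# configurable replay offset, so every analysis stage can be exercised
# without external data.

#' Factorial design specification for synthetic TOJ sessions
#'
#' Defaults reproduce the macaque study design: 50 sessions of 100 trials
#' (5000 trials), a 2 (Boundary: within/across) x 2 (Play order) x
#' 25 (Temporal distance) x 5 (Exposure) within-subject crossing, videos of
#' 8-12 s made of two 4-6 s clips at 25 frames/s, and a temporal-distance
#' grid starting at 25 frames (1000 ms) rising in 3-frame steps to
#' 97 frames (3880 ms). A human-style variant uses 20 sessions and 2
#' exposures (2000 trials).
#'
#' @param n_sessions number of daily sessions.
#' @param trials_per_session trials per session; must equal the
#'   boundary x play-order x TD crossing size so each session holds one
#'   full crossing.
#' @param n_exposures number of repeated exposures (R1..Rn); sessions are
#'   blocked by exposure.
#' @param td_levels number of temporal-distance levels.
#' @param td_min_frames probe separation at TD level 1, in frames.
#' @param td_step_frames per-level increment, in frames.
#' @param frame_rate_hz video frame rate.
#' @param clip_len_range_s range (min, max) of each clip's length in
#'   seconds; a video is two concatenated clips.
#' @return A `design_spec` list.
#' @export
design_spec <- function(n_sessions = 50, trials_per_session = 100,
                        n_exposures = 5, td_levels = 25, td_min_frames = 25,
                        td_step_frames = 3, frame_rate_hz = 25,
                        clip_len_range_s = c(4, 6)) {
  spec <- list(n_sessions = as.integer(n_sessions),
               trials_per_session = as.integer(trials_per_session),
               n_exposures = as.integer(n_exposures),
               td_levels = as.integer(td_levels),
               td_min_frames = as.integer(td_min_frames),
               td_step_frames = as.integer(td_step_frames),
               frame_rate_hz = frame_rate_hz,
               clip_len_range_s = as.numeric(clip_len_range_s))
  if (spec$trials_per_session != 4L * spec$td_levels) {
    stop("trials_per_session must equal 2 x 2 x td_levels so each session ",
         "holds one full boundary x play-order x TD crossing", call. = FALSE)
  }
  if (spec$n_sessions %% spec$n_exposures != 0L) {
    stop("n_sessions must be a multiple of n_exposures (exposure-blocked ",
         "sessions)", call. = FALSE)
  }
  class(spec) <- "design_spec"
  spec
}

#' Maximum temporal distance of a design, in milliseconds
#' @param spec a [design_spec()].
#' @return Scalar: separation at the top TD level, in ms.
#' @export
td_max_ms <- function(spec) {
  frames <- spec$td_min_frames + spec$td_step_frames * (spec$td_levels - 1L)
  1000 * frames / spec$frame_rate_hz
}

#' Parameters of the generative replay + LATER process
#'
#' Reaction times are generated as the reciprocal of a Gaussian promptness
#' draw whose mean is `1 / replay_mean_rt(...)`: the mean RT for a chosen
#' frame at video time t is `t0_s + scan_rate_s_per_s * t`, plus
#' `replay_offset` once the chosen frame lies at or beyond the clip
#' boundary. `replay_offset = 0` is strict forward replay; a negative
#' offset equal to minus the scanned duration of Clip 1 is a full
#' global-compression reset.
#'
#' @param replay_offset seconds added to the mean RT for chosen frames in
#'   Clip 2 (0 = strict forward; negative = compression of Clip 1).
#' @param scan_rate_s_per_s replay time needed per second of encoded
#'   video; default 0.0942 (a compression factor of ~10.6).
#' @param t0_s non-replay base latency in seconds.
#' @param promptness_sd SD of the Gaussian promptness noise (s^-1).
#' @param context_rate_gain additive increase of the promptness mean on
#'   across-context trials (s^-1); the generative counterpart of a LATER
#'   "shift" (rate-of-rise) effect.
#' @param context_mode how the across-context condition perturbs the
#'   promptness distribution: `"shift"` adds `context_rate_gain` to the
#'   mean; `"swivel"` scales mean and SD jointly by `context_scale`
#'   (preserving mean/SD, i.e. the reciprobit intercept); `"none"`
#'   disables the context effect.
#' @param context_scale multiplicative factor for `context_mode =
#'   "swivel"`.
#' @param acc_intercept,acc_ts_weight,acc_across_weight coefficients of
#'   the chance-floored logistic accuracy model
#'   `P(correct) = max(0.5, plogis(c0 + c1 (1 - TS) + c2 across))`.
#' @return A `generator_params` list.
#' @export
generator_params <- function(replay_offset = 0, scan_rate_s_per_s = 0.0942,
                             t0_s = 0.9, promptness_sd = 0.15,
                             context_rate_gain = 0.1,
                             context_mode = c("shift", "swivel", "none"),
                             context_scale = 1.2,
                             acc_intercept = 0, acc_ts_weight = 2.5,
                             acc_across_weight = 0.5) {
  stopifnot(scan_rate_s_per_s > 0, promptness_sd > 0, t0_s > 0)
  params <- list(replay_offset = replay_offset,
                 scan_rate_s_per_s = scan_rate_s_per_s, t0_s = t0_s,
                 promptness_sd = promptness_sd,
                 context_rate_gain = context_rate_gain,
                 context_mode = match.arg(context_mode),
                 context_scale = context_scale,
                 acc_intercept = acc_intercept,
                 acc_ts_weight = acc_ts_weight,
                 acc_across_weight = acc_across_weight)
  class(params) <- "generator_params"
  params
}

#' Lay out the factorial design of one synthetic subject
#'
#' Emits `n_sessions * trials_per_session` trials. Each session holds one
#' full boundary x play-order x TD crossing in seeded random order;
#' exposures are blocked over sessions (R1 sessions first, then R2, ...),
#' mirroring a list-repetition schedule. Clip lengths are drawn uniformly
#' from `clip_len_range_s`; probe frames are placed uniformly subject to
#' the trial's TD level and boundary condition. Choices and reaction times
#' are left unset (`NA`); see [generate_dataset()].
#'
#' @param spec a [design_spec()].
#' @param seed integer seed; the same seed reproduces the same table.
#' @param subject_id subject label.
#' @return A `toj_trials` tibble with `chosen_frame`, `correct`, `rt_s`
#'   set to `NA`.
#' @export
build_design <- function(spec = design_spec(), seed = 1L,
                         subject_id = "synthetic") {
  withr::with_seed(as.integer(seed), build_design_impl(spec, subject_id))
}

build_design_impl <- function(spec, subject_id) {
  n_total <- spec$n_sessions * spec$trials_per_session
  sessions_per_exp <- spec$n_sessions %/% spec$n_exposures

  cells <- expand.grid(boundary = c("within", "across"),
                       play_order = c("forward", "reverse"),
                       td_level = seq_len(spec$td_levels),
                       stringsAsFactors = FALSE)

  session_index <- rep(seq_len(spec$n_sessions),
                       each = spec$trials_per_session)
  exposure <- rep(rep(seq_len(spec$n_exposures), each = sessions_per_exp),
                  each = spec$trials_per_session)
  # primate / non-primate lists alternate across sessions within a block
  session_cat <- rep_len(c("nonprimate", "primate"), spec$n_sessions)
  category <- session_cat[session_index]

  perm <- unlist(lapply(seq_len(spec$n_sessions), function(s) {
    sample.int(nrow(cells))
  }), use.names = FALSE)
  boundary <- cells$boundary[perm]
  play_order <- cells$play_order[perm]
  td_level <- cells$td_level[perm]

  fr <- spec$frame_rate_hz
  clip1 <- as.integer(round(stats::runif(n_total, spec$clip_len_range_s[1],
                                         spec$clip_len_range_s[2]) * fr))
  clip2 <- as.integer(round(stats::runif(n_total, spec$clip_len_range_s[1],
                                         spec$clip_len_range_s[2]) * fr))
  n_frames <- clip1 + clip2
  boundary_frame <- clip1
  sep <- spec$td_min_frames + spec$td_step_frames * (td_level - 1L)

  if (any(sep >= pmin(clip1, clip2))) {
    bad <- which(sep >= pmin(clip1, clip2))[1L]
    stop("design infeasible: TD separation exceeds clip length at trial ",
         bad, call. = FALSE)
  }

  early <- integer(n_total)
  is_across <- boundary == "across"
  # across: early in Clip 1, late = early + sep in Clip 2
  lo <- pmax(0L, boundary_frame - sep)
  hi <- pmin(boundary_frame - 1L, n_frames - 1L - sep)
  early[is_across] <- lo[is_across] +
    floor(stats::runif(sum(is_across)) * (hi - lo + 1L)[is_across])
  # within: both probes inside one clip, chosen at random
  in_clip2 <- !is_across & stats::runif(n_total) < 0.5
  in_clip1 <- !is_across & !in_clip2
  early[in_clip1] <- floor(stats::runif(sum(in_clip1)) *
                             (boundary_frame - sep)[in_clip1])
  early[in_clip2] <- boundary_frame[in_clip2] +
    floor(stats::runif(sum(in_clip2)) * (clip2 - sep)[in_clip2])
  early <- as.integer(early)
  late <- early + as.integer(sep)

  video_duration_s <- n_frames / fr
  # per-session elapsed clock: video + delay + response overhead (~3 s)
  trial_in_session <- rep(seq_len(spec$trials_per_session),
                          spec$n_sessions)
  elapsed <- (trial_in_session - 1L) * (mean(video_duration_s) + 5)

  trials <- tibble::tibble(
    subject_id = subject_id, session_index = session_index,
    trial_index = trial_in_session, video_duration_s = video_duration_s,
    boundary_frame = boundary_frame, n_frames = n_frames,
    frame_rate_hz = fr, probe_early_frame = early, probe_late_frame = late,
    chosen_frame = NA_integer_, correct = NA, rt_s = NA_real_,
    boundary_condition = NA_character_, play_order = play_order,
    td_level = td_level, exposure = exposure, category = category,
    touch_side = sample(c("left", "right"), n_total, replace = TRUE),
    elapsed_time_s = elapsed
  )
  trials$boundary_condition <- label_condition(trials)
  trial_table(trials, validate = FALSE)
}

#' Mean reaction time under a replay model
#'
#' `t0 + scan_rate * t(chosen_frame) + replay_offset * [chosen >= boundary]`
#' where `t(f) = f / frame_rate_hz` is the chosen frame's time in the
#' video. Strictly increasing in chosen-frame time within a clip.
#'
#' @param trials a trial table with `chosen_frame` set.
#' @param params a [generator_params()].
#' @return Numeric vector of mean RTs in seconds.
#' @export
replay_mean_rt <- function(trials, params = generator_params()) {
  if (any(is.na(trials$chosen_frame))) {
    stop("chosen_frame must be set before computing replay mean RT",
         call. = FALSE)
  }
  t_chosen <- trials$chosen_frame / trials$frame_rate_hz
  in_clip2 <- trials$chosen_frame >= trials$boundary_frame
  rt <- params$t0_s + params$scan_rate_s_per_s * t_chosen +
    params$replay_offset * in_clip2
  if (any(rt <= 0)) {
    stop("parameter error: replay offset drives mean RT non-positive",
         call. = FALSE)
  }
  rt
}

#' Draw LATER-style reaction times
#'
#' Promptness is drawn from `Normal(1/mean_rt [+ context gain], sd)` and
#' redrawn until it exceeds 0.05 s^-1 (capping RT at 20 s), then inverted.
#'
#' @param mean_rt vector of mean RTs in seconds.
#' @param params a [generator_params()].
#' @param across logical vector: is the trial across-context?
#' @return Numeric vector of RTs in seconds.
#' @export
simulate_rt <- function(mean_rt, params = generator_params(),
                        across = FALSE) {
  stopifnot(all(mean_rt > 0))
  n <- length(mean_rt)
  across <- rep_len(across, n)
  mu <- 1 / mean_rt
  sd <- rep_len(params$promptness_sd, n)
  if (params$context_mode == "shift") {
    mu <- mu + params$context_rate_gain * across
  } else if (params$context_mode == "swivel") {
    mu <- mu * ifelse(across, params$context_scale, 1)
    sd <- sd * ifelse(across, params$context_scale, 1)
  }
  p <- stats::rnorm(n, mu, sd)
  bad <- which(p <= 0.05)
  while (length(bad) > 0L) {
    p[bad] <- stats::rnorm(length(bad), mu[bad], sd[bad])
    bad <- bad[p[bad] <= 0.05]
  }
  1 / p
}

#' Draw TOJ choices from a chance-floored logistic accuracy model
#'
#' `P(correct) = clamp(plogis(c0 + c1 (1 - TS) + c2 across), 0.5, 1)`:
#' accuracy improves as the probes become temporally more discriminable
#' (lower TS) and on across-context trials, and never falls below chance.
#' This is synthetic scaffolding; it makes no claim about the animals'
#' choice process.
#'
#' @param trials a trial table (TS computable).
#' @param params a [generator_params()].
#' @return Logical vector: correct choice per trial.
#' @export
simulate_choice <- function(trials, params = generator_params()) {
  ts <- temporal_similarity(trials)
  across <- trials$boundary_condition == "across"
  p <- stats::plogis(params$acc_intercept +
                       params$acc_ts_weight * (1 - ts) +
                       params$acc_across_weight * across)
  p <- pmin(pmax(p, 0.5), 1)
  stats::runif(nrow(trials)) < p
}

#' Generate a complete synthetic TOJ dataset
#'
#' Builds the factorial design, draws choices from the accuracy model and
#' reaction times from the replay + LATER process. Deterministic given
#' `seed`.
#'
#' @param spec a [design_spec()].
#' @param params a [generator_params()].
#' @param seed integer seed.
#' @param subject_id subject label.
#' @return A complete `toj_trials` tibble.
#' @export
generate_dataset <- function(spec = design_spec(),
                             params = generator_params(), seed = 1L,
                             subject_id = "synthetic") {
  trials <- build_design(spec, seed = seed, subject_id = subject_id)
  withr::with_seed(as.integer(seed) + 1L, {
    correct <- simulate_choice(trials, params)
    trials$chosen_frame <- as.integer(
      ifelse(correct, trials$probe_early_frame, trials$probe_late_frame))
    trials$correct <- correct
    mean_rt <- replay_mean_rt(trials, params)
    trials$rt_s <- simulate_rt(
      mean_rt, params, across = trials$boundary_condition == "across")
  })
  trial_table(trials)
}

#' Generate a multi-subject synthetic cohort
#'
#' @param n_subjects number of subjects.
#' @param spec,params,seed as in [generate_dataset()]; each subject uses
#'   an offset seed.
#' @return A `toj_trials` tibble with subjects `S1..Sn`.
#' @export
generate_cohort <- function(n_subjects = 6, spec = design_spec(),
                            params = generator_params(), seed = 1L) {
  tables <- lapply(seq_len(n_subjects), function(i) {
    as.data.frame(generate_dataset(spec, params, seed = seed + 1000L * i,
                                   subject_id = sprintf("S%d", i)))
  })
  trial_table(do.call(rbind, tables))
}
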