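# Builders for small hand-specified trial tables and truncated promptness
# samples used across the suite.

# A valid trial table from vectors; defaults give a 10 s video at 25 fps
# with the boundary at frame 125 and both probes in Clip 1.
make_trials <- function(rt = 1.5, early = 50L, late = 100L,
                        chosen = NULL, boundary = 125L, n_frames = 250L,
                        subject = "S1", session = 1L, correct = NULL,
                        frame_rate = 25) {
  n <- max(length(rt), length(early), length(late), length(boundary),
           length(n_frames), length(subject))
  rt <- rep_len(rt, n); early <- rep_len(as.integer(early), n)
  late <- rep_len(as.integer(late), n)
  boundary <- rep_len(as.integer(boundary), n)
  n_frames <- rep_len(as.integer(n_frames), n)
  subject <- rep_len(subject, n)
  if (is.null(chosen)) chosen <- early
  chosen <- rep_len(as.integer(chosen), n)
  if (is.null(correct)) correct <- chosen == early
  df <- tibble::tibble(
    subject_id = subject, session_index = rep_len(as.integer(session), n),
    trial_index = seq_len(n), video_duration_s = n_frames / frame_rate,
    boundary_frame = boundary, n_frames = n_frames,
    frame_rate_hz = frame_rate, probe_early_frame = early,
    probe_late_frame = late, chosen_frame = chosen,
    correct = rep_len(correct, n), rt_s = rt,
    boundary_condition = "within_clip1", play_order = "forward",
    td_level = 1L, exposure = 1L, category = "nonprimate",
    touch_side = "left", elapsed_time_s = seq_len(n) * 10
  )
  df$boundary_condition <- label_condition(df)
  trial_table(df)
}

# Truncated Gaussian promptness draws inverted to RTs (the generative
# LATER process used for the model-recovery studies).
draw_rts <- function(n, m, s, floor_p = 0.05) {
  p <- stats::rnorm(n, m, s)
  while (any(p <= floor_p)) {
    p[p <= floor_p] <- stats::rnorm(sum(p <= floor_p), m, s)
  }
  1 / p
}

# Two-condition RT data under a given LATER change mode.
draw_condition_pair <- function(kind = c("shift", "swivel", "null"),
                                n = 1000L, m = 1 / 1.5, s = 0.15,
                                gain = 0.1, scale = 1.2) {
  kind <- match.arg(kind)
  m2 <- switch(kind, shift = m + gain, swivel = m * scale, null = m)
  s2 <- switch(kind, shift = s, swivel = s * scale, null = s)
  list(within = draw_rts(n, m, s), across = draw_rts(n, m2, s2))
}

# Flat gray test image, or a smooth deterministic sinusoidal texture
# (smooth enough that Harris corners are stable under mild noise).
make_image <- function(h = 48L, w = 48L, value = 128L, texture = FALSE,
                       seed = 1L) {
  img <- array(as.integer(value), c(h, w, 3L))
  if (texture) {
    withr::with_seed(seed, {
      y <- matrix(seq_len(h), h, w)
      x <- matrix(seq_len(w), h, w, byrow = TRUE)
      base <- matrix(0, h, w)
      for (k in 1:4) {
        fy <- sample(1:5, 1); fx <- sample(1:5, 1)
        base <- base + sin(2 * pi * (fy * y / h + fx * x / w) +
                             stats::runif(1, 0, 2 * pi))
      }
    })
    base <- as.integer(round(127 + 30 * base))
    base <- pmin(pmax(base, 0L), 255L)
    for (ch in 1:3) img[, , ch] <- base
  }
  img
}
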