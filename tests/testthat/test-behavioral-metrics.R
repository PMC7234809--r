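test_that("compression arithmetic follows span and duration exactly", {
  cf <- compression_factor(0.942, 10)
  expect_equal(cf$scan_ms_per_s, 94.2)
  expect_equal(cf$factor, 10 / 0.942)

  expect_equal(compression_factor(10, 10)$factor, 1)
  expect_equal(compression_factor(0.5, 10)$factor, 20)
  # factor x span = duration exactly
  expect_equal(compression_factor(0.37, 10)$factor * 0.37, 10)
  expect_error(compression_factor(-0.1), "non-positive")

  # the fitted span on strict-forward data is close to the generative one
  d <- generate_dataset(seed = 71)
  span <- estimate_rt_span(d)
  expect_gt(span, 0.7)
  expect_lt(span, 1.3)
})

test_that("clip contrast reproduces the closed-form paired t on a toy", {
  # 3 subjects with paired differences -0.1, -0.2, -0.3
  clip1 <- c(1.0, 1.1, 1.2)
  clip2 <- clip1 + c(0.1, 0.2, 0.3)
  tabs <- lapply(1:3, function(i) {
    as.data.frame(make_trials(
      rt = c(rep(clip1[i], 10), rep(clip2[i], 10)),
      early = c(rep(50L, 10), rep(150L, 10)),
      late = c(rep(100L, 10), rep(200L, 10)),
      boundary = 125L, subject = sprintf("S%d", i)))
  })
  tab <- trial_table(do.call(rbind, tabs))
  res <- clip_rt_contrast(tab)
  d <- clip1 - clip2
  t_oracle <- mean(d) / (stats::sd(d) / sqrt(3))
  expect_equal(res$t, t_oracle, tolerance = 1e-8)
  expect_equal(res$t, -3.464, tolerance = 1e-3)
  expect_equal(res$df, 2)
  expect_equal(res$cohens_d, mean(d) / stats::sd(d), tolerance = 1e-8)

  # no mean clip difference over subjects: t ~ 0, p ~ 0.5
  diffs0 <- c(-0.1, 0, 0.1)
  same <- lapply(1:3, function(i) {
    as.data.frame(make_trials(
      rt = c(rep(1.0, 10), rep(1.0 + diffs0[i], 10)),
      early = c(rep(50L, 10), rep(150L, 10)),
      late = c(rep(100L, 10), rep(200L, 10)),
      boundary = 125L, subject = sprintf("S%d", i)))
  })
  res0 <- clip_rt_contrast(trial_table(do.call(rbind, same)))
  expect_equal(res0$t, 0, tolerance = 1e-8)
  expect_equal(res0$p_value, 0.5, tolerance = 1e-8)

  # forward-replay cohort: Clip 1 faster, one-tailed p < 0.05
  coh <- generate_cohort(6, spec = design_spec(n_sessions = 10), seed = 72)
  res1 <- clip_rt_contrast(coh)
  expect_lt(res1$mean_rt_clip1, res1$mean_rt_clip2)
  expect_lt(res1$p_value, 0.05)
  expect_lt(res1$log_rt$p_value, 0.05)
})

test_that("trial-type ANOVA matches the textbook F on subject means", {
  mk_cohort <- function(mu, sd = 0.1, seed = 73) {
    withr::with_seed(seed, {
      tabs <- lapply(1:6, function(i) {
        rts <- c(stats::rnorm(1, mu[1], sd), stats::rnorm(1, mu[2], sd),
                 stats::rnorm(1, mu[3], sd))
        as.data.frame(make_trials(
          rt = rep(rts, each = 5),
          early = rep(c(50L, 150L, 100L), each = 5),
          late = rep(c(100L, 200L, 150L), each = 5),
          boundary = 125L, subject = sprintf("S%d", i)))
      })
      trial_table(do.call(rbind, tabs))
    })
  }
  strong <- trial_type_anova(mk_cohort(c(1, 2, 3)))
  expect_equal(strong$df, c(2, 15))
  expect_lt(strong$p_value, 1e-6)

  # independent closed-form oracle on the subject x condition means
  m <- strong$means
  groups <- split(m$rt_s, m$boundary_condition)
  grand <- mean(m$rt_s)
  ss_b <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                     numeric(1)))
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f_oracle <- (ss_b / 2) / (ss_w / 15)
  expect_equal(strong$F, f_oracle, tolerance = 1e-8)

  # each subject equally fast in all three trial types: F is exactly 0
  withr::with_seed(74, {
    tabs0 <- lapply(1:6, function(i) {
      rt_i <- stats::rnorm(1, 1.5, 0.1)
      as.data.frame(make_trials(
        rt = rep(rt_i, 15),
        early = rep(c(50L, 150L, 100L), each = 5),
        late = rep(c(100L, 200L, 150L), each = 5),
        boundary = 125L, subject = sprintf("S%d", i)))
    })
  })
  null <- trial_type_anova(trial_table(do.call(rbind, tabs0)))
  expect_lt(null$F, 1e-6)
})

test_that("sliding windows average accuracy and promptness by location", {
  tab <- make_trials(rt = rep(1.5, 50),
                     early = as.integer(seq(0, 200, length.out = 50)),
                     late = as.integer(seq(0, 200, length.out = 50)) + 30L,
                     boundary = 116L, correct = TRUE,
                     chosen = as.integer(seq(0, 200, length.out = 50)))
  out <- sliding_accuracy(tab)
  expect_true(all(out$accuracy$value[out$accuracy$n > 0] == 1))
  expect_equal(out$chance, 0.5)
  expect_equal(out$mean_boundary_frame, 116)

  # a window covering the full range returns the global mean everywhere
  wide <- sliding_accuracy(tab, window_frames = 1000L, step = 200L)
  expect_true(all(wide$reciprocal_rt$value == mean(1 / tab$rt_s)))

  # empty windows are NA gaps
  sparse <- make_trials(rt = 1.5, early = c(0L, 200L), late = c(30L, 230L),
                        chosen = c(0L, 200L), boundary = 116L)
  gap <- sliding_accuracy(sparse, window_frames = 5L, step = 10L)
  expect_true(any(is.na(gap$accuracy$value)))
})

test_that("inverse efficiency is RT(ms) over percent correct", {
  # 1500 ms at 75% -> IES = 20
  early <- rep(c(20L, 80L, 150L, 210L), each = 8)
  ok <- rep(c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), 4)
  tab <- make_trials(rt = rep(1.5, 32), early = early, late = early + 25L,
                     boundary = 125L, correct = ok,
                     chosen = ifelse(ok, early, early + 25L))
  res <- inverse_efficiency(tab)
  expect_equal(res$ies$percent_correct, rep(75, 4))
  expect_equal(res$ies$ies, rep(20, 4))

  # 6 subjects x 4 segments: df (3, 20); per-subject-constant IES: F ~ 0
  tabs <- lapply(1:6, function(i) {
    as.data.frame(make_trials(
      rt = rep(1.4 + 0.02 * i, 40),
      early = rep(c(20L, 80L, 150L, 210L), 10),
      late = rep(c(45L, 105L, 175L, 235L), 10), boundary = 125L,
      subject = sprintf("S%d", i)))
  })
  flat <- inverse_efficiency(trial_table(do.call(rbind, tabs)))
  expect_equal(flat$df, c(3, 20))
  expect_lt(flat$F, 1e-6)
})
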