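test_that("the reciprocal-latency GLM is standardized least squares", {
  withr::with_seed(61, {
    # regressor equal to the (unit-SD) outcome: beta 1, p ~ 0
    y0 <- stats::rnorm(200)
    prom <- 5 + (y0 - mean(y0)) / stats::sd(y0)
    tab <- as.data.frame(make_trials(rt = 1 / prom))
    tab$self <- prom + stats::rnorm(200, 0, 1e-8)
    g <- reciprocal_latency_glm(trial_table(tab), "self")
    co <- g$coefficients[g$coefficients$term == "self", ]
    expect_equal(co$beta, 1, tolerance = 1e-5)
    expect_lt(co$p, 1e-100)
    expect_true(co$ci_lower <= co$beta && co$beta <= co$ci_upper)
  })

  # estimates equal an independent normal-equations solution
  d <- generate_dataset(design_spec(n_sessions = 5), seed = 62)
  w <- d[d$boundary_condition != "across", ]
  regs <- c("chosen_frame_location", "td_level", "play_order")
  g <- reciprocal_latency_glm(w, regs)
  X <- cbind(1, tojreplay:::build_design_matrix(w, regs))
  beta_oracle <- solve(t(X) %*% X, t(X) %*% (1 / w$rt_s))
  expect_equal(unname(g$coefficients$beta), unname(drop(beta_oracle)),
               tolerance = 1e-8)

  # collinear designs are refused with the columns named
  tab2 <- as.data.frame(w)
  tab2$dup <- tab2$td_level
  expect_error(reciprocal_latency_glm(trial_table(tab2),
                                      c("td_level", "dup")),
               "collinear")
})

test_that("a pure-noise regressor is significant at roughly alpha rate", {
  d <- generate_dataset(design_spec(n_sessions = 10), seed = 63)
  w <- as.data.frame(d[d$boundary_condition != "across", ])
  w <- w[seq_len(min(500L, nrow(w))), ]
  hits <- 0L
  withr::with_seed(64, {
    for (i in 1:100) {
      w$noise <- stats::rnorm(nrow(w))
      g <- reciprocal_latency_glm(trial_table(w), "noise")
      tval <- g$coefficients$t[g$coefficients$term == "noise"]
      hits <- hits + (abs(tval) >= 2)
    }
  })
  expect_lte(hits, 7) # ~alpha = 0.05 of 100 runs
})

test_that("strict-forward data yields negative location slopes", {
  d <- generate_dataset(seed = 65)
  w <- d[d$boundary_condition != "across", ]
  g <- reciprocal_latency_glm(w, c("chosen_frame_location",
                                   "temporal_similarity", "td_level",
                                   "play_order", "exposure", "correct"))
  co <- g$coefficients[g$coefficients$term == "chosen_frame_location", ]
  expect_lt(co$beta, 0)
  expect_lt(co$p, 0.001)

  # noise-free sanity: reciprocal latency strictly decreases in location
  loc <- seq(0, 1, length.out = 50)
  rt <- 0.9 + 0.942 * loc
  expect_true(all(diff(1 / rt) < 0))
})

test_that("per-subject slope tests split by correctness", {
  d <- generate_cohort(n_subjects = 3, spec = design_spec(n_sessions = 10),
                       seed = 66)
  w <- d[d$boundary_condition != "across", ]
  st <- slope_test(w, "chosen_frame_location",
                   nuisance = c("td_level", "play_order"))
  expect_equal(nrow(st), 9L) # 3 subjects x 3 splits
  fitted <- st[st$fitted, ]
  expect_true(all(fitted$beta < 0))
  # same sign in the correct-only and incorrect-only splits
  expect_true(all(fitted$beta[fitted$split == "correct"] < 0))
  expect_true(all(fitted$beta[fitted$split == "incorrect"] < 0))

  # undersized splits are flagged, not fitted
  tiny <- w[seq_len(40), ]
  st2 <- slope_test(tiny, "chosen_frame_location", min_trials = 30L)
  expect_true(any(!st2$fitted))
  expect_true(all(is.na(st2$beta[!st2$fitted])))
})

test_that("polynomial trends detect only the generated degree", {
  withr::with_seed(67, {
    hits1 <- 0L; hits2 <- 0L; hits3 <- 0L
    for (i in 1:100) {
      n <- 400
      loc_frames <- sample(0:224, n, replace = TRUE)
      prom <- 1 - 0.3 * (loc_frames / 249) + stats::rnorm(n, 0, 0.15)
      prom <- pmax(prom, 0.1)
      tab <- make_trials(rt = 1 / prom, early = loc_frames,
                         chosen = loc_frames,
                         late = loc_frames + 25L,
                         boundary = 260L, n_frames = 250L)
      tt <- polynomial_trend_test(tab)
      hits1 <- hits1 + tt$significant[1L]
      hits2 <- hits2 + tt$significant[2L]
      hits3 <- hits3 + tt$significant[3L]
    }
    expect_gte(hits1, 90)
    expect_lte(hits2, 12)
    expect_lte(hits3, 12)

    # a genuine cubic component is detected
    n <- 2000
    loc_frames <- sample(0:224, n, replace = TRUE)
    x <- loc_frames / 249
    prom <- 1 - 0.3 * x + 0.8 * (x - 0.5)^3 + stats::rnorm(n, 0, 0.1)
    prom <- pmax(prom, 0.1)
    tab <- make_trials(rt = 1 / prom, early = loc_frames,
                       chosen = loc_frames,
                       late = loc_frames + 25L,
                       boundary = 260L, n_frames = 250L)
    tt <- polynomial_trend_test(tab)
    expect_true(tt$significant[3L])
  })
})

test_that("the orthogonal basis decouples trend degrees", {
  withr::with_seed(68, {
    loc_frames <- sample(0:224, 500, replace = TRUE)
    prom <- 1 - 0.2 * (loc_frames / 249) + stats::rnorm(500, 0, 0.1)
    tab <- make_trials(rt = 1 / pmax(prom, 0.1), early = loc_frames,
                       chosen = loc_frames,
                       late = loc_frames + 25L,
                       boundary = 260L, n_frames = 250L)
  })
  deg2 <- polynomial_trend_test(tab, max_degree = 2L)
  deg3 <- polynomial_trend_test(tab, max_degree = 3L)
  expect_equal(deg2$beta[1:2], deg3$beta[1:2], tolerance = 1e-10)

  few <- make_trials(rt = c(1, 1.1, 1.2), early = c(0L, 100L, 200L),
                     chosen = c(0L, 100L, 200L),
                     late = c(25L, 125L, 225L), boundary = 260L)
  expect_error(polynomial_trend_test(few), "distinct")
})
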