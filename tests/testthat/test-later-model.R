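test_that("promptness log-likelihood matches the Gaussian density", {
  # single rt = 1 at (m, s) = (1, 1): standard normal density at its mean
  expect_equal(promptness_loglik(1, 1, 1), log(1 / sqrt(2 * pi)))

  withr::with_seed(5, {
    rts <- draw_rts(20, 0.7, 0.12)
    # independent brute-force sum of per-observation densities
    brute <- function(rts, m, s) {
      tot <- 0
      for (r in rts) {
        p <- 1 / r
        tot <- tot - 0.5 * log(2 * pi * s^2) - (p - m)^2 / (2 * s^2)
      }
      tot
    }
    expect_equal(promptness_loglik(rts, 0.7, 0.12), brute(rts, 0.7, 0.12),
                 tolerance = 1e-10)

    # the MLE identity: likelihood over m peaks at the promptness mean
    m_hat <- mean(1 / rts)
    grid <- seq(m_hat - 0.1, m_hat + 0.1, length.out = 41)
    lls <- vapply(grid, function(m) promptness_loglik(rts, m, 0.12),
                  numeric(1))
    expect_true(all(promptness_loglik(rts, m_hat, 0.12) >= lls))
  })
  expect_error(promptness_loglik(numeric(0), 1, 1), "empty")
})

test_that("condition MLE is the divide-by-n Gaussian estimate", {
  fit <- fit_condition_mle(c(1, 2), min_n = 2)
  expect_equal(fit$m, 0.75)
  expect_equal(fit$s, 0.25)

  withr::with_seed(6, {
    rts <- simulate_rt(rep(1.25, 1e4), generator_params(promptness_sd = 0.2))
    rec <- fit_condition_mle(rts)
    expect_lt(abs(rec$m - 0.8), 3 * 0.2 / sqrt(1e4))
    expect_lt(abs(rec$s - 0.2), 3 * 0.2 / sqrt(2 * 1e4))
  })

  expect_error(fit_condition_mle(c(1, 2)), "insufficient")
  expect_error(fit_condition_mle(rep(1.5, 10)), "degenerate")
})

test_that("identical condition data leaves all variants tied; null wins", {
  withr::with_seed(8, rts <- draw_rts(200, 0.65, 0.1))
  res <- fit_later(list(within = rts, across = rts))
  lls <- res$comparison$log_likelihood
  # equal up to the numeric optimizer's function tolerance
  expect_lt(max(lls) - min(lls), 1e-3 * max(1, abs(mean(lls))))
  expect_equal(res$comparison$variant[which.min(res$comparison$bic)],
               "null")
})

test_that("shift data is recovered as shift, with the closed-form s", {
  withr::with_seed(9, rts <- draw_condition_pair("shift", n = 1000))
  res <- fit_later(rts)
  ll <- function(v) res$fits[[v]]$log_likelihood
  expect_lte(ll("two_fits") - ll("shift"), 2)
  expect_lt(ll("swivel"), ll("shift"))

  # closed-form oracle: shared s is the pooled divide-by-n SD around the
  # per-condition promptness means
  p1 <- 1 / rts$within; p2 <- 1 / rts$across
  pooled_s <- sqrt((sum((p1 - mean(p1))^2) + sum((p2 - mean(p2))^2)) /
                     (length(p1) + length(p2)))
  shift <- res$fits$shift
  expect_equal(unname(shift$params$within["s"]), pooled_s,
               tolerance = 1e-4)
  expect_equal(unname(shift$params$within["m"]), mean(p1), tolerance = 1e-4)
  # and the numeric optimum cannot beat the closed-form likelihood
  closed <- promptness_loglik(rts$within, mean(p1), pooled_s) +
    promptness_loglik(rts$across, mean(p2), pooled_s)
  expect_equal(shift$log_likelihood, closed, tolerance = 1e-7)
})

test_that("likelihood nesting holds on arbitrary data", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      kind <- sample(c("shift", "swivel", "null"), 1)
      rts <- draw_condition_pair(kind, n = 150)
    })
    res <- fit_later(rts)
    ll <- function(v) res$fits[[v]]$log_likelihood
    expect_gte(ll("two_fits") + 1e-6, ll("shift"))
    expect_gte(ll("two_fits") + 1e-6, ll("swivel"))
    expect_gte(ll("shift") + 1e-6, ll("null"))
    expect_gte(ll("swivel") + 1e-6, ll("null"))
  }
})

test_that("fits depend on the promptness scale only", {
  withr::with_seed(12, rts <- draw_condition_pair("shift", n = 200))
  fit <- fit_variant(rts, "two_fits")
  for (cond in names(fit$params)) {
    ms <- fit$params[[cond]]
    der <- fit$derived[[cond]]
    # any (mu, sigma1, theta) with a common scale factor maps to the same
    # (m, s); the reported convention is sigma1 = 1
    for (k in c(1, 2.5, 10)) {
      mu <- k * der[["mu"]]; sigma1 <- k * der[["sigma1"]]
      theta <- k * der[["theta"]]
      expect_equal(mu / theta, unname(ms["m"]), tolerance = 1e-10)
      expect_equal(sigma1 / theta, unname(ms["s"]), tolerance = 1e-10)
    }
  }
})

test_that("BIC follows the -2logL + k log(n) formula and labels evidence", {
  mk <- function(ll, k, n, variant = "null") {
    structure(list(variant = variant, params = list(),
                   log_likelihood = ll, n_params = as.integer(k),
                   n_obs = as.integer(n)), class = "later_fit")
  }
  cmp <- compare_bic(list(mk(-100, 3, 1000)))
  expect_equal(cmp$bic, 200 + 3 * log(1000))

  cmp2 <- compare_bic(list(mk(-50, 2, 100, "null"),
                           mk(-50, 4, 100, "two_fits")))
  expect_equal(cmp2$delta_bic[2L], 2 * log(100))
  expect_equal(cmp2$evidence, c("best", "strong"))

  cmp3 <- compare_bic(list(mk(-50, 2, 100), mk(-51.5, 2, 100)))
  expect_equal(cmp3$evidence[2L], "positive") # delta = 3

  expect_error(compare_bic(list(mk(-50, 2, 100), mk(-50, 2, 200))),
               "same data")
})

test_that("reciprobit points use Hazen positions and pool ties", {
  pts <- reciprobit_points(c(1, 2))
  expect_equal(pts$p, c(0.25, 0.75))
  expect_equal(pts$z, stats::qnorm(c(0.25, 0.75)))
  expect_equal(pts$promptness, c(1, 0.5))

  tied <- reciprobit_points(c(1, 1, 2))
  expect_equal(nrow(tied), 2L)
  expect_equal(tied$n, c(2L, 1L))
  expect_equal(tied$p, c((2 - 1) / 3, (3 - 0.5) / 3))

  # simulated Gaussian promptness falls on a line of slope -1/s
  withr::with_seed(13, rts <- draw_rts(5000, 0.65, 0.12))
  pts <- reciprobit_points(rts)
  keep <- pts$p > 0.01 & pts$p < 0.99
  slope <- stats::coef(stats::lm(z ~ promptness,
                                 data = pts[keep, ]))[2L]
  expect_equal(unname(slope), -1 / 0.12, tolerance = 0.05)

  expect_error(reciprobit_points(rep(1.5, 4)), "distinct")
})

test_that("variant recovery holds across 100 seeded simulations", {
  run_one <- function(kind, seed) {
    withr::with_seed(seed, rts <- draw_condition_pair(kind, n = 1000))
    cmp <- fit_later(rts)$comparison
    list(best = cmp$variant[which.min(cmp$bic)],
         swivel_minus_shift = cmp$bic[cmp$variant == "swivel"] -
           cmp$bic[cmp$variant == "shift"])
  }
  shift_runs <- lapply(1:100, function(i) run_one("shift", 2000 + i))
  swivel_runs <- lapply(1:100, function(i) run_one("swivel", 4000 + i))

  expect_gte(sum(vapply(shift_runs, function(r) r$swivel_minus_shift > 6,
                        logical(1))), 90)
  expect_gte(sum(vapply(swivel_runs, function(r) r$swivel_minus_shift < -6,
                        logical(1))), 90)
  expect_gte(sum(vapply(swivel_runs, function(r) r$best == "swivel",
                        logical(1))), 90)
})
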