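# LATER (Linear Approach to Threshold with Ergodic Rate) fitting.
#
# A decision signal rises linearly from a start level S0 to a threshold
# ST (distance theta = ST - S0) at a rate r drawn per trial from
# Normal(mu, sigma1); the latency is theta / r, so promptness 1/RT is
# Gaussian with mean m = mu/theta and SD s = sigma1/theta. The likelihood
# depends on (m, s) only; reported (mu, theta) use the identifiability
# convention sigma1 = 1, i.e. theta = 1/s, mu = m/s.

#' Gaussian log-likelihood on the promptness scale
#'
#' Sum of Gaussian log-densities of the promptness values `1/rt` at mean
#' `m` and SD `s`. All model variants are compared on this common scale,
#' so no Jacobian back to the RT scale is applied.
#'
#' @param rts reaction times in seconds (all positive).
#' @param m promptness mean (s^-1).
#' @param s promptness SD (s^-1), positive.
#' @return Scalar log-likelihood.
#' @export
promptness_loglik <- function(rts, m, s) {
  if (length(rts) == 0L) stop("empty reaction-time vector", call. = FALSE)
  stopifnot(all(rts > 0), s > 0)
  ll <- sum(stats::dnorm(1 / rts, mean = m, sd = s, log = TRUE))
  if (!is.finite(ll)) stop("non-finite log-likelihood", call. = FALSE)
  ll
}

#' Exact Gaussian MLE of one condition's promptness distribution
#'
#' `m` is the sample mean of promptness and `s` the divide-by-n
#' (population-style) SD: the exact maximum-likelihood estimates.
#'
#' @param rts reaction times in seconds.
#' @param min_n minimum number of observations (default 3).
#' @return List with elements `m` and `s`.
#' @export
fit_condition_mle <- function(rts, min_n = 3L) {
  if (length(rts) < min_n) {
    stop("insufficient data: need at least ", min_n, " observations",
         call. = FALSE)
  }
  p <- 1 / rts
  m <- mean(p)
  s <- sqrt(mean((p - m)^2))
  if (s == 0) {
    stop("degenerate data: zero promptness variance", call. = FALSE)
  }
  list(m = m, s = s)
}

.later_variants <- c("null", "shift", "swivel", "two_fits")

#' Fit one LATER variant to two latency conditions
#'
#' The four variants constrain the per-condition promptness parameters
#' (m, s):
#' * `null` - one shared (m, s): no effect of the manipulation (2 params);
#' * `shift` - rate-of-rise mu free per condition, threshold and sigma1
#'   shared: shared `s`, free `m_c`; reciprobit lines parallel (3 params);
#' * `swivel` - threshold theta free per condition, mu and sigma1 shared:
#'   shared ratio `m_c/s_c`, free `s_c`; reciprobit lines pivot on the
#'   infinite-time intercept (3 params);
#' * `two_fits` - all parameters free (4 params).
#'
#' `null` and `two_fits` have closed-form MLEs; `shift` and `swivel` are
#' maximized numerically (Nelder-Mead, relative tolerance 1e-8, up to 1e4
#' iterations) starting from the `two_fits` solution.
#'
#' @param rts_by_condition named list of two positive RT vectors, e.g.
#'   `list(within = ..., across = ...)`.
#' @param variant one of `"null"`, `"shift"`, `"swivel"`, `"two_fits"`.
#' @param min_n minimum observations per condition (default 10).
#' @return A `later_fit` list: `variant`, `params` (per-condition m, s),
#'   `log_likelihood`, `n_params`, `n_obs`, and derived `(mu, theta)`
#'   under the sigma1 = 1 convention.
#' @export
fit_variant <- function(rts_by_condition, variant = .later_variants,
                        min_n = 10L) {
  variant <- match.arg(variant)
  stopifnot(length(rts_by_condition) == 2L)
  if (is.null(names(rts_by_condition))) {
    names(rts_by_condition) <- c("cond1", "cond2")
  }
  lapply(rts_by_condition, function(r) {
    if (length(r) < min_n) {
      stop("insufficient data: each condition needs >= ", min_n,
           " observations", call. = FALSE)
    }
    stopifnot(all(r > 0))
  })
  p1 <- 1 / rts_by_condition[[1L]]
  p2 <- 1 / rts_by_condition[[2L]]
  free1 <- fit_condition_mle(rts_by_condition[[1L]])
  free2 <- fit_condition_mle(rts_by_condition[[2L]])

  nll <- function(m1, s1, m2, s2) {
    -sum(stats::dnorm(p1, m1, s1, log = TRUE)) -
      sum(stats::dnorm(p2, m2, s2, log = TRUE))
  }

  if (variant == "two_fits") {
    par <- list(c(m = free1$m, s = free1$s), c(m = free2$m, s = free2$s))
    ll <- -nll(free1$m, free1$s, free2$m, free2$s)
    n_params <- 4L
  } else if (variant == "null") {
    pooled <- fit_condition_mle(c(rts_by_condition[[1L]],
                                  rts_by_condition[[2L]]))
    par <- list(c(m = pooled$m, s = pooled$s), c(m = pooled$m, s = pooled$s))
    ll <- -nll(pooled$m, pooled$s, pooled$m, pooled$s)
    n_params <- 2L
  } else if (variant == "shift") {
    # shared s, free m1/m2; optimized on (m1, m2, log s)
    obj <- function(th) nll(th[1L], exp(th[3L]), th[2L], exp(th[3L]))
    start <- c(free1$m, free2$m, log(sqrt((free1$s^2 * length(p1) +
                                             free2$s^2 * length(p2)) /
                                            (length(p1) + length(p2)))))
    opt <- later_optim(obj, start, variant)
    par <- list(c(m = opt$par[1L], s = exp(opt$par[3L])),
                c(m = opt$par[2L], s = exp(opt$par[3L])))
    ll <- -opt$value
    n_params <- 3L
  } else { # swivel: shared k = m/s, free s1/s2
    obj <- function(th) {
      k <- th[1L]; s1 <- exp(th[2L]); s2 <- exp(th[3L])
      nll(k * s1, s1, k * s2, s2)
    }
    k0 <- mean(c(free1$m / free1$s, free2$m / free2$s))
    start <- c(k0, log(free1$s), log(free2$s))
    opt <- later_optim(obj, start, variant)
    par <- list(c(m = opt$par[1L] * exp(opt$par[2L]), s = exp(opt$par[2L])),
                c(m = opt$par[1L] * exp(opt$par[3L]), s = exp(opt$par[3L])))
    ll <- -opt$value
    n_params <- 3L
  }

  names(par) <- names(rts_by_condition)
  derived <- lapply(par, function(ms) {
    c(mu = unname(ms["m"] / ms["s"]), sigma1 = 1,
      theta = unname(1 / ms["s"]))
  })
  structure(list(variant = variant, params = par, derived = derived,
                 log_likelihood = ll, n_params = n_params,
                 n_obs = length(p1) + length(p2)),
            class = "later_fit")
}

later_optim <- function(obj, start, variant) {
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-8, maxit = 1e4))
  if (opt$convergence != 0L) {
    stop("LATER '", variant, "' fit did not converge (optim code ",
         opt$convergence, " after ", opt$counts[1L], " evaluations)",
         call. = FALSE)
  }
  opt
}

#' Compare fitted LATER variants by BIC
#'
#' `BIC = -2 logL + n_params * log(n_obs)` with `n_obs` the total number
#' of observations across both conditions. Delta-BIC is taken relative to
#' the best (lowest-BIC) variant; a difference above 2 counts as positive
#' evidence and above 6 as strong evidence.
#'
#' @param fits list of `later_fit` objects on the same data.
#' @return A `later_model_comparison` tibble: one row per variant with
#'   `log_likelihood`, `n_params`, `bic`, `delta_bic`, `evidence`.
#' @export
compare_bic <- function(fits) {
  n_obs <- vapply(fits, function(f) f$n_obs, integer(1))
  if (length(unique(n_obs)) != 1L) {
    stop("fits were not computed on the same data (n_obs differ)",
         call. = FALSE)
  }
  bic <- vapply(fits, function(f) {
    -2 * f$log_likelihood + f$n_params * log(f$n_obs)
  }, numeric(1))
  delta <- bic - min(bic)
  evidence <- ifelse(delta == 0, "best",
                     ifelse(delta > 6, "strong",
                            ifelse(delta > 2, "positive", "weak")))
  out <- tibble::tibble(
    variant = unname(vapply(fits, function(f) f$variant, character(1))),
    log_likelihood = unname(vapply(fits, function(f) f$log_likelihood,
                                   numeric(1))),
    n_params = unname(vapply(fits, function(f) f$n_params, integer(1))),
    bic = unname(bic), delta_bic = unname(delta),
    evidence = unname(evidence)
  )
  class(out) <- c("later_model_comparison", class(out))
  out
}

#' Fit all four LATER variants and compare them
#'
#' @inheritParams fit_variant
#' @return List with `fits` (named list of `later_fit`) and `comparison`
#'   (see [compare_bic()]).
#' @export
fit_later <- function(rts_by_condition, min_n = 10L) {
  fits <- lapply(.later_variants, function(v) {
    fit_variant(rts_by_condition, v, min_n = min_n)
  })
  names(fits) <- .later_variants
  list(fits = fits, comparison = compare_bic(fits))
}

#' Reciprobit plotting points
#'
#' Maps the empirical latency distribution to reciprobit coordinates:
#' promptness `1/rt` against the probit (z) of the cumulative probability
#' P(RT <= rt), using Hazen plotting positions `(i - 0.5)/n` on the
#' cumulative counts. Tied RTs collapse to one point carrying their pooled
#' mass. Under LATER the points fall on the line `z = (m - promptness)/s`.
#'
#' @param rts reaction times in seconds (>= 2 distinct values).
#' @return Tibble with columns `rt`, `promptness`, `p`, `z`, `n` (tie
#'   multiplicity), ordered by increasing RT.
#' @export
reciprobit_points <- function(rts) {
  stopifnot(all(rts > 0))
  tab <- table(sort(rts))
  if (length(tab) < 2L) {
    stop("need at least 2 distinct reaction times", call. = FALSE)
  }
  vals <- as.numeric(names(tab))
  counts <- as.integer(tab)
  n <- sum(counts)
  p <- (cumsum(counts) - 0.5 * counts) / n
  tibble::tibble(rt = vals, promptness = 1 / vals, p = p,
                 z = stats::qnorm(p), n = counts)
}

#' @export
print.later_fit <- function(x, ...) {
  cat("<later_fit> variant:", x$variant, "\n")
  for (nm in names(x$params)) {
    cat(sprintf("  %-8s m = %.4f  s = %.4f\n", nm,
                x$params[[nm]]["m"], x$params[[nm]]["s"]))
  }
  cat(sprintf("  logL = %.3f  (%d params, %d obs)\n", x$log_likelihood,
              x$n_params, x$n_obs))
  invisible(x)
}

#' Serialize LATER results to JSON
#'
#' @param x a `later_fit` or the list returned by [fit_later()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_later_json <- function(x, path) {
  payload <- if (inherits(x, "later_fit")) {
    list(fit = unclass(x))
  } else {
    list(fits = lapply(x$fits, unclass),
         comparison = as.data.frame(x$comparison))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
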