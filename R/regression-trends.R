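# Reciprocal-latency regression. The outcome is promptness (1/RT); a
# negative coefficient on chosen-frame location is the signature of
# forward replay (later frames take longer to reach in memory).

# Standardize a design column: z-score continuous, +/-0.5 for two-level
# factors/logicals, so coefficients are comparable effect sizes.
standardize_regressor <- function(x, name) {
  if (is.logical(x)) return(ifelse(x, 0.5, -0.5))
  if (is.character(x) || is.factor(x)) {
    lev <- sort(unique(as.character(x)))
    if (length(lev) != 2L) {
      stop("regressor '", name, "' is categorical with ", length(lev),
           " levels; only two-level factors are supported", call. = FALSE)
    }
    return(ifelse(as.character(x) == lev[2L], 0.5, -0.5))
  }
  s <- stats::sd(x)
  if (s == 0) stop("regressor '", name, "' is constant", call. = FALSE)
  (x - mean(x)) / s
}

# Assemble the standardized design matrix for a set of named regressors.
# Derived columns (chosen_frame_location, temporal_similarity) are
# computed from the table when not already present.
build_design_matrix <- function(table, regressors) {
  cols <- lapply(regressors, function(nm) {
    x <- if (nm %in% names(table)) {
      table[[nm]]
    } else if (nm == "chosen_frame_location") {
      chosen_frame_location(table)
    } else if (nm == "temporal_similarity") {
      temporal_similarity(table)
    } else {
      stop("unknown regressor: ", nm, call. = FALSE)
    }
    standardize_regressor(x, nm)
  })
  names(cols) <- regressors
  X <- do.call(cbind, cols)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(seq_len(ncol(X) + 1L), keep) - 1L
    stop("rank-deficient design; collinear column(s): ",
         paste(regressors[dropped], collapse = ", "), call. = FALSE)
  }
  X
}

#' Gaussian GLM of reciprocal latency
#'
#' Fits promptness (`1/rt_s`) on the named regressors with a
#' Gaussian-family, identity-link model (least squares). Continuous
#' regressors are z-scored and two-level regressors coded +/-0.5, so the
#' coefficients are comparable standardized effect sizes. The regressor
#' names `chosen_frame_location` and `temporal_similarity` are computed
#' from the table on the fly.
#'
#' @param table a trial table.
#' @param regressors character vector of design columns.
#' @return A `toj_glm` list: `coefficients` tibble (term, beta, sem, t,
#'   p, ci_lower, ci_upper), `n_obs`, `family`, `fit` (the underlying
#'   `lm`).
#' @export
reciprocal_latency_glm <- function(table, regressors) {
  y <- 1 / table$rt_s
  if (stats::sd(y) == 0) stop("constant outcome", call. = FALSE)
  X <- build_design_matrix(table, regressors)
  dat <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = dat)
  coefs <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = 0.95)
  terms <- rownames(coefs)
  out <- tibble::tibble(
    term = ifelse(terms == "(Intercept)", "(Intercept)",
                  sub("^`|`$", "", terms)),
    beta = unname(coefs[, 1L]), sem = unname(coefs[, 2L]),
    t = unname(coefs[, 3L]), p = unname(coefs[, 4L]),
    ci_lower = unname(ci[, 1L]), ci_upper = unname(ci[, 2L])
  )
  structure(list(coefficients = out, n_obs = nrow(table),
                 family = "gaussian(identity)", fit = fit),
            class = "toj_glm")
}

#' Per-subject slope of reciprocal latency on a regressor of interest
#'
#' For each subject, fits [reciprocal_latency_glm()] with the regressor of
#' interest plus nuisance regressors and extracts the coefficient of
#' interest; repeated for all trials, correct-only and incorrect-only
#' splits. Splits with fewer than `min_trials` trials are flagged and not
#' fitted.
#'
#' @param table a trial table (one or more subjects).
#' @param regressor_of_interest column name (e.g.
#'   `"chosen_frame_location"`).
#' @param nuisance character vector of nuisance regressor names.
#' @param min_trials minimum trials per fit (default 30).
#' @return Tibble with one row per subject x split: `subject_id`, `split`,
#'   `n`, `fitted`, `beta`, `sem`, `t`, `p`, `ci_lower`, `ci_upper`.
#' @export
slope_test <- function(table, regressor_of_interest = "chosen_frame_location",
                       nuisance = character(), min_trials = 30L) {
  splits <- list(all = rep(TRUE, nrow(table)),
                 correct = table$correct,
                 incorrect = !table$correct)
  rows <- list()
  for (sid in unique(table$subject_id)) {
    for (sp in names(splits)) {
      idx <- table$subject_id == sid & splits[[sp]]
      n <- sum(idx)
      if (n < min_trials) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject_id = sid, split = sp, n = n, fitted = FALSE,
          beta = NA_real_, sem = NA_real_, t = NA_real_, p = NA_real_,
          ci_lower = NA_real_, ci_upper = NA_real_)
        next
      }
      g <- reciprocal_latency_glm(table[idx, , drop = FALSE],
                                  c(regressor_of_interest, nuisance))
      co <- g$coefficients[g$coefficients$term == regressor_of_interest, ]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = sid, split = sp, n = n, fitted = TRUE,
        beta = co$beta, sem = co$sem, t = co$t, p = co$p,
        ci_lower = co$ci_lower, ci_upper = co$ci_upper)
    }
  }
  do.call(rbind, rows)
}

#' Hierarchical polynomial trend test
#'
#' Regresses promptness on an orthogonal polynomial basis of the
#' chosen-frame location and reports, for each degree 1..max_degree, the
#' incremental term's t and p given all lower-degree terms (orthogonality
#' makes the lower-degree estimates invariant to adding higher terms).
#'
#' @param table a trial table.
#' @param max_degree highest polynomial degree (default 3: linear,
#'   quadratic, cubic).
#' @return Tibble with columns `degree`, `beta`, `sem`, `t`, `p`,
#'   `significant` (p < 0.05).
#' @export
polynomial_trend_test <- function(table, max_degree = 3L) {
  loc <- chosen_frame_location(table)
  n_distinct <- length(unique(loc))
  if (n_distinct <= max_degree) {
    stop("only ", n_distinct, " distinct locations; degree ", max_degree,
         " trend untestable", call. = FALSE)
  }
  y <- 1 / table$rt_s
  basis <- stats::poly(loc, degree = max_degree)
  fit <- stats::lm(y ~ basis)
  coefs <- summary(fit)$coefficients[-1L, , drop = FALSE]
  tibble::tibble(degree = seq_len(max_degree), beta = coefs[, 1L],
                 sem = coefs[, 2L], t = coefs[, 3L], p = coefs[, 4L],
                 significant = coefs[, 4L] < 0.05)
}

#' @export
print.toj_glm <- function(x, ...) {
  cat("<toj_glm> reciprocal latency,", x$family, "-", x$n_obs, "trials\n")
  print(x$coefficients)
  invisible(x)
}
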