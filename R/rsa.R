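# Representational similarity analysis of reaction-time patterns.
#
# Videos are divided into equal segments by chosen-frame location; the
# segment-wise mean RTs yield a rank-scaled dissimilarity matrix (RDM)
# that is compared, by bootstrap Spearman correlation, against an
# offset-parameterised family of hypothetical replay models ranging from
# full global compression (Clip 2 replay restarts at the Clip 1 origin)
# to strict forward replay (no reset) and beyond.

#' Segment-wise mean reaction times
#'
#' Divides the normalized chosen-frame location `[0, 1]` into
#' `n_segments` equal bins and averages RT within each. Intended for
#' within-context trials, where the chosen-frame location indexes replay
#' depth.
#'
#' @param table a trial table (typically within-context trials only).
#' @param n_segments number of segments (default 8; 10 and 14 are common
#'   robustness variants).
#' @return A `segment_profile` tibble with columns `segment`, `mean_rt`,
#'   `n`; attribute `n_segments`.
#' @export
segment_profile <- function(table, n_segments = 8L) {
  loc <- chosen_frame_location(table)
  seg <- pmin(floor(loc * n_segments) + 1L, n_segments)
  counts <- tabulate(seg, nbins = n_segments)
  if (any(counts == 0L)) {
    stop("empty segment(s): ", paste(which(counts == 0L), collapse = ", "),
         "; reduce n_segments or supply more trials", call. = FALSE)
  }
  means <- as.numeric(tapply(table$rt_s, factor(seg, seq_len(n_segments)),
                             mean))
  out <- tibble::tibble(segment = seq_len(n_segments), mean_rt = means,
                        n = counts)
  attr(out, "n_segments") <- as.integer(n_segments)
  class(out) <- c("segment_profile", class(out))
  out
}

#' Rank-scaled dissimilarity matrix from a segment profile
#'
#' Pairwise dissimilarity between segments i and j is the Euclidean
#' distance of their scalar mean RTs, `|mean_i - mean_j|`. Off-diagonal
#' entries are then replaced by their rank in the distribution of all
#' upper-triangle elements (average ranks for ties) and linearly scaled to
#' `[0, 1]`; the matrix is mirrored to symmetry with a zero diagonal.
#' When every pairwise distance is tied (flat profile) the scaling is
#' degenerate: all off-diagonal entries are set to 0.5 and the attribute
#' `degenerate` is `TRUE`.
#'
#' @param profile a [segment_profile()] or a bare numeric vector of
#'   segment values.
#' @return An `n x n` matrix of class `rt_rdm`.
#' @export
rdm_from_profile <- function(profile) {
  values <- if (is.numeric(profile)) profile else profile$mean_rt
  n <- length(values)
  d <- abs(outer(values, values, "-"))
  ut <- upper.tri(d)
  raw <- d[ut]
  degenerate <- length(unique(raw)) == 1L
  scaled <- if (degenerate) {
    rep(0.5, length(raw))
  } else {
    r <- rank(raw) # average ranks for ties
    (r - min(r)) / (max(r) - min(r))
  }
  out <- matrix(0, n, n)
  out[ut] <- scaled
  out <- out + t(out)
  structure(out, class = c("rt_rdm", "matrix", "array"),
            degenerate = degenerate)
}

#' Hypothetical replay reaction-time pattern
#'
#' Per-segment value `slope * i + slope * offset * [i >= boundary]`:
#' a line in segment index with a step at the first Clip-2 segment. The
#' offset is expressed in slope-units (one unit = the per-segment RT
#' increment). `offset = 0` is the strict-forward model;
#' `offset = -(boundary_segment - 1)` restarts Clip 2 at the Clip 1
#' origin - the full global-compression model.
#'
#' @param offset step applied from `boundary_segment` onward, in
#'   slope-units.
#' @param n_segments number of segments.
#' @param boundary_segment first segment of Clip 2 (default
#'   `n_segments/2 + 1`).
#' @param slope per-segment increment (arbitrary positive units).
#' @return Numeric vector of hypothetical per-segment RT values.
#' @export
model_rt_pattern <- function(offset = 0, n_segments = 8L,
                             boundary_segment = n_segments / 2 + 1L,
                             slope = 1) {
  stopifnot(slope > 0, boundary_segment >= 2, boundary_segment <= n_segments)
  i <- seq_len(n_segments)
  slope * i + slope * offset * (i >= boundary_segment)
}

#' Offset-parameterised family of replay model RDMs
#'
#' A uniform grid of offsets from `-(boundary_segment - 1)` (full
#' global-compression reset) to `+(boundary_segment - 1)`, with the
#' central model at offset 0 (strict forward). With the defaults (11
#' models, 8 segments, boundary at segment 5) the grid runs -4 to +4 in
#' steps of 0.8: model 1 is the global-compression model, model 6 the
#' strict-forward model.
#'
#' @param n_models odd number of models (default 11).
#' @param n_segments segments per video (default 8).
#' @param boundary_segment first Clip-2 segment.
#' @return List with `offsets` (numeric grid), `patterns` (list of
#'   per-segment values) and `rdms` (list of `rt_rdm`).
#' @export
offset_model_family <- function(n_models = 11L, n_segments = 8L,
                                boundary_segment = n_segments / 2 + 1L) {
  if (n_models %% 2L == 0L) {
    stop("n_models must be odd so the strict-forward model sits at the ",
         "center of the grid", call. = FALSE)
  }
  lim <- boundary_segment - 1
  offsets <- seq(-lim, lim, length.out = n_models)
  patterns <- lapply(offsets, model_rt_pattern, n_segments = n_segments,
                     boundary_segment = boundary_segment)
  rdms <- lapply(patterns, rdm_from_profile)
  list(offsets = offsets, patterns = patterns, rdms = rdms)
}

# Spearman correlation between the upper triangles of two RDMs.
rdm_spearman <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  ut <- upper.tri(a)
  stats::cor(a[ut], b[ut], method = "spearman")
}

#' Correlate a data RDM with a model RDM
#'
#' Builds per-subject segment profiles from the table, averages them into
#' a group RDM, and returns its Spearman correlation (upper triangle) with
#' the model RDM.
#'
#' @param table a trial table (within-context trials).
#' @param model_rdm an `rt_rdm` or plain matrix.
#' @param n_segments segments per video.
#' @return Scalar Spearman correlation.
#' @export
rdm_model_correlation <- function(table, model_rdm, n_segments = 8L) {
  rdm_spearman(group_rdm(table, n_segments), model_rdm)
}

# Average per-subject RDMs into one group RDM.
group_rdm <- function(table, n_segments = 8L) {
  subjects <- split(seq_len(nrow(table)), table$subject_id)
  rdms <- lapply(subjects, function(idx) {
    rdm_from_profile(segment_profile(table[idx, , drop = FALSE], n_segments))
  })
  Reduce(`+`, rdms) / length(rdms)
}

#' Bootstrap Spearman correlation between data and a model RDM
#'
#' Per iteration, trials are resampled with replacement within each
#' subject; per-subject RDMs are rebuilt, averaged into a group RDM, and
#' correlated (Spearman, upper triangle) with the model RDM. Iterations
#' whose resample leaves a segment empty are redrawn (count reported).
#'
#' @param table a trial table (within-context trials).
#' @param model_rdm model RDM.
#' @param n_iter bootstrap iterations (default 100).
#' @param n_segments segments per video.
#' @param seed integer seed.
#' @param unit resampling unit: `"trial"` (within subject; default) or
#'   `"subject"` (resample subjects, for larger cohorts).
#' @return List with `mean_r`, `sem`, `r` (per-iteration vector) and
#'   `n_redrawn`.
#' @export
spearman_model_fit <- function(table, model_rdm, n_iter = 100L,
                               n_segments = 8L, seed = 1L,
                               unit = c("trial", "subject")) {
  unit <- match.arg(unit)
  subjects <- split(seq_len(nrow(table)), table$subject_id)
  loc <- chosen_frame_location(table)
  seg_all <- pmin(floor(loc * n_segments) + 1L, n_segments)
  rt_all <- table$rt_s

  rdm_of <- function(idx) {
    seg <- seg_all[idx]
    counts <- tabulate(seg, nbins = n_segments)
    if (any(counts == 0L)) return(NULL)
    means <- as.numeric(tapply(rt_all[idx], factor(seg, seq_len(n_segments)),
                               mean))
    rdm_from_profile(means)
  }

  withr::with_seed(as.integer(seed), {
    r <- numeric(n_iter)
    n_redrawn <- 0L
    for (it in seq_len(n_iter)) {
      repeat {
        rdms <- if (unit == "trial") {
          lapply(subjects, function(idx) {
            rdm_of(sample(idx, length(idx), replace = TRUE))
          })
        } else {
          picked <- sample(names(subjects), length(subjects), replace = TRUE)
          lapply(picked, function(s) rdm_of(subjects[[s]]))
        }
        if (!any(vapply(rdms, is.null, logical(1)))) break
        n_redrawn <- n_redrawn + 1L
      }
      grp <- Reduce(`+`, rdms) / length(rdms)
      r[it] <- rdm_spearman(grp, model_rdm)
    }
  })
  list(mean_r = mean(r), sem = stats::sd(r) / sqrt(n_iter), r = r,
       n_redrawn = n_redrawn)
}

#' Compare two models' bootstrap correlation distributions
#'
#' Two-sided Wilcoxon signed-rank test on the paired per-iteration
#' correlations, with Benjamini-Hochberg adjustment across a set of such
#' comparisons. If every paired difference is zero the test is degenerate
#' and p = 1.
#'
#' @param rs_a,rs_b equal-length per-iteration correlation vectors (the
#'   `r` element of [spearman_model_fit()]).
#' @return List with `p_value` and `statistic`.
#' @export
compare_models <- function(rs_a, rs_b) {
  stopifnot(length(rs_a) == length(rs_b))
  d <- rs_a - rs_b
  if (all(d == 0)) {
    return(list(p_value = 1, statistic = NA_real_))
  }
  wt <- suppressWarnings(stats::wilcox.test(rs_a, rs_b, paired = TRUE,
                                            alternative = "two.sided"))
  list(p_value = wt$p.value, statistic = unname(wt$statistic))
}

#' Benjamini-Hochberg adjustment of a set of model-comparison p values
#'
#' @param p numeric vector of p values.
#' @return Vector of FDR-adjusted p values.
#' @export
fdr_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Write an RDM as a plain-text matrix file
#' @param rdm an `rt_rdm` or matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rdm <- function(rdm, path) {
  utils::write.table(unclass(rdm), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
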