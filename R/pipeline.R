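# End-to-end orchestration: filter -> condition labels -> LATER comparison
# -> RSA -> GLM/trends -> behavioral metrics, from a YAML/JSON config or an
# in-memory list, writing tidy tables and JSON summaries plus a manifest.

#' Run the full TOJ replay analysis pipeline
#'
#' The configuration names either an input trial table
#' (`input$trials`: CSV path) or a synthetic generator
#' (`generator`: fields `seed`, `n_subjects`, plus any [design_spec()] or
#' [generator_params()] overrides), analysis toggles (`stages`, default
#' all of `filter`, `later`, `rsa`, `glm`, `metrics`), the RSA segment
#' counts (`segments`, default 8), and an output directory (`out_dir`).
#' Every stage writes its outputs before the next starts, so a failing
#' stage leaves earlier results on disk; the error names the stage. A
#' `manifest.json` records the config, seed and package version.
#'
#' @param config list, or path to a YAML/JSON config file.
#' @return Invisibly, a list with per-stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (is.null(config$out_dir)) {
    stop("config error: out_dir is required", call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("filter", "later", "rsa", "glm", "metrics")
  segments <- as.integer(config$segments %||% 8L)
  seed <- as.integer(config$seed %||% config$generator$seed %||% 1L)

  table <- if (!is.null(config$input$trials)) {
    load_trials(config$input$trials)
  } else if (!is.null(config$generator)) {
    gen <- config$generator
    spec <- do.call(design_spec,
                    gen[intersect(names(gen), names(formals(design_spec)))])
    params <- do.call(generator_params,
                      gen[intersect(names(gen),
                                    names(formals(generator_params)))])
    n_subjects <- gen$n_subjects %||% 1L
    if (n_subjects > 1L) {
      generate_cohort(n_subjects, spec, params, seed = seed)
    } else {
      generate_dataset(spec, params, seed = seed)
    }
  } else {
    stop("config error: provide input$trials or a generator block",
         call. = FALSE)
  }

  results <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if ("filter" %in% stages) {
    table <- run_stage("filter", filter_rt(table))
    write_trials(table, file.path(config$out_dir, "trials_filtered.csv"))
    results$filter_log <- filter_log(table)
  }

  within <- table[table$boundary_condition != "across", , drop = FALSE]
  across <- table[table$boundary_condition == "across", , drop = FALSE]

  if ("later" %in% stages) {
    results$later <- run_stage("later", fit_later(
      list(within = within$rt_s, across = across$rt_s)))
    write_later_json(results$later,
                     file.path(config$out_dir, "later_comparison.json"))
  }

  if ("rsa" %in% stages) {
    results$rsa <- run_stage("rsa", lapply(segments, function(ns) {
      fam <- offset_model_family(n_segments = ns)
      strict <- fam$rdms[[(length(fam$rdms) + 1L) %/% 2L]]
      reset <- fam$rdms[[1L]]
      fit_strict <- spearman_model_fit(within, strict, n_segments = ns,
                                       seed = seed)
      fit_reset <- spearman_model_fit(within, reset, n_segments = ns,
                                      seed = seed)
      cmp <- compare_models(fit_strict$r, fit_reset$r)
      sweep_r <- vapply(fam$rdms, function(m) {
        rdm_model_correlation(within, m, n_segments = ns)
      }, numeric(1))
      write_rdm(group_rdm(within, ns),
                file.path(config$out_dir,
                          sprintf("rdm_data_%dseg.txt", ns)))
      list(n_segments = ns, strict_forward = fit_strict[c("mean_r", "sem")],
           global_compression = fit_reset[c("mean_r", "sem")],
           wilcoxon_p = cmp$p_value, offsets = fam$offsets,
           sweep_r = sweep_r,
           best_offset = fam$offsets[which.max(sweep_r)])
    }))
    jsonlite::write_json(results$rsa,
                         file.path(config$out_dir, "rsa_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("glm" %in% stages) {
    regs <- c("chosen_frame_location", "temporal_similarity", "td_level",
              "play_order", "category", "touch_side", "exposure",
              "elapsed_time_s", "correct")
    results$glm <- run_stage("glm", reciprocal_latency_glm(within, regs))
    utils::write.csv(as.data.frame(results$glm$coefficients),
                     file.path(config$out_dir, "glm_within.csv"),
                     row.names = FALSE)
    results$slopes <- run_stage("glm", slope_test(
      within, "chosen_frame_location",
      nuisance = c("td_level", "play_order", "exposure")))
    utils::write.csv(as.data.frame(results$slopes),
                     file.path(config$out_dir, "slopes_by_subject.csv"),
                     row.names = FALSE)
    results$trends <- run_stage("glm", polynomial_trend_test(within))
  }

  if ("metrics" %in% stages) {
    results$metrics <- run_stage("metrics", {
      span <- estimate_rt_span(table)
      out <- list(compression = compression_factor(span), rt_span_s = span,
                  inverse_efficiency = inverse_efficiency(table)[
                    c("F", "df", "p_value")])
      # group contrasts need at least two subjects
      if (length(unique(table$subject_id)) >= 2L) {
        out$clip_contrast <- clip_rt_contrast(table)[
          c("mean_rt_clip1", "mean_rt_clip2", "t", "p_value")]
        out$trial_type_anova <- trial_type_anova(table)[
          c("F", "df", "p_value")]
      }
      out
    })
    jsonlite::write_json(results$metrics,
                         file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package_version =
      as.character(utils::packageVersion("tojreplay")),
    seed = seed, segments = segments, stages = stages,
    config = config
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
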