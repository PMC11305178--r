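#' Run the full analysis pipeline
#'
#' End-to-end analysis of a trial table: trial- and participant-level
#' exclusion, per participant-by-condition MAP fits, AICc model
#' comparison, per-parameter one-way repeated-measures ANOVAs over SOA,
#' and (when the table pools SOA ranges from more than one experiment) a
#' segmented regression of each parameter against SOA — one breakpoint
#' for `sd`, `beta1` and `beta2`, two for the target report rate and `g`,
#' whose SOA functions are non-monotonic within the masking range.
#'
#' @param trials trial table (see [read_trials()]), or `NULL` to simulate
#'   one from `config`.
#' @param config optional `maskmix_config`; used when `trials` is `NULL`.
#' @param models model names fitted per cell; the first is the primary
#'   model whose parameters feed the ANOVAs and segmented fits. Model
#'   comparison is run when more than one is given.
#' @param exclusion_threshold overall-performance cut-off in `(0, 1)`.
#' @param piecewise `"auto"` (segmented fits when > 5 distinct SOAs are
#'   present), `TRUE` or `FALSE`.
#' @param n_starts random starts per fit.
#' @param seed integer seed controlling fitting starts (and simulation if
#'   `config` is used without a seed of its own).
#' @param outdir optional directory; when given, writes `fits.csv`,
#'   `comparison.csv`, `anova.csv`, `segmented.csv` and `manifest.json`.
#' @return list with `summaries`, `fits`, `comparison`, `anova`,
#'   `segmented`, `manifest`.
#' @export
run_pipeline <- function(trials = NULL, config = NULL,
                         models = "two_misreport",
                         exclusion_threshold = 0.55,
                         piecewise = "auto",
                         n_starts = 20, seed = 1L, outdir = NULL) {
  stopifnot(length(models) >= 1, exclusion_threshold > 0,
            exclusion_threshold < 1)
  if (is.null(trials)) {
    if (is.null(config)) stop("supply trials or a generator config", call. = FALSE)
    trials <- generate_experiment(config)$trials
  }

  summaries <- participant_summary(trials, exclusion_threshold)
  keep_ids <- exclude_participants(summaries, exclusion_threshold)
  trials <- trials[trials$participant_id %in% keep_ids, , drop = FALSE]
  kept <- compute_errors(exclude_trials(trials)$kept)

  cells <- split(kept, list(kept$participant_id, kept$condition), drop = TRUE)
  primary <- models[1]
  fit_rows <- list(); cmp_rows <- list()
  for (nm in names(cells)) {
    cell <- cells[[nm]]
    pid <- cell$participant_id[1]; cond <- cell$condition[1]
    cell_seed <- (seed + 7L * as.integer(factor(pid, levels = keep_ids)) +
                    131L * match(cond, unique(kept$condition))) %%
                 .Machine$integer.max
    base_cell <- is_baseline(cond)
    cell_models <- if (base_cell) "standard" else models
    for (m in cell_models) {
      f <- map_fit(m, cell, n_starts = n_starts, seed = cell_seed)
      fit_rows[[length(fit_rows) + 1L]] <- data.frame(
        participant_id = pid, condition = cond, model = m,
        g = f$params$g, beta1 = f$params$beta1, beta2 = f$params$beta2,
        sd = f$params$sd, mu = f$params$mu,
        target_report_rate = target_report_rate(f$params),
        loglik = f$loglik, aicc = f$aicc, n_trials = f$n_trials,
        converged = f$converged)
    }
  }
  fits <- do.call(rbind, fit_rows)

  comparison <- NULL
  if (length(models) > 1) {
    masked <- fits[fits$model %in% models & !is_baseline(fits$condition), ]
    ref <- masked[masked$model == primary,
                  c("participant_id", "condition", "aicc")]
    names(ref)[3] <- "aicc_ref"
    masked <- merge(masked, ref, by = c("participant_id", "condition"))
    masked$delta_aicc <- masked$aicc - masked$aicc_ref
    comparison <- stats::aggregate(delta_aicc ~ model, data = masked, FUN = mean)
    comparison$n_cells <- stats::aggregate(delta_aicc ~ model, data = masked,
                                           FUN = length)$delta_aicc
  }

  pf <- fits[fits$model == primary & !is_baseline(fits$condition), ]
  pf$soa <- as.numeric(pf$condition)
  params <- c("target_report_rate", "sd", "g", "beta1", "beta2")
  anova_tab <- do.call(rbind, lapply(params, function(par) {
    d <- data.frame(participant = pf$participant_id, level = pf$soa,
                    value = pf[[par]])
    complete <- all(table(d$participant, d$level) == 1)
    if (!complete) return(NULL)
    out <- rm_anova_oneway(d)
    out$parameter <- par
    out
  }))

  do_piecewise <- isTRUE(piecewise) ||
    (identical(piecewise, "auto") && length(unique(pf$soa)) > 5)
  segmented <- NULL
  if (do_piecewise) {
    segmented <- do.call(rbind, lapply(params, function(par) {
      nb <- if (par %in% c("target_report_rate", "g")) 2L else 1L
      sf <- fit_piecewise(pf$soa, pf[[par]], n_break = nb)
      ov <- overall_model_test(sf); sl <- slope_difference_test(sf)
      data.frame(parameter = par, n_break = nb,
                 breakpoints = paste(sf$breakpoints, collapse = ";"),
                 slopes = paste(sprintf("%.5f", sf$slopes$slope), collapse = ";"),
                 slope_ses = paste(sprintf("%.5f", sf$slopes$se), collapse = ";"),
                 overall_F = ov$F, overall_df1 = ov$df1, overall_df2 = ov$df2,
                 overall_p = ov$p,
                 slope_diff_F = sl$F, slope_diff_df1 = sl$df1,
                 slope_diff_df2 = sl$df2, slope_diff_p = sl$p)
    }))
  }

  manifest <- list(
    seed = seed, models = models, primary_model = primary,
    exclusion_threshold = exclusion_threshold, n_starts = n_starts,
    n_participants_included = length(keep_ids),
    package_version = as.character(utils::packageVersion("maskmix")),
    conventions = list(angles = "degrees, full 360-degree circle",
                       sd = "circular sd of the von Mises component, degrees",
                       bias = "mu shifts the target component only"))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fits, file.path(outdir, "fits.csv"), row.names = FALSE)
    if (!is.null(comparison))
      utils::write.csv(comparison, file.path(outdir, "comparison.csv"),
                       row.names = FALSE)
    if (!is.null(anova_tab))
      utils::write.csv(anova_tab, file.path(outdir, "anova.csv"),
                       row.names = FALSE)
    if (!is.null(segmented))
      utils::write.csv(segmented, file.path(outdir, "segmented.csv"),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  list(summaries = summaries, fits = fits, comparison = comparison,
       anova = anova_tab, segmented = segmented, manifest = manifest)
}

#' Simulate an experiment and write its trial and truth tables
#'
#' Thin wrapper over [generate_experiment()] that writes the trial CSV
#' (in the [read_trials()] schema) and the ground-truth parameter CSV.
#'
#' @param config a `maskmix_config`.
#' @param outdir output directory.
#' @return invisibly, the list from [generate_experiment()].
#' @export
simulate_experiment <- function(config, outdir) {
  sim <- generate_experiment(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$trials, file.path(outdir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$truth, file.path(outdir, "truth.csv"),
                   row.names = FALSE)
  invisible(sim)
}
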