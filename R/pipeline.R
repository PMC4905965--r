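#' Run the full analysis pipeline
#'
#' Ties the stages together: obtain a panel (simulate the packaged
#' scenario or read a manifest), censor and standardize, build lagged
#' cohort covariances, fit a prior model and/or run the exploratory
#' search, analyze cohort trends, and write a single JSON report plus
#' TSV tables.  Deterministic for a fixed seed.
#'
#' @param config a list (or path to a JSON file holding one) with
#'   entries: `seed` (integer); `out_dir`; `panel` (manifest path, or
#'   `NULL` to simulate); `scenario` (list `subjects_per_cohort`,
#'   `timepoints_per_subject` for the simulated scenario); `censor`
#'   (logical); `prior_model` (model JSON path or `NULL`); `search`
#'   (list of [search_settings()] overrides, or `NULL` to skip);
#'   `cohort_axis`; `alpha`.
#' @return The report list, invisibly; the same content is written to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  defaults <- list(seed = 1L, out_dir = "usemnet-run", panel = NULL,
                   scenario = list(subjects_per_cohort = 20L,
                                   timepoints_per_subject = 600L),
                   censor = TRUE, prior_model = NULL,
                   search = list(), cohort_axis = NULL, alpha = 0.05)
  config <- utils::modifyList(defaults, config)
  if (!is.null(config$panel) && !file.exists(config$panel))
    stop("panel manifest not found: ", config$panel)
  if (!is.null(config$prior_model) && !file.exists(config$prior_model))
    stop("prior model not found: ", config$prior_model)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = config)

  panel <- if (is.null(config$panel)) {
    sc <- default_dmn_scenario(
      seed = config$seed,
      subjects_per_cohort = config$scenario$subjects_per_cohort,
      timepoints_per_subject = config$scenario$timepoints_per_subject)
    simulate_panel(sc)
  } else read_panel(config$panel)
  prep <- prepare_panel(panel, censor = config$censor)
  report$prep <- list(
    n_subjects = length(panel$subjects),
    n_censored = sum(!unlist(prep$panel$mask)),
    n_per_cohort = as.list(prep$covs$n_per_cohort),
    n_total = prep$covs$n_total)

  fit_for_trends <- NULL
  if (!is.null(config$prior_model)) {
    spec <- read_model_json(config$prior_model)
    prior <- fit_prior_model(spec$model, prep$covs)
    report$prior <- list(
      pooled = fit_report(prior$pooled),
      per_cohort = fit_report(prior$per_cohort))
    fit_for_trends <- prior$per_cohort
  }
  if (!is.null(config$search)) {
    st <- do.call(search_settings, config$search)
    sr <- explore(panel$node_names, prep$covs, st)
    utils::write.table(sr$trace, file.path(config$out_dir, "search_trace.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_model_json(sr$model, file.path(config$out_dir, "search_model.json"))
    report$search <- list(
      stop_reason = sr$stop_reason,
      n_edges = nrow(sr$model$edges),
      edges = paste(sr$model$edges$source, "->", sr$model$edges$target),
      fit = fit_report(sr$fit))
    fit_for_trends <- sr$fit
    if (!is.null(config$prior_model)) {
      spec <- read_model_json(config$prior_model)
      ov <- edge_overlap_probability(spec$model$edges, sr$model$edges,
                                     length(panel$node_names))
      report$overlap <- ov
    }
  }
  if (!is.null(fit_for_trends)) {
    tr <- decade_trends(fit_for_trends, config$cohort_axis, config$alpha)
    utils::write.table(tr, file.path(config$out_dir, "trends.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pr <- pair_by_receiver(tr)
    report$trends <- list(
      n_rising = sum(tr$class == "rising"),
      n_falling = sum(tr$class == "falling"),
      n_flat = sum(tr$class == "flat"),
      paired_receivers = pr$paired,
      unpaired_receivers = pr$unpaired)
  }
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10,
                       null = "null")
  invisible(report)
}

fit_report <- function(fit) {
  ix <- fit$indices
  list(chi_square = fit$chisq, df = fit$df, q = fit$q,
       n_per_cohort = as.list(fit$n_per_cohort),
       rmsea = ix$rmsea, rmsea_lo90 = ix$rmsea_lo90,
       rmsea_hi90 = ix$rmsea_hi90, bcc = ix$bcc, cfi = ix$cfi,
       per_cohort_rmsea_hi90 = ix$per_cohort$rmsea_hi90)
}
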