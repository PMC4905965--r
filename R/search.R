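#' Settings for the exploratory specification search
#'
#' @param rmsea_threshold stop once the per-cohort RMSEA 90% upper bound
#'   is at or below this value for at least `min_cohorts` cohorts.
#' @param min_cohorts cohorts required to satisfy the RMSEA rule;
#'   `NULL` means at least half (`ceiling(G / 2)`).
#' @param max_edges hard cap on accepted edges (overfitting guard).
#' @param top_m candidate pairs carried to the fitting stage per iteration.
#' @param mi_aggregate how a candidate edge aggregates its three path MIs.
#' @param control optimizer settings, see [usem_control()].
#' @return List of search settings.
#' @export
search_settings <- function(rmsea_threshold = 0.08, min_cohorts = NULL,
                            max_edges = 25L, top_m = 5L,
                            mi_aggregate = c("sum", "max"),
                            control = usem_control()) {
  list(rmsea_threshold = rmsea_threshold, min_cohorts = min_cohorts,
       max_edges = max_edges, top_m = top_m,
       mi_aggregate = match.arg(mi_aggregate), control = control)
}

#' Exploratory specification search over connections
#'
#' Starts from the null model (only each node's unlagged variable loading
#' on its lagged copy) and grows the edge set stepwise.  Each iteration:
#' modification indices are computed for every unconnected node pair, the
#' top candidates are refitted as full three-path additions in both
#' orientations, and the single addition with the lowest Browne-Cudeck
#' criterion is accepted (ties broken by lower RMSEA, then lexicographic
#' edge label).  The search stops when the per-cohort RMSEA 90% upper
#' bound is at or below the threshold for at least half the cohorts, when
#' no candidate improves the BCC, or at the edge cap.
#'
#' @param nodes character vector of node labels.
#' @param covs cohort covariances from [cohort_covariances()].
#' @param settings see [search_settings()].
#' @return List with the final `model`, its `fit`, a `trace` data frame
#'   mirroring the iteration protocol (iteration, candidate, tested
#'   orientation fit statistics, MI, acceptance) and `stop_reason`.
#' @export
explore <- function(nodes, covs, settings = search_settings()) {
  G <- length(covs$S)
  min_cohorts <- settings$min_cohorts
  if (is.null(min_cohorts)) min_cohorts <- ceiling(G / 2)
  Ns <- as.numeric(covs$n_per_cohort)
  n_total <- sum(Ns)
  model <- build_usem(nodes)
  fit <- fit_ml(model, covs, grouping = "free",
                control = settings$control, se = FALSE, ci = TRUE)
  trace <- list()
  it <- 0L
  stop_reason <- NULL
  repeat {
    it <- it + 1L
    satisfied <- sum(fit$indices$per_cohort$rmsea_hi90 <=
                       settings$rmsea_threshold)
    if (satisfied >= min_cohorts) { stop_reason <- "rmsea"; break }
    if (nrow(model$edges) >= settings$max_edges) {
      stop_reason <- "max_edges"; break
    }
    mi_paths <- modification_indices(fit, covs)
    if (nrow(mi_paths) == 0) { stop_reason <- "saturated"; break }
    mi_edges <- aggregate_mi(mi_paths, settings$mi_aggregate)
    pair_key <- apply(cbind(mi_edges$source, mi_edges$target), 1,
                      function(x) paste(sort(x), collapse = "|"))
    pair_mi <- tapply(mi_edges$mi, pair_key, max)
    top_pairs <- names(sort(pair_mi, decreasing = TRUE))
    top_pairs <- top_pairs[seq_len(min(settings$top_m, length(top_pairs)))]
    best <- NULL
    for (pk in top_pairs) {
      ends <- strsplit(pk, "|", fixed = TRUE)[[1]]
      for (dir in 1:2) {
        s <- ends[dir]; t <- ends[3 - dir]
        cand_model <- build_usem(nodes, rbind(
          model$edges,
          data.frame(source = s, target = t, bidirectional = FALSE)))
        starts <- lapply(fit$theta, function(th)
          insert_edge_start(th, nrow(model$edges) + sum(model$edges$bidirectional),
                            length(nodes), settings$control$start_path))
        cfit <- fit_ml(cand_model, covs, grouping = "free",
                       control = settings$control, starts = starts,
                       se = FALSE, ci = FALSE)
        cand_mi <- mi_edges$mi[mi_edges$source == s & mi_edges$target == t]
        trace[[length(trace) + 1L]] <- data.frame(
          iteration = it, candidate = paste(s, "->", t),
          chisq = cfit$chisq, df = cfit$df,
          rmsea = cfit$indices$rmsea, bcc = cfit$indices$bcc,
          mi = if (length(cand_mi)) cand_mi else NA_real_,
          accepted = FALSE, stringsAsFactors = FALSE)
        better <- is.null(best) ||
          cfit$indices$bcc < best$fit$indices$bcc ||
          (cfit$indices$bcc == best$fit$indices$bcc &&
             (cfit$indices$rmsea < best$fit$indices$rmsea ||
                (cfit$indices$rmsea == best$fit$indices$rmsea &&
                   paste(s, "->", t) < best$label)))
        if (better)
          best <- list(model = cand_model, fit = cfit,
                       label = paste(s, "->", t),
                       row = length(trace))
      }
    }
    if (is.null(best) || best$fit$indices$bcc >= fit$indices$bcc) {
      stop_reason <- "no_bcc_improvement"; break
    }
    trace[[best$row]]$accepted <- TRUE
    model <- best$model
    fit <- best$fit
    fit$indices <- fit_indices(fit, covs, ci = TRUE)
  }
  fit <- fit_ml(model, covs, grouping = "free", control = settings$control)
  trace_df <- if (length(trace)) do.call(rbind, trace) else
    data.frame(iteration = integer(0), candidate = character(0),
               chisq = numeric(0), df = integer(0), rmsea = numeric(0),
               bcc = numeric(0), mi = numeric(0), accepted = logical(0))
  structure(list(model = model, fit = fit, trace = trace_df,
                 stop_reason = stop_reason,
                 settings = settings), class = "usem_search")
}

# Expand a parent parameter vector to a model with one appended edge,
# starting the three new paths at `start_path`.
insert_edge_start <- function(theta, E_parent, n, start_path) {
  E <- E_parent
  c(theta[seq_len(E)], start_path,
    theta[E + seq_len(E)], start_path,
    theta[2 * E + seq_len(E)], start_path,
    theta[(3 * E + 1):length(theta)])
}

#' @export
print.usem_search <- function(x, ...) {
  acc <- x$trace[x$trace$accepted, ]
  cat(sprintf("usem_search: %d edges accepted, stopped on '%s'\n",
              nrow(acc), x$stop_reason))
  if (nrow(acc)) print(acc[, c("iteration", "candidate", "chisq", "df",
                               "rmsea", "bcc")], row.names = FALSE)
  invisible(x)
}

#' Fit a prior connectivity model pooled and per cohort
#'
#' Assesses a model specified a priori (for example a meta-analytically
#' derived edge set) both as a multi-group fit with per-cohort free
#' parameters and as an equality-constrained pooled fit, for side-by-side
#' reporting against an exploratory model.
#'
#' @param model a `usem_model`.
#' @param covs cohort covariances.
#' @param control optimizer settings.
#' @return List with `per_cohort` and `pooled` `usem_fit` objects.
#' @export
fit_prior_model <- function(model, covs, control = usem_control()) {
  list(per_cohort = fit_ml(model, covs, grouping = "free", control = control),
       pooled = fit_ml(model, covs, grouping = "equal", control = control))
}
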