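#' Censor multi-ROI spike artifacts
#'
#' Marks as censored every time point whose point-to-point signal change
#' (absolute first difference, measured in units of the subject's per-ROI
#' standard deviation over the full series) meets any rule of a threshold
#' ladder: by default more than 7 SDs across at least 2 ROIs, 6 SDs across
#' 3, 5 SDs across 4, 4 SDs across 5, or 3 SDs across 6 ROIs.  A large
#' jump censors the point it lands on; because the following difference is
#' usually also large, an isolated spike censors the spiked point and its
#' successor, whereas a level shift censors only the transition point.
#' The data themselves are never altered, only the masks.
#'
#' @param panel a `usem_panel`.
#' @param ladder two-column matrix of `(sd_threshold, min_rois)` rules.
#' @param deviation `"difference"` (default) measures changes between
#'   consecutive time points; `"mean"` measures deviation from the series
#'   mean.
#' @return The panel with updated censoring masks.
#' @export
censor_spikes <- function(panel,
                          ladder = cbind(sd = c(7, 6, 5, 4, 3),
                                         rois = c(2, 3, 4, 5, 6)),
                          deviation = c("difference", "mean")) {
  deviation <- match.arg(deviation)
  for (i in seq_along(panel$subjects)) {
    y <- panel$subjects[[i]]
    if (nrow(y) < 2) stop("subject ", panel$meta$id[i], ": need >= 2 time points")
    sds <- apply(y, 2, stats::sd)
    if (any(sds == 0))
      stop("subject ", panel$meta$id[i], ": constant (zero SD) ROI series: ",
           paste(colnames(y)[sds == 0], collapse = ", "))
    if (deviation == "difference") {
      dev <- abs(diff(y)) / rep(sds, each = nrow(y) - 1)
      hit_t <- seq(2, nrow(y))            # row t of diff is change into point t
    } else {
      dev <- abs(sweep(y, 2, colMeans(y))) / rep(sds, each = nrow(y))
      hit_t <- seq_len(nrow(y))
    }
    bad <- rep(FALSE, nrow(dev))
    for (r in seq_len(nrow(ladder)))
      bad <- bad | rowSums(dev > ladder[r, 1]) >= ladder[r, 2]
    m <- panel$mask[[i]]
    m[hit_t[bad]] <- FALSE
    panel$mask[[i]] <- m
  }
  panel
}

#' Standardize each subject-by-ROI series
#'
#' Centers and scales every subject x ROI series to mean 0 and variance 1
#' over its uncensored time points.  Censored points are transformed with
#' the same affine map so downstream steps see consistent values, but they
#' never enter the mean/variance computation.
#'
#' @param panel a `usem_panel`.
#' @param divisor `"n-1"` (default, sample variance) or `"n"` (population
#'   variance).  The choice is a pure rescaling and is immaterial to every
#'   covariance-structure result downstream.
#' @return The standardized panel.
#' @export
standardize_panel <- function(panel, divisor = c("n-1", "n")) {
  divisor <- match.arg(divisor)
  for (i in seq_along(panel$subjects)) {
    y <- panel$subjects[[i]]
    keep <- panel$mask[[i]]
    if (sum(keep) < 2)
      stop("subject ", panel$meta$id[i], ": fewer than 2 uncensored time points")
    mu <- colMeans(y[keep, , drop = FALSE])
    v <- apply(y[keep, , drop = FALSE], 2, stats::var)
    if (divisor == "n") v <- v * (sum(keep) - 1) / sum(keep)
    if (any(v == 0))
      stop("subject ", panel$meta$id[i], ": zero-variance ROI series: ",
           paste(colnames(y)[v == 0], collapse = ", "))
    panel$subjects[[i]] <- sweep(sweep(y, 2, mu), 2, sqrt(v), "/")
  }
  panel
}

#' Build the lagged two-block dataset
#'
#' For each subject, pairs every uncensored time point with its uncensored
#' successor: the pair contributes one observation row
#' `(x_t, x_{t+1})` over `2 * n_nodes` variables (unlagged block first).
#' Pairs never span a censored point or a subject boundary.
#'
#' @param panel a standardized `usem_panel`.
#' @return A `usem_lagged` object: `rows` (list of per-subject observation
#'   matrices), `meta`, `node_names`, `n_per_cohort` (named vector
#'   \eqn{N^{(g)}}) and `n_total`.
#' @export
build_lagged <- function(panel) {
  n <- length(panel$node_names)
  rows <- vector("list", length(panel$subjects))
  for (i in seq_along(panel$subjects)) {
    y <- panel$subjects[[i]]
    keep <- panel$mask[[i]]
    ok <- which(keep[-length(keep)] & keep[-1])
    rows[[i]] <- cbind(y[ok, , drop = FALSE], y[ok + 1, , drop = FALSE])
    colnames(rows[[i]]) <- c(panel$node_names, paste0(panel$node_names, "_lag"))
  }
  per_subj <- vapply(rows, nrow, 0L)
  n_per_cohort <- tapply(per_subj, panel$meta$cohort, sum)
  structure(list(rows = rows, meta = panel$meta,
                 node_names = panel$node_names,
                 n_per_cohort = c(n_per_cohort),
                 n_total = sum(per_subj)), class = "usem_lagged")
}

#' Assess autoregressive order by incremental variance explained
#'
#' Fits successively higher-order AR(k) models per ROI by within-subject
#' least squares (pooled across subjects) and reports the incremental
#' proportion of variance explained by each added lag, `k = 1..max_lag`.
#'
#' @param panel a `usem_panel` (standardization recommended).
#' @param max_lag highest lag fitted.
#' @return Matrix of incremental variance explained, ROIs x lags.
#' @export
assess_ar_order <- function(panel, max_lag = 5L) {
  stopifnot(max_lag >= 1)
  shortest <- min(vapply(panel$subjects, nrow, 0L))
  if (max_lag >= shortest)
    stop("max_lag (", max_lag, ") must be below the shortest series length (",
         shortest, ")")
  n <- length(panel$node_names)
  out <- matrix(NA_real_, n, max_lag,
                dimnames = list(panel$node_names, paste0("lag", seq_len(max_lag))))
  for (j in seq_len(n)) {
    resp <- list(); preds <- list()
    for (i in seq_along(panel$subjects)) {
      x <- panel$subjects[[i]][, j]
      Tn <- length(x)
      t0 <- seq(max_lag + 1, Tn)
      resp[[i]] <- x[t0]
      preds[[i]] <- vapply(seq_len(max_lag), function(k) x[t0 - k],
                           numeric(length(t0)))
    }
    y <- unlist(resp)
    X <- do.call(rbind, preds)
    tss <- sum((y - mean(y))^2)
    prev <- 0
    for (k in seq_len(max_lag)) {
      fit <- stats::lm.fit(cbind(1, X[, seq_len(k), drop = FALSE]), y)
      r2 <- 1 - sum(fit$residuals^2) / tss
      out[j, k] <- r2 - prev
      prev <- r2
    }
  }
  out
}

#' Per-cohort sample covariances of the lagged dataset
#'
#' Stacks each cohort's observation rows and computes the sample
#' covariance over the `2 * n_nodes` variables with divisor
#' \eqn{N^{(g)} - 1}.
#'
#' @param lagged a `usem_lagged` from [build_lagged()].
#' @return A `usem_covs` object: `S` (list of covariance matrices by
#'   cohort), `n_per_cohort`, `n_total`, `node_names`.
#' @export
cohort_covariances <- function(lagged) {
  cohorts <- sort(unique(lagged$meta$cohort))
  p <- 2 * length(lagged$node_names)
  S <- lapply(cohorts, function(g) {
    rows <- do.call(rbind, lagged$rows[lagged$meta$cohort == g])
    if (nrow(rows) < 2) stop("cohort ", g, ": no usable lagged pairs")
    if (nrow(rows) < p + 1)
      warning("cohort ", g, ": fewer observations (", nrow(rows),
              ") than variables + 1 (", p + 1, "); covariance may be singular")
    stats::cov(rows)
  })
  names(S) <- cohorts
  structure(list(S = S,
                 n_per_cohort = lagged$n_per_cohort[as.character(cohorts)],
                 n_total = lagged$n_total,
                 node_names = lagged$node_names), class = "usem_covs")
}

#' Run censoring, standardization, lagging and covariance assembly
#'
#' Convenience wrapper chaining [censor_spikes()], [standardize_panel()],
#' [build_lagged()] and [cohort_covariances()].
#'
#' @param panel a raw `usem_panel`.
#' @param censor apply the spike-censoring filter first.
#' @param divisor standardization divisor, see [standardize_panel()].
#' @return A list with the processed `panel`, the `lagged` dataset and the
#'   cohort covariances `covs`.
#' @export
prepare_panel <- function(panel, censor = TRUE, divisor = "n-1") {
  if (censor) panel <- censor_spikes(panel)
  panel <- standardize_panel(panel, divisor = divisor)
  lagged <- build_lagged(panel)
  list(panel = panel, lagged = lagged, covs = cohort_covariances(lagged))
}
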