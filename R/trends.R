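#' Cohort trends of path coefficients
#'
#' Correlates each edge's lagged-to-lagged path coefficient (the most
#' informative effect: the influence of one region on another after
#' autocorrelation and delayed effects are accounted for) across cohorts
#' with the cohort axis, and classifies each edge as rising, falling or
#' flat by a two-sided t test with `G - 2` degrees of freedom.
#'
#' Pearson's r is invariant under affine rescaling of the axis, so cohort
#' index and cohort midpoint age give identical values.
#'
#' @param fit a `usem_fit` with per-cohort free parameters, or a
#'   coefficient table as returned by [path_coefficients()].
#' @param cohort_axis numeric axis (default `1..G`).
#' @param alpha two-sided significance level for the trend class.
#' @return A `usem_trends` data frame: `source`, `target`, per-cohort
#'   coefficient columns, `r`, `p`, `class` (`rising`/`falling`/`flat`);
#'   constant coefficient vectors get `r = NA` and class `flat`.
#' @export
decade_trends <- function(fit, cohort_axis = NULL, alpha = 0.05) {
  co <- if (inherits(fit, "usem_fit")) {
    if (fit$grouping != "free")
      stop("trend analysis needs per-cohort free parameters")
    path_coefficients(fit, "lagged")
  } else fit
  cmat <- as.matrix(co[, grep("^cohort_", names(co)), drop = FALSE])
  G <- ncol(cmat)
  if (G < 3) stop("need at least 3 cohorts for a trend")
  if (is.null(cohort_axis)) cohort_axis <- seq_len(G)
  stopifnot(length(cohort_axis) == G)
  r <- p <- rep(NA_real_, nrow(cmat))
  for (i in seq_len(nrow(cmat))) {
    v <- cmat[i, ]
    if (stats::sd(v) == 0) next
    r[i] <- stats::cor(v, cohort_axis)
    tt <- r[i] * sqrt((G - 2) / (1 - r[i]^2))
    p[i] <- 2 * stats::pt(-abs(tt), G - 2)
  }
  cls <- ifelse(is.na(r) | p >= alpha, "flat",
                ifelse(r > 0, "rising", "falling"))
  out <- data.frame(source = co$source, target = co$target,
                    cmat, r = r, p = p, class = cls,
                    stringsAsFactors = FALSE)
  class(out) <- c("usem_trends", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "cohort_axis") <- cohort_axis
  out
}

#' Pair significant trend edges by receiving node
#'
#' Groups rising/falling edges by their target and reports which nodes
#' receive at least one rising and one falling input (paired) and which
#' receive significant inputs of one sign only (unpaired).
#'
#' @param trends a `usem_trends` table.
#' @return List with `paired` (character vector of receiver nodes),
#'   `unpaired`, and the underlying `by_receiver` data frame.
#' @export
pair_by_receiver <- function(trends) {
  sig <- trends[trends$class != "flat", ]
  if (nrow(sig) == 0)
    return(list(paired = character(0), unpaired = character(0),
                by_receiver = data.frame(receiver = character(0),
                                         n_rising = integer(0),
                                         n_falling = integer(0))))
  tab <- do.call(rbind, lapply(split(sig, sig$target), function(d)
    data.frame(receiver = d$target[1],
               n_rising = sum(d$class == "rising"),
               n_falling = sum(d$class == "falling"),
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  list(paired = tab$receiver[tab$n_rising > 0 & tab$n_falling > 0],
       unpaired = tab$receiver[tab$n_rising == 0 | tab$n_falling == 0],
       by_receiver = tab)
}

#' Sex-split cohort trends
#'
#' Refits the model separately to each sex's cohort covariances and
#' returns per-sex trend tables plus a per-edge divergence flag marking
#' edges whose trend is significant in exactly one sex.
#'
#' @param panel a raw `usem_panel` with sex metadata.
#' @param model the `usem_model` to fit.
#' @param cohort_axis,alpha as in [decade_trends()].
#' @param censor apply spike censoring during preparation.
#' @param control optimizer settings.
#' @return List of per-sex `usem_trends` tables and `divergent` (data
#'   frame of edges with each sex's class).
#' @export
sex_split_trends <- function(panel, model, cohort_axis = NULL, alpha = 0.05,
                             censor = TRUE, control = usem_control()) {
  sexes <- sort(unique(panel$meta$sex))
  for (g in unique(panel$meta$cohort))
    if (length(unique(panel$meta$sex[panel$meta$cohort == g])) < length(sexes))
      stop("cohort ", g, " is missing a sex level")
  tabs <- lapply(sexes, function(sx) {
    keep <- panel$meta$sex == sx
    sub <- new_panel(panel$subjects[keep], panel$meta[keep, ],
                     panel$node_names, panel$mask[keep])
    covs <- prepare_panel(sub, censor = censor)$covs
    fit <- fit_ml(model, covs, grouping = "free", control = control,
                  se = FALSE, ci = FALSE)
    decade_trends(fit, cohort_axis, alpha)
  })
  names(tabs) <- sexes
  base <- tabs[[1]][, c("source", "target")]
  classes <- vapply(tabs, function(t) t$class, character(nrow(base)))
  divergent <- base[rowSums(classes != "flat") == 1, , drop = FALSE]
  if (nrow(divergent) > 0)
    divergent <- cbind(divergent,
                       classes[rowSums(classes != "flat") == 1, , drop = FALSE])
  tabs$divergent <- divergent
  tabs
}

#' Probability of an edge-set overlap under random choice
#'
#' Ignoring direction, two edge sets over `n` nodes overlap in `k`
#' undirected pairs; under a hypergeometric null (the second set drawn
#' uniformly from the `choose(n, 2)` possible pairs), returns the exact
#' tail probability of an overlap at least as large.  Computed exactly
#' from binomial coefficients.
#'
#' @param set_a,set_b edge lists (data frames with `source`, `target`).
#' @param n_nodes number of nodes in the network.
#' @return List with `n_possible`, `size_a`, `size_b`, `overlap` and
#'   `p_value`.
#' @export
edge_overlap_probability <- function(set_a, set_b, n_nodes) {
  undirected <- function(e)
    unique(vapply(seq_len(nrow(e)), function(i)
      paste(sort(c(e$source[i], e$target[i])), collapse = "|"), ""))
  a <- undirected(as.data.frame(set_a))
  b <- undirected(as.data.frame(set_b))
  npos <- choose(n_nodes, 2)
  if (length(a) > npos || length(b) > npos)
    stop("edge set larger than the number of possible undirected pairs")
  k <- length(intersect(a, b))
  K <- length(a); m <- length(b)
  kmax <- min(K, m)
  p <- sum(vapply(k:kmax, function(x)
    choose(K, x) * choose(npos - K, m - x), 0)) / choose(npos, m)
  list(n_possible = npos, size_a = K, size_b = m, overlap = k, p_value = p)
}

#' Per-subject trend correlations
#'
#' Secondary check of cohort-level trends: fits the model to each subject
#' alone (one single-group fit per subject) and correlates each edge's
#' per-subject lagged-path coefficient with the subject's cohort.
#' Subject-level estimates carry large standard errors, so this is a
#' robustness view, not the primary trend statistic.
#'
#' @param panel a raw `usem_panel`.
#' @param model the `usem_model` to fit.
#' @param censor apply spike censoring.
#' @param control optimizer settings.
#' @return Data frame `source`, `target`, `r` over subjects.
#' @export
subject_trends <- function(panel, model, censor = TRUE,
                           control = usem_control()) {
  layout <- usem_layout(model)
  E <- layout$E
  coefs <- vapply(seq_along(panel$subjects), function(i) {
    sub <- new_panel(panel$subjects[i], panel$meta[i, ], panel$node_names,
                     panel$mask[i])
    covs <- prepare_panel(sub, censor = censor)$covs
    fit <- fit_ml(model, covs, grouping = "free", control = control,
                  se = FALSE, ci = FALSE)
    fit$theta[[1]][E + seq_len(E)]
  }, numeric(E))
  de <- directed_edges(model)
  data.frame(source = de$source, target = de$target,
             r = apply(coefs, 1, function(v)
               stats::cor(v, panel$meta$cohort)),
             stringsAsFactors = FALSE)
}
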