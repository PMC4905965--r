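#' Fit a unified SEM to cohort covariance matrices by maximum likelihood
#'
#' Minimizes the Wishart discrepancy
#' \eqn{F^{(g)} = \ln|\Sigma(\theta_g)| - \ln|S_g| + tr(S_g \Sigma(\theta_g)^{-1}) - p}
#' per cohort.  Under `grouping = "free"` each cohort has its own
#' parameters and the groups are fitted independently; under
#' `grouping = "equal"` one parameter vector is shared and the weighted sum
#' \eqn{\sum_g (N^{(g)}-1) F^{(g)}} is minimized jointly.  The model
#' chi-square is \eqn{\sum_g (N^{(g)}-1) \hat F^{(g)}} in both modes.
#' Standard errors come from the inverse expected information.
#'
#' @param model a `usem_model`.
#' @param covs a `usem_covs` from [cohort_covariances()].
#' @param grouping `"free"` or `"equal"`.
#' @param control optimizer settings, see [usem_control()].
#' @param starts optional list of per-cohort start vectors (internal use by
#'   the specification search).
#' @param se compute standard errors (skippable for speed in search loops).
#' @param ci compute RMSEA confidence bounds in the index bundle.
#' @return A `usem_fit` with per-cohort discrepancies and parameters, an
#'   `estimates` table (cohort, source, target, path type, estimate, SE),
#'   pooled `chisq`, `df`, `q`, convergence diagnostics and a fit-index
#'   bundle (see [fit_indices()]).
#' @export
fit_ml <- function(model, covs, grouping = c("free", "equal"),
                   control = usem_control(), starts = NULL, se = TRUE,
                   ci = TRUE) {
  grouping <- match.arg(grouping)
  layout <- usem_layout(model)
  G <- length(covs$S)
  Ns <- as.numeric(covs$n_per_cohort)
  for (S in covs$S)
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("cohort covariance matrix is not positive definite")
  if (grouping == "free") {
    fits <- lapply(seq_len(G), function(g)
      fit_group_ml(layout, covs$S[[g]],
                   start = if (is.null(starts)) NULL else starts[[g]],
                   control = control))
    theta <- lapply(fits, `[[`, "theta")
    Fg <- vapply(fits, `[[`, 0, "F")
    diag_info <- list(iterations = vapply(fits, `[[`, 0L, "iterations"),
                      grad_norm = max(vapply(fits, `[[`, 0, "grad_norm")))
  } else {
    objs <- lapply(seq_len(G), function(g)
      ram_objective(layout, covs$S[[g]],
                    as.numeric(determinant(covs$S[[g]])$modulus)))
    w <- Ns - 1
    fn <- function(th) sum(w * vapply(objs, function(o) o$fn(th), 0))
    gr <- function(th) {
      gm <- vapply(objs, function(o) o$gr(th), numeric(layout$npar))
      as.numeric(gm %*% w)
    }
    Sbar <- Reduce(`+`, Map(`*`, covs$S, w)) / sum(w)
    start <- if (is.null(starts)) default_start(layout, Sbar, control)
             else starts[[1]]
    o <- stats::nlminb(start, fn, gr,
                       control = list(iter.max = control$max_iter,
                                      rel.tol = control$rel_tol))
    theta <- rep(list(o$par), G)
    Fg <- vapply(seq_len(G), function(g) objs[[g]]$fn(o$par), 0)
    diag_info <- list(iterations = o$iterations,
                      grad_norm = max(abs(gr(o$par))) / (1 + abs(o$objective)))
  }
  acc <- usem_df(model, G, grouping)
  chisq <- sum((Ns - 1) * Fg)
  ses <- NULL
  if (se) ses <- fit_standard_errors(layout, theta, Ns, grouping)
  est <- estimates_table(layout, theta, ses, names(covs$S))
  fit <- structure(list(
    model = model, layout = layout, grouping = grouping,
    cohorts = names(covs$S), n_per_cohort = covs$n_per_cohort,
    n_total = covs$n_total,
    theta = theta, Fg = Fg, chisq = chisq,
    df = acc$df, q = acc$q, p = acc$p,
    estimates = est, diagnostics = diag_info), class = "usem_fit")
  fit$indices <- fit_indices(fit, covs, ci = ci)
  fit
}

fit_standard_errors <- function(layout, theta, Ns, grouping) {
  if (grouping == "free") {
    lapply(seq_along(theta), function(g) {
      d <- ram_derivs(layout, theta[[g]])
      K <- information_K(d$Si, d$D)
      Iinv <- tryCatch(solve((Ns[g] - 1) / 2 * K), error = function(e) NULL)
      if (is.null(Iinv)) rep(NA_real_, layout$npar) else sqrt(pmax(diag(Iinv), 0))
    })
  } else {
    Ksum <- 0
    for (g in seq_along(theta)) {
      d <- ram_derivs(layout, theta[[g]])
      Ksum <- Ksum + (Ns[g] - 1) / 2 * information_K(d$Si, d$D)
    }
    Iinv <- tryCatch(solve(Ksum), error = function(e) NULL)
    se1 <- if (is.null(Iinv)) rep(NA_real_, layout$npar) else sqrt(pmax(diag(Iinv), 0))
    rep(list(se1), length(theta))
  }
}

estimates_table <- function(layout, theta, ses, cohorts) {
  qp <- layout$q_paths
  do.call(rbind, lapply(seq_along(theta), function(g) {
    data.frame(cohort = cohorts[g],
               source = layout$edge_source,
               target = layout$edge_target,
               path_type = layout$path_type,
               estimate = theta[[g]][seq_len(qp)],
               se = if (is.null(ses)) NA_real_ else ses[[g]][seq_len(qp)],
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.usem_fit <- function(x, ...) {
  cat(sprintf(
    "usem_fit (%s): %d cohorts, chisq = %.3f, df = %d, q = %d\n",
    x$grouping, length(x$cohorts), x$chisq, x$df, x$q))
  ix <- x$indices
  cat(sprintf("  RMSEA %.4f (90%% CI %.4f-%.4f), BCC %.3f, CFI %.3f\n",
              ix$rmsea, ix$rmsea_lo90, ix$rmsea_hi90, ix$bcc, ix$cfi))
  invisible(x)
}

#' Extract a coefficient matrix by cohort for one path type
#'
#' @param fit a `usem_fit` with per-cohort free parameters.
#' @param path_type one of `"lagged"`, `"contemporaneous"`, `"crosslag"`,
#'   `"auto"`.
#' @return Data frame of edges by cohorts with coefficient columns.
#' @export
path_coefficients <- function(fit, path_type = "lagged") {
  est <- fit$estimates[fit$estimates$path_type == path_type, ]
  wide <- stats::reshape(est[, c("cohort", "source", "target", "estimate")],
                         idvar = c("source", "target"),
                         timevar = "cohort", direction = "wide")
  names(wide) <- sub("^estimate\\.", "cohort_", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Compare feedback and unidirectional treatments of reciprocal edges
#'
#' For edges whose direction is undecided a priori, fits (a) the
#' non-recursive variant in which each listed edge contributes both
#' directions' path triples as a feedback loop, and (b) for each listed
#' edge, the two recursive variants with a single orientation (other
#' listed edges kept as feedback loops).  Also fits the fully recursive
#' model taking each edge's better orientation.  Variants are ranked by
#' RMSEA, then CFI.
#'
#' @param model a `usem_model` containing the listed edges.
#' @param covs cohort covariances.
#' @param bidirectional_edges data frame `source`/`target` of edges to
#'   treat as reciprocal.
#' @param grouping,control passed to [fit_ml()].
#' @return A list with `comparison` (one row per variant: label, chisq,
#'   df, RMSEA, CFI, BCC), `fits` and `best` (label of the top-ranked
#'   variant).
#' @export
fit_bidirectional_variants <- function(model, covs, bidirectional_edges,
                                       grouping = "free",
                                       control = usem_control()) {
  be <- as.data.frame(bidirectional_edges, stringsAsFactors = FALSE)
  key <- paste(model$edges$source, model$edges$target)
  miss <- !(paste(be$source, be$target) %in% key |
            paste(be$target, be$source) %in% key)
  if (any(miss))
    stop("bidirectional edge not in model: ",
         paste(be$source[miss], "->", be$target[miss], collapse = ", "))
  set_flags <- function(feedback_rows) {
    e <- model$edges
    e$bidirectional <- FALSE
    for (i in seq_len(nrow(be))) {
      at <- which((e$source == be$source[i] & e$target == be$target[i]) |
                  (e$source == be$target[i] & e$target == be$source[i]))
      if (i %in% feedback_rows) {
        e$bidirectional[at] <- TRUE
      } else if (attr(feedback_rows, "flip")[i]) {
        tmp <- e$source[at]; e$source[at] <- e$target[at]; e$target[at] <- tmp
      }
    }
    build_usem(model$nodes, e)
  }
  variants <- list()
  all_fb <- seq_len(nrow(be)); attr(all_fb, "flip") <- rep(FALSE, nrow(be))
  variants[["feedback"]] <- set_flags(all_fb)
  orient_best <- logical(nrow(be))
  for (i in seq_len(nrow(be))) {
    for (flip in c(FALSE, TRUE)) {
      fb <- setdiff(seq_len(nrow(be)), i)
      fl <- rep(FALSE, nrow(be)); fl[i] <- flip
      attr(fb, "flip") <- fl
      lab <- sprintf("%s -> %s", if (flip) be$target[i] else be$source[i],
                     if (flip) be$source[i] else be$target[i])
      variants[[lab]] <- set_flags(fb)
    }
  }
  fits <- lapply(variants, fit_ml, covs = covs, grouping = grouping,
                 control = control, se = FALSE, ci = FALSE)
  # better orientation per edge by RMSEA
  for (i in seq_len(nrow(be))) {
    fwd <- sprintf("%s -> %s", be$source[i], be$target[i])
    rev <- sprintf("%s -> %s", be$target[i], be$source[i])
    orient_best[i] <- fits[[rev]]$indices$rmsea < fits[[fwd]]$indices$rmsea
  }
  fb0 <- integer(0); attr(fb0, "flip") <- orient_best
  variants[["recursive"]] <- set_flags(fb0)
  fits[["recursive"]] <- fit_ml(variants[["recursive"]], covs,
                                grouping = grouping, control = control,
                                se = FALSE, ci = FALSE)
  comparison <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(variant = nm, chisq = f$chisq, df = f$df,
               rmsea = f$indices$rmsea, cfi = f$indices$cfi,
               bcc = f$indices$bcc, stringsAsFactors = FALSE)
  }))
  comparison <- comparison[order(comparison$rmsea, -comparison$cfi), ]
  rownames(comparison) <- NULL
  list(comparison = comparison, fits = fits, best = comparison$variant[1])
}
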