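#' Root mean square error of approximation
#'
#' \eqn{RMSEA = \sqrt{\max(\chi^2 - df, 0) / (n \cdot df)}}.
#'
#' @param chi_square model chi-square.
#' @param df model degrees of freedom (must be positive).
#' @param n sample size (total across groups for a pooled fit; the group's
#'   own size for a single-cohort fit).
#' @return RMSEA point estimate.
#' @export
rmsea <- function(chi_square, df, n) {
  if (df <= 0) stop("RMSEA requires df > 0")
  if (n <= 1) stop("RMSEA requires n > 1")
  sqrt(max(chi_square - df, 0) / (n * df))
}

# Solve Phi(chi^2 | ncp, df) = prob for the noncentrality parameter; the
# noncentral chi-square CDF is decreasing in the ncp, so the root is
# bracketed and found by uniroot to high relative precision.  Returns 0
# (clamped) when even ncp = 0 gives a CDF below prob.
solve_ncp <- function(chi_square, df, prob, tol = 1e-10) {
  f <- function(d) suppressWarnings(stats::pchisq(chi_square, df, ncp = d)) - prob
  if (f(0) <= 0) return(0)
  hi <- max(2 * (chi_square - df), 10)
  while (f(hi) > 0) hi <- hi * 2
  stats::uniroot(f, c(0, hi), tol = tol * max(1, chi_square),
                 maxiter = 200)$root
}

#' 90% confidence interval for RMSEA
#'
#' The upper noncentrality \eqn{\delta_U} solves
#' \eqn{\Phi(\chi^2 | \delta, df) = 0.05} and the lower \eqn{\delta_L}
#' solves \eqn{\Phi(\chi^2 | \delta, df) = 0.95} (noncentral chi-square
#' CDF, clamped at 0 when no root exists); the bounds are
#' \eqn{\sqrt{\delta / (n \cdot df)}}.
#'
#' @inheritParams rmsea
#' @return Named vector `c(lo90, hi90)`.
#' @export
rmsea_ci <- function(chi_square, df, n) {
  if (df <= 0) stop("RMSEA requires df > 0")
  dU <- solve_ncp(chi_square, df, 0.05)
  dL <- solve_ncp(chi_square, df, 0.95)
  c(lo90 = sqrt(dL / (n * df)), hi90 = sqrt(dU / (n * df)))
}

#' Browne-Cudeck criterion
#'
#' \eqn{BCC = \chi^2 + 2q \cdot \sum_g b^{(g)} p^{(g)}(p^{(g)}+3) /
#' (N^{(g)} - p^{(g)} - 2) \big/ \sum_g p^{(g)}(p^{(g)}+3)} with
#' \eqn{b^{(g)} = N^{(g)}}.  For large groups the penalty tends to
#' \eqn{2q} (the AIC limit); the criterion penalizes each parameter
#' slightly more than AIC in finite samples.  `printed_form = TRUE`
#' switches the denominator to \eqn{\sum_g b^{(g)} (p^{(g)}+3)}, a variant
#' that appears in some published statements of the criterion but whose
#' penalty vanishes as the sample grows.
#'
#' @param chi_square minimized model chi-square.
#' @param q number of free parameters.
#' @param group_sizes per-group sample sizes \eqn{N^{(g)}}.
#' @param p_per_group per-group observed-variable counts \eqn{p^{(g)}}.
#' @param printed_form use the large-sample-degenerate denominator.
#' @return BCC value.
#' @export
bcc <- function(chi_square, q, group_sizes, p_per_group, printed_form = FALSE) {
  stopifnot(q >= 0)
  N <- group_sizes
  pg <- rep_len(p_per_group, length(N))
  if (any(N <= pg + 2))
    stop("BCC requires every group size to exceed p + 2")
  b <- N
  num <- sum(b * pg * (pg + 3) / (N - pg - 2))
  den <- if (printed_form) sum(b * (pg + 3)) else sum(pg * (pg + 3))
  chi_square + 2 * q * num / den
}

#' Comparative fit index
#'
#' \eqn{CFI = 1 - \max(\chi^2 - df, 0) / \max(\chi^2_{null} - df_{null},
#' \chi^2 - df, 0)}, clamped to `[0, 1]`; the null is the independence
#' model (all observed variables uncorrelated, variances free).
#'
#' @param chi_square,df target model fit.
#' @param null_chi_square,null_df independence-model fit.
#' @return CFI in `[0, 1]`.
#' @export
cfi <- function(chi_square, df, null_chi_square, null_df) {
  num <- max(chi_square - df, 0)
  den <- max(null_chi_square - null_df, num)
  if (den == 0) return(1)
  if (null_chi_square - null_df < num)
    warning("null model fits better than target model; CFI clamped")
  min(max(1 - num / den, 0), 1)
}

# Independence-model (all variables uncorrelated, variances free) fit has
# the closed form F = log|diag(S)| - log|S| per group.
independence_fit <- function(covs) {
  Ns <- as.numeric(covs$n_per_cohort)
  Fg <- vapply(covs$S, function(S)
    sum(log(diag(S))) - as.numeric(determinant(S)$modulus), 0)
  p <- nrow(covs$S[[1]])
  G <- length(covs$S)
  list(chisq = sum((Ns - 1) * Fg),
       df = as.integer(G * p * (p + 1) / 2 - G * p))
}

#' Fit-index bundle for a fitted unified SEM
#'
#' Computes the chi-square based index set for a `usem_fit`: RMSEA with
#' 90% noncentral chi-square bounds (using the total sample size), BCC,
#' CFI against the independence null, AIC and BIC, plus a per-cohort
#' sub-bundle in which each cohort's chi-square, degrees of freedom and
#' own sample size are used.
#'
#' @param fit a `usem_fit`.
#' @param covs the cohort covariances the model was fitted to.
#' @param ci compute the noncentral chi-square confidence bounds (the
#'   costly part; search loops skip it for candidate fits).
#' @return List with `chi_square`, `df`, `n_total`, `rmsea`,
#'   `rmsea_lo90`, `rmsea_hi90`, `bcc`, `cfi`, `aic`, `bic` and
#'   `per_cohort` (data frame).
#' @export
fit_indices <- function(fit, covs, ci = TRUE) {
  Ns <- as.numeric(covs$n_per_cohort)
  n_total <- sum(Ns)
  null <- independence_fit(covs)
  ci_tot <- if (ci && fit$df > 0) rmsea_ci(fit$chisq, fit$df, n_total)
            else c(NA_real_, NA_real_)
  qg <- usem_df(fit$model, 1L)$q_per_group
  dfg <- fit$p * (fit$p + 1) / 2 - qg
  per <- do.call(rbind, lapply(seq_along(Ns), function(g) {
    chg <- (Ns[g] - 1) * fit$Fg[g]
    cig <- if (ci && dfg > 0) rmsea_ci(chg, dfg, Ns[g])
           else c(NA_real_, NA_real_)
    data.frame(cohort = fit$cohorts[g], n = Ns[g], chi_square = chg,
               df = dfg,
               rmsea = if (dfg > 0) rmsea(chg, dfg, Ns[g]) else NA,
               rmsea_lo90 = cig[1], rmsea_hi90 = cig[2],
               stringsAsFactors = FALSE)
  }))
  list(chi_square = fit$chisq, df = fit$df, n_total = n_total,
       rmsea = if (fit$df > 0) rmsea(fit$chisq, fit$df, n_total) else NA,
       rmsea_lo90 = unname(ci_tot[1]), rmsea_hi90 = unname(ci_tot[2]),
       bcc = bcc(fit$chisq, fit$q, Ns, fit$p),
       cfi = cfi(fit$chisq, fit$df, null$chisq, null$df),
       aic = fit$chisq + 2 * fit$q,
       bic = fit$chisq + fit$q * log(n_total),
       null_chi_square = null$chisq, null_df = null$df,
       per_cohort = per)
}
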