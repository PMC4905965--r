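#' Modification indices for candidate connections
#'
#' For every node pair with no edge in either direction, computes the
#' univariate score-test statistic of each of the three paths the edge
#' would free (per direction), evaluated at the restricted optimum: with
#' score \eqn{s = -(N-1)/2 \cdot \partial F/\partial\theta} and effective
#' information \eqn{(N-1)/2 (K_{cc} - K_{cf} K_{ff}^{-1} K_{fc})}, the MI
#' is \eqn{s^2 / I_{eff}}, a lower-bound estimate of the chi-square drop
#' obtained by actually freeing the parameter.  Under per-cohort free
#' parameters the MI of a path is summed over cohorts.
#'
#' @param fit a converged `usem_fit`.
#' @param covs the cohort covariances the model was fitted to.
#' @return A data frame with one row per candidate path: `source`,
#'   `target`, `path_type`, `mi`; candidates whose effective information
#'   is numerically singular are dropped with a warning.
#' @export
modification_indices <- function(fit, covs) {
  layout <- fit$layout
  n <- layout$n
  nodes <- fit$model$nodes
  de <- directed_edges(fit$model)
  present <- matrix(FALSE, n, n)
  if (nrow(de) > 0)
    present[cbind(match(de$target, nodes), match(de$source, nodes))] <- TRUE
  cand <- list()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    if (!present[i, j] && !present[j, i]) cand[[length(cand) + 1]] <- c(i, j)
  if (length(cand) == 0)
    return(data.frame(source = character(0), target = character(0),
                      path_type = character(0), mi = numeric(0),
                      stringsAsFactors = FALSE))
  # candidate path positions in A, three per direction per pair
  rows <- integer(0); cols <- integer(0)
  src <- character(0); tgt <- character(0); typ <- character(0)
  for (pr in cand) for (d in 1:2) {
    s <- if (d == 1) pr[1] else pr[2]
    t <- if (d == 1) pr[2] else pr[1]
    rows <- c(rows, t, n + t, n + t)
    cols <- c(cols, s, n + s, s)
    src <- c(src, rep(nodes[s], 3))
    tgt <- c(tgt, rep(nodes[t], 3))
    typ <- c(typ, "contemporaneous", "lagged", "crosslag")
  }
  nc <- length(rows)
  Ns <- as.numeric(covs$n_per_cohort)
  mi <- numeric(nc)
  dropped <- FALSE
  for (g in seq_along(covs$S)) {
    th <- fit$theta[[g]]
    d <- ram_derivs(layout, th)
    S_obs <- covs$S[[g]]
    W <- d$Si %*% (d$Sig - S_obs) %*% d$Si
    GA <- 2 * crossprod(d$B, W %*% d$Sig)
    Dc <- lapply(seq_len(nc), function(m) {
      X <- outer(d$B[, rows[m]], d$Sig[cols[m], ])
      X + t(X)
    })
    K <- information_K(d$Si, c(d$D, Dc))
    nf <- layout$npar
    Kff_inv <- tryCatch(solve(K[seq_len(nf), seq_len(nf)]),
                        error = function(e) NULL)
    if (is.null(Kff_inv)) {
      Kff_inv <- solve(K[seq_len(nf), seq_len(nf)] + diag(1e-8, nf))
    }
    for (m in seq_len(nc)) {
      kcf <- K[nf + m, seq_len(nf)]
      denom <- K[nf + m, nf + m] - sum(kcf * (Kff_inv %*% kcf))
      if (denom > 1e-10) {
        g_m <- GA[rows[m], cols[m]]
        mi[m] <- mi[m] + (Ns[g] - 1) / 2 * g_m^2 / denom
      } else {
        mi[m] <- NA_real_
        dropped <- TRUE
      }
    }
  }
  out <- data.frame(source = src, target = tgt, path_type = typ, mi = mi,
                    stringsAsFactors = FALSE)
  if (dropped) {
    warning("some candidates dropped: singular effective information")
    out <- out[!is.na(out$mi), ]
  }
  out
}

# Aggregate path-level MIs to one value per candidate directed edge.
aggregate_mi <- function(mi_table, how = c("sum", "max")) {
  how <- match.arg(how)
  if (nrow(mi_table) == 0)
    return(data.frame(source = character(0), target = character(0),
                      mi = numeric(0), stringsAsFactors = FALSE))
  key <- paste(mi_table$source, mi_table$target)
  agg <- tapply(mi_table$mi, key, if (how == "sum") sum else max)
  parts <- strsplit(names(agg), " ")
  data.frame(source = vapply(parts, `[`, "", 1),
             target = vapply(parts, `[`, "", 2),
             mi = as.numeric(agg), stringsAsFactors = FALSE)
}
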