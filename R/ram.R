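# Reticular-action-model (RAM) machinery for the unified SEM.
#
# Variables are ordered (u_1..u_n, l_1..l_n): unlagged block first, then
# the one-step-offset block.  The asymmetric matrix A holds directed path
# coefficients A[target, source]; S is diagonal (residual variances,
# exogenous covariances fixed at zero); all variables are observed, so the
# implied covariance is Sigma = (I - A)^-1 S (I - A)^-T.
#
# Parameter vector layout for a model with E directed edges and n nodes:
#   theta = (c_1..c_E, d_1..d_E, e_1..e_E, a_1..a_n, log psi_1..log psi_2n)
# where c = unlagged->unlagged, d = lagged->lagged, e = unlagged->lagged
# cross-lag, a = autoregressive, and residual variances are optimized on
# the log scale to keep them positive.

usem_layout <- function(model) {
  n <- length(model$nodes)
  de <- directed_edges(model)
  E <- nrow(de)
  src <- match(de$source, model$nodes)
  tgt <- match(de$target, model$nodes)
  rows <- c(tgt, n + tgt, n + tgt, n + seq_len(n))
  cols <- c(src, n + src, src, seq_len(n))
  type <- c(rep("contemporaneous", E), rep("lagged", E), rep("crosslag", E),
            rep("auto", n))
  lab <- c(rep(paste(de$source, "->", de$target), 3),
           paste(model$nodes, "->", model$nodes))
  list(n = n, p = 2L * n, E = E,
       idxA = cbind(rows, cols),
       q_paths = 3L * E + n,
       npar = 3L * E + n + 2L * n,
       path_type = type, path_label = lab,
       edge_source = c(rep(de$source, 3), model$nodes),
       edge_target = c(rep(de$target, 3), model$nodes),
       var_names = c(model$nodes, paste0(model$nodes, "_lag")))
}

ram_matrices <- function(layout, theta) {
  p <- layout$p
  A <- matrix(0, p, p)
  A[layout$idxA] <- theta[seq_len(layout$q_paths)]
  S <- diag(exp(theta[(layout$q_paths + 1):layout$npar]), p)
  list(A = A, S = S)
}

#' Implied covariance of a RAM path system
#'
#' Computes \eqn{\Sigma = (I - A)^{-1} S (I - A)^{-T}} for an asymmetric
#' path-coefficient matrix `A` (entry `[target, source]`) and a symmetric
#' residual matrix `S`.
#'
#' @param A square path-coefficient matrix.
#' @param S symmetric residual covariance matrix of the same dimension.
#' @return Symmetric implied covariance matrix.
#' @export
implied_covariance <- function(A, S) {
  p <- nrow(A)
  stopifnot(nrow(S) == p, ncol(A) == p)
  IA <- diag(p) - A
  if (abs(det(IA)) < 1e-12) {
    gr <- which(A != 0, arr.ind = TRUE)
    stop("singular (I - A): the path system contains an ill-posed cycle ",
         "(feedback loop with coefficient product 1) among entries ",
         paste(sprintf("[%d,%d]", gr[, 1], gr[, 2]), collapse = " "))
  }
  B <- solve(IA)
  Sig <- B %*% S %*% t(B)
  (Sig + t(Sig)) / 2
}

# Wishart ML discrepancy F = log|Sigma| - log|S_obs| + tr(S_obs Sigma^-1) - p
# and its analytic gradient in the theta parameterization.
ram_objective <- function(layout, S_obs, ldet_obs) {
  p <- layout$p
  qp <- layout$q_paths
  idxA <- layout$idxA
  np <- layout$npar
  Ip <- diag(p)
  fn <- function(theta) {
    A <- matrix(0, p, p); A[idxA] <- theta[seq_len(qp)]
    B <- tryCatch(solve(Ip - A), error = function(e) NULL)
    if (is.null(B)) return(1e10)
    sv <- exp(theta[(qp + 1):np])
    Sig <- B %*% (t(B) * sv)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    2 * sum(log(diag(ch))) - ldet_obs + sum(chol2inv(ch) * S_obs) - p
  }
  gr <- function(theta) {
    A <- matrix(0, p, p); A[idxA] <- theta[seq_len(qp)]
    B <- tryCatch(solve(Ip - A), error = function(e) NULL)
    if (is.null(B)) return(numeric(np))
    sv <- exp(theta[(qp + 1):np])
    Sig <- B %*% (t(B) * sv)
    Si <- tryCatch(solve(Sig), error = function(e) NULL)
    if (is.null(Si)) return(numeric(np))
    W <- Si %*% (Sig - S_obs) %*% Si
    GA <- 2 * crossprod(B, W %*% Sig)     # dF/dA[i,j]
    gS <- diag(crossprod(B, W %*% B)) * sv
    c(GA[idxA], gS)
  }
  list(fn = fn, gr = gr)
}

# Minimize the ML discrepancy for one group.  Deterministic restarts with
# perturbed starts are attempted if the optimizer fails to converge or
# leaves a large scaled gradient.
fit_group_ml <- function(layout, S_obs, start = NULL,
                         control = usem_control()) {
  obj <- ram_objective(layout, S_obs, as.numeric(determinant(S_obs)$modulus))
  if (is.null(start)) start <- default_start(layout, S_obs, control)
  best <- NULL
  for (r in 0:control$restarts) {
    th0 <- if (r == 0) start else
      start + 0.1 * r * cos(seq_along(start) * (r + 1))
    o <- stats::nlminb(th0, obj$fn, obj$gr,
                       control = list(iter.max = control$max_iter,
                                      rel.tol = control$rel_tol))
    gnorm <- max(abs(obj$gr(o$par))) / (1 + abs(o$objective))
    cand <- list(F = o$objective, theta = o$par, iterations = o$iterations,
                 grad_norm = gnorm, converged = gnorm < control$grad_tol)
    if (is.null(best) || cand$F < best$F) best <- cand
    if (best$converged) break
  }
  if (!best$converged && best$grad_norm > 1e-3)
    stop(sprintf(
      "ML fit did not converge: best discrepancy %.6g, scaled gradient %.3g",
      best$F, best$grad_norm))
  best
}

default_start <- function(layout, S_obs, control) {
  c(rep(control$start_path, layout$q_paths - layout$n),
    rep(control$start_path, layout$n),
    log(pmax(diag(S_obs), 1e-3)))
}

#' Optimizer settings for maximum-likelihood fitting
#'
#' @param max_iter iteration cap per optimizer run.
#' @param rel_tol relative convergence tolerance on the discrepancy.
#' @param grad_tol maximum scaled gradient norm accepted at the optimum.
#' @param restarts deterministic perturbed restarts on non-convergence.
#' @param start_path starting value for free path coefficients.
#' @return List of control settings.
#' @export
usem_control <- function(max_iter = 500L, rel_tol = 1e-10, grad_tol = 1e-6,
                         restarts = 5L, start_path = 0.1) {
  list(max_iter = max_iter, rel_tol = rel_tol, grad_tol = grad_tol,
       restarts = restarts, start_path = start_path)
}

# Derivative matrices dSigma/dtheta at theta, for expected-information and
# score-test computations.  Returns the pieces shared by both.
ram_derivs <- function(layout, theta) {
  p <- layout$p
  qp <- layout$q_paths
  A <- matrix(0, p, p); A[layout$idxA] <- theta[seq_len(qp)]
  sv <- exp(theta[(qp + 1):layout$npar])
  B <- solve(diag(p) - A)
  Sig <- B %*% (t(B) * sv)
  Sig <- (Sig + t(Sig)) / 2
  Si <- solve(Sig)
  D <- vector("list", layout$npar)
  for (m in seq_len(qp)) {
    i <- layout$idxA[m, 1]; j <- layout$idxA[m, 2]
    X <- outer(B[, i], Sig[j, ])          # B e_i e_j' Sigma
    D[[m]] <- X + t(X)
  }
  for (m in seq_len(2 * layout$n))
    D[[qp + m]] <- outer(B[, m], B[, m]) * sv[m]
  list(B = B, Sig = Sig, Si = Si, D = D, sv = sv)
}

# Unit expected-information matrix K with K[a,b] = tr(Si D_a Si D_b).
# The Fisher information for a group of size N is (N-1)/2 * K.
information_K <- function(Si, Dlist) {
  p <- nrow(Si)
  V1 <- t(vapply(Dlist, function(D) as.vector(Si %*% D %*% Si), numeric(p * p)))
  V2 <- t(vapply(Dlist, function(D) as.vector(D), numeric(p * p)))
  V1 %*% t(V2)
}
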