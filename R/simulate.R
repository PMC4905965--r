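#' Simulation configuration for a contemporaneous + lag-1 structural model
#'
#' Defines the generative model used by [simulate_panel()]: at each time step
#' \eqn{y_t = (I - C)^{-1} (L y_{t-1} + a \circ y_{t-1} + \epsilon_t)}, where
#' `C` holds contemporaneous path coefficients (target row, source column,
#' zero diagonal), `L` holds cross-lag coefficients, `a` is a per-node lag-1
#' autoregression coefficient and the innovations \eqn{\epsilon_t} are
#' independent Gaussians with per-node standard deviation `innovation_sd`.
#' Coefficients may drift across cohorts, either through a linear
#' `cohort_schedule` (per-edge intercept at cohort 1 plus slope per cohort)
#' or through an explicit per-cohort coefficient array.
#'
#' @param node_names character vector of node labels.
#' @param contemporaneous_coeffs square numeric matrix (zero diagonal) of
#'   contemporaneous coefficients, or an `n x n x G` array giving each
#'   cohort's matrix explicitly.
#' @param crosslag_coeffs square numeric matrix of lag-1 cross coefficients.
#' @param auto_coeffs per-node lag-1 autoregression coefficient in `[0, 1)`.
#' @param innovation_sd per-node positive innovation standard deviation, or
#'   the string `"unit-variance"` to calibrate innovation variances so that
#'   every node's stationary variance equals 1 in every cohort (see
#'   [calibrate_innovations()]).
#' @param cohort_schedule optional data frame with columns `source`,
#'   `target`, `intercept`, `slope`; the contemporaneous coefficient of the
#'   edge at cohort `k` is `intercept + slope * (k - 1)`.
#' @param n_cohorts number of cohorts `G`.
#' @param subjects_per_cohort subjects simulated per cohort.
#' @param timepoints_per_subject retained time points per subject.
#' @param burn_in time steps discarded at the start of each subject's series.
#' @param spike_spec optional list of artifact descriptors, each a list with
#'   elements `subject` (global subject index), `time`, `rois` (labels or
#'   indices) and `amplitude` (in units of the series' SD).
#' @param seed integer seed controlling all randomness of the simulation.
#'
#' @return An object of class `usem_sim_config`.
#' @seealso [simulate_panel()], [default_dmn_scenario()]
#' @export
sim_config <- function(node_names,
                       contemporaneous_coeffs = NULL,
                       crosslag_coeffs = NULL,
                       auto_coeffs = 0,
                       innovation_sd = 1,
                       cohort_schedule = NULL,
                       n_cohorts = 1L,
                       subjects_per_cohort = 1L,
                       timepoints_per_subject = 150L,
                       burn_in = 200L,
                       spike_spec = NULL,
                       seed = 1L) {
  n <- length(node_names)
  stopifnot(n >= 1, n_cohorts >= 1, subjects_per_cohort >= 1,
            timepoints_per_subject >= 2, burn_in >= 0)
  if (is.null(contemporaneous_coeffs))
    contemporaneous_coeffs <- matrix(0, n, n)
  if (is.null(crosslag_coeffs)) crosslag_coeffs <- matrix(0, n, n)
  auto_coeffs <- rep_len(auto_coeffs, n)
  if (any(auto_coeffs < 0 | auto_coeffs >= 1))
    stop("auto_coeffs must lie in [0, 1)")
  cfg <- structure(list(
    node_names = node_names,
    contemporaneous_coeffs = contemporaneous_coeffs,
    crosslag_coeffs = crosslag_coeffs,
    auto_coeffs = auto_coeffs,
    innovation_sd = innovation_sd,
    cohort_schedule = cohort_schedule,
    n_cohorts = as.integer(n_cohorts),
    subjects_per_cohort = as.integer(subjects_per_cohort),
    timepoints_per_subject = as.integer(timepoints_per_subject),
    burn_in = as.integer(burn_in),
    spike_spec = spike_spec,
    seed = as.integer(seed)), class = "usem_sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Contemporaneous coefficient matrix of one cohort
#'
#' @param config a `usem_sim_config`.
#' @param cohort cohort index in `1..n_cohorts`.
#' @return The `n x n` contemporaneous coefficient matrix for that cohort.
#' @export
cohort_coeffs <- function(config, cohort) {
  cc <- config$contemporaneous_coeffs
  n <- length(config$node_names)
  if (is.array(cc) && length(dim(cc)) == 3L) {
    C <- cc[, , cohort]
  } else {
    C <- cc
    sch <- config$cohort_schedule
    if (!is.null(sch)) {
      si <- match(sch$source, config$node_names)
      ti <- match(sch$target, config$node_names)
      C[cbind(ti, si)] <- sch$intercept + sch$slope * (cohort - 1)
    }
  }
  dimnames(C) <- list(config$node_names, config$node_names)
  C
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants of the generative model: zero diagonal
#' and invertibility of `I - C`, and stationarity of the induced VAR(1)
#' (spectral radius of its companion matrix below 1) for every cohort.
#'
#' @param config a `usem_sim_config`.
#' @return `config`, invisibly; errors name the offending cohort.
#' @export
validate_sim_config <- function(config) {
  n <- length(config$node_names)
  for (g in seq_len(config$n_cohorts)) {
    C <- cohort_coeffs(config, g)
    if (any(diag(C) != 0))
      stop("contemporaneous coefficient matrix has nonzero diagonal in cohort ", g)
    IC <- diag(n) - C
    if (abs(det(IC)) < 1e-12)
      stop("(I - C) is singular in cohort ", g)
    M <- solve(IC, config$crosslag_coeffs + diag(config$auto_coeffs, n))
    rho <- max(Mod(eigen(M, only.values = TRUE)$values))
    if (rho >= 1)
      stop(sprintf(
        "non-stationary configuration in cohort %d: spectral radius %.4f >= 1",
        g, rho))
  }
  invisible(config)
}

#' Stationary covariance of the induced VAR(1)
#'
#' Solves the discrete Lyapunov equation \eqn{\Sigma = M \Sigma M' + Q} for
#' the reduced-form transition matrix \eqn{M = (I-C)^{-1}(L + diag(a))} and
#' innovation covariance \eqn{Q = (I-C)^{-1} D (I-C)^{-T}} by direct
#' Kronecker-product linear solve.
#'
#' @param config a `usem_sim_config`.
#' @param cohort cohort index.
#' @param innovation_var optional per-node innovation variances overriding
#'   the configuration (used by the calibration).
#' @return The `n x n` stationary covariance of the observed series.
#' @export
stationary_covariance <- function(config, cohort = 1L, innovation_var = NULL) {
  n <- length(config$node_names)
  C <- cohort_coeffs(config, cohort)
  IC <- solve(diag(n) - C)
  M <- IC %*% (config$crosslag_coeffs + diag(config$auto_coeffs, n))
  if (is.null(innovation_var)) {
    sd <- resolved_innovation_sd(config, cohort)
    innovation_var <- sd^2
  }
  Q <- IC %*% diag(innovation_var, n) %*% t(IC)
  S <- matrix(solve(diag(n * n) - kronecker(M, M), as.vector(Q)), n, n)
  dimnames(S) <- list(config$node_names, config$node_names)
  (S + t(S)) / 2
}

#' Calibrate innovation variances to unit stationary variance
#'
#' The stationary variance of each node is linear in the vector of
#' innovation variances, so the calibration solves one `n x n` linear
#' system per cohort whose columns are the stationary diagonal produced by
#' a unit innovation in each node.  Errors if no positive solution exists
#' (strong incoming paths can push a node's stationary variance above 1
#' before any innovation noise is added).
#'
#' @param config a `usem_sim_config`.
#' @param cohort cohort index.
#' @return Per-node innovation standard deviations.
#' @export
calibrate_innovations <- function(config, cohort = 1L) {
  n <- length(config$node_names)
  basis <- vapply(seq_len(n), function(i) {
    v <- numeric(n); v[i] <- 1
    diag(stationary_covariance(config, cohort, innovation_var = v))
  }, numeric(n))
  d <- solve(basis, rep(1, n))
  if (any(d <= 0))
    stop("no positive innovation-variance calibration for cohort ", cohort,
         ": stationary variances cannot all be 1 under these coefficients")
  sqrt(d)
}

resolved_innovation_sd <- function(config, cohort) {
  if (identical(config$innovation_sd, "unit-variance")) {
    calibrate_innovations(config, cohort)
  } else {
    rep_len(config$innovation_sd, length(config$node_names))
  }
}

#' Simulate a cohort-structured multivariate time-series panel
#'
#' Generates `n_cohorts * subjects_per_cohort` series of length
#' `timepoints_per_subject` from the configured contemporaneous + lag-1
#' structural model.  Contemporaneous effects are resolved exactly by
#' solving the simultaneous system (multiplication by \eqn{(I-C)^{-1}})
#' at every step; a burn-in prefix is discarded so retained samples are
#' draws from the stationary distribution.  Optional spike artifacts are
#' added after generation.  Subjects alternate female/male within each
#' cohort so the panel carries sex metadata.
#'
#' @param config a valid `usem_sim_config`.
#' @return A `usem_panel`: list with `subjects` (list of time x node
#'   matrices), `meta` (data frame with `id`, `cohort`, `sex`), `mask`
#'   (list of logical keep-vectors, all `TRUE` on generation) and
#'   `node_names`.
#' @export
simulate_panel <- function(config) {
  validate_sim_config(config)
  n <- length(config$node_names)
  G <- config$n_cohorts
  nsub <- config$subjects_per_cohort
  Tn <- config$timepoints_per_subject
  burn <- config$burn_in
  set.seed(config$seed)
  subjects <- vector("list", G * nsub)
  meta <- data.frame(
    id = sprintf("s%03d", seq_len(G * nsub)),
    cohort = rep(seq_len(G), each = nsub),
    sex = rep(rep(c("F", "M"), length.out = nsub), G),
    stringsAsFactors = FALSE)
  idx <- 0L
  for (g in seq_len(G)) {
    C <- cohort_coeffs(config, g)
    IC <- solve(diag(n) - C)
    Lag <- config$crosslag_coeffs + diag(config$auto_coeffs, n)
    sd_g <- resolved_innovation_sd(config, g)
    for (s in seq_len(nsub)) {
      idx <- idx + 1L
      y <- matrix(0, Tn + burn, n)
      yp <- stats::rnorm(n)
      for (t in seq_len(Tn + burn)) {
        yt <- IC %*% (Lag %*% yp + stats::rnorm(n) * sd_g)
        y[t, ] <- yt
        yp <- yt
      }
      y <- y[(burn + 1):(burn + Tn), , drop = FALSE]
      colnames(y) <- config$node_names
      subjects[[idx]] <- y
    }
  }
  if (!is.null(config$spike_spec)) {
    for (sp in config$spike_spec) {
      ri <- if (is.character(sp$rois)) match(sp$rois, config$node_names) else sp$rois
      y <- subjects[[sp$subject]]
      y[sp$time, ri] <- y[sp$time, ri] +
        sp$amplitude * apply(y[, ri, drop = FALSE], 2, stats::sd)
      subjects[[sp$subject]] <- y
    }
  }
  new_panel(subjects, meta, config$node_names)
}

new_panel <- function(subjects, meta, node_names, mask = NULL) {
  if (is.null(mask))
    mask <- lapply(subjects, function(y) rep(TRUE, nrow(y)))
  structure(list(subjects = subjects, meta = meta, mask = mask,
                 node_names = node_names), class = "usem_panel")
}

#' @export
print.usem_panel <- function(x, ...) {
  cat(sprintf("usem_panel: %d subjects, %d nodes, %d cohorts\n",
              length(x$subjects), length(x$node_names),
              length(unique(x$meta$cohort))))
  cens <- sum(!unlist(x$mask))
  if (cens > 0) cat(sprintf("  %d censored time points\n", cens))
  invisible(x)
}

#' The packaged 9-node default-mode-network scenario
#'
#' Builds the simulation configuration whose ground truth is the 13-edge
#' exploratory connectivity model: six decade cohorts of 20 subjects, with
#' the lagged-to-lagged path coefficient of each edge at cohort *k* equal
#' to the packaged per-decade value (these are contemporaneous structural
#' coefficients of the generator, which the unified SEM estimates as its
#' lagged-block paths).  Innovation SDs are calibrated so every node has
#' unit stationary variance, putting the generating coefficients on the
#' standardized scale that fitting uses; the uniform autoregression
#' coefficient is 0.4, the largest round value admitting such a
#' calibration in all cohorts.
#'
#' @param seed integer seed.
#' @param subjects_per_cohort,timepoints_per_subject scenario size
#'   (defaults: 20 subjects, 600 time points).
#' @return A `usem_sim_config` for 9 nodes and 6 cohorts.
#' @export
default_dmn_scenario <- function(seed = 1L, subjects_per_cohort = 20L,
                                 timepoints_per_subject = 600L) {
  ref <- dmn_reference_model()
  nodes <- ref$nodes$name
  n <- length(nodes)
  G <- 6L
  arr <- array(0, c(n, n, G), dimnames = list(nodes, nodes, NULL))
  for (i in seq_len(nrow(ref$edges))) {
    ti <- match(ref$edges$target[i], nodes)
    si <- match(ref$edges$source[i], nodes)
    arr[ti, si, ] <- as.numeric(ref$coefficients[i, ])
  }
  sim_config(
    node_names = nodes,
    contemporaneous_coeffs = arr,
    auto_coeffs = 0.4,
    innovation_sd = "unit-variance",
    n_cohorts = G,
    subjects_per_cohort = subjects_per_cohort,
    timepoints_per_subject = timepoints_per_subject,
    burn_in = 200L,
    seed = seed)
}
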