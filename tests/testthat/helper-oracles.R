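# Independent oracles and small fixture builders shared across tests.

# Discrete-Lyapunov oracle: accumulate S <- M S M' + Q until convergence.
# Deliberately independent of the package's Kronecker-product solve.
oracle_stationary_cov <- function(M, Q, tol = 1e-13, max_iter = 100000) {
  S <- Q
  for (i in seq_len(max_iter)) {
    S_new <- M %*% S %*% t(M) + Q
    if (max(abs(S_new - S)) < tol) return(S_new)
    S <- S_new
  }
  stop("oracle did not converge")
}

# Population joint covariance of (y_t, y_t+1) on the standardized scale for
# a contemporaneous + lag-1 structural model.
oracle_joint_cov <- function(C, a, innovation_sd = NULL) {
  n <- nrow(C)
  IC <- solve(diag(n) - C)
  M <- IC %*% diag(a, n)
  s2 <- if (is.null(innovation_sd)) rep(1, n) else innovation_sd^2
  Q <- IC %*% diag(s2, n) %*% t(IC)
  Sst <- oracle_stationary_cov(M, Q)
  D <- diag(1 / sqrt(diag(Sst)))
  R <- D %*% Sst %*% D
  Mt <- D %*% M %*% solve(D)
  rbind(cbind(R, t(Mt %*% R)), cbind(Mt %*% R, R))
}

# Build a usem_panel directly from a list of matrices (one cohort each or
# explicit metadata), bypassing the simulator.
make_panel <- function(mats, cohort = NULL, sex = NULL, node_names = NULL) {
  if (is.null(node_names)) node_names <- colnames(mats[[1]])
  if (is.null(node_names)) {
    node_names <- paste0("R", seq_len(ncol(mats[[1]])))
    mats <- lapply(mats, function(m) { colnames(m) <- node_names; m })
  }
  if (is.null(cohort)) cohort <- rep(1L, length(mats))
  if (is.null(sex)) sex <- rep(c("F", "M"), length.out = length(mats))
  meta <- data.frame(id = sprintf("s%03d", seq_along(mats)),
                     cohort = cohort, sex = sex, stringsAsFactors = FALSE)
  usemnet:::new_panel(mats, meta, node_names)
}

# Small two-node chain configuration: A -> B with contemporaneous weight c.
chain_config <- function(c = 0.5, a = 0.3, nsub = 4, T = 400, seed = 1) {
  C <- matrix(0, 2, 2); C[2, 1] <- c
  sim_config(c("A", "B"), contemporaneous_coeffs = C, auto_coeffs = a,
             n_cohorts = 1, subjects_per_cohort = nsub,
             timepoints_per_subject = T, seed = seed)
}

# Three-node chain A -> B -> C with fixed weights, one cohort.
three_node_config <- function(nsub = 4, T = 500, seed = 1, a = 0.3,
                              w1 = 0.5, w2 = 0.4) {
  C <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  C["B", "A"] <- w1
  C["C", "B"] <- w2
  sim_config(c("A", "B", "C"), contemporaneous_coeffs = C, auto_coeffs = a,
             n_cohorts = 1, subjects_per_cohort = nsub,
             timepoints_per_subject = T, seed = seed)
}

three_node_model <- function() {
  build_usem(c("A", "B", "C"),
             data.frame(source = c("A", "B"), target = c("B", "C")))
}

# Covariances from a simulated config, optional censoring off.
covs_of <- function(config, censor = FALSE) {
  prepare_panel(simulate_panel(config), censor = censor)$covs
}
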