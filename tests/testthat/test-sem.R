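test_that("parameter registry and degrees of freedom follow the path expansion", {
  nodes <- dmn_nodes()$name
  ref <- dmn_reference_model()
  m13 <- build_usem(nodes, ref$edges[, c("source", "target")])
  acc <- usem_df(m13, 6, "free")
  expect_equal(acc$q, 6 * (13 * 3 + 9 + 18))   # 396
  expect_equal(acc$df, 630L)
  null <- usem_df(build_usem(nodes), 6, "free")
  expect_equal(null$q, 162)
  expect_equal(null$df, 864L)
  two <- usem_df(build_usem(c("A", "B"),
                            data.frame(source = "A", target = "B")), 1)
  expect_equal(two$q, 9)
  expect_equal(two$df, 1L)
  # a bidirectional edge contributes both triples
  bi <- build_usem(c("A", "B"),
                   data.frame(source = "A", target = "B", bidirectional = TRUE))
  expect_equal(usem_df(bi, 1)$q, 12)
})

test_that("malformed edge lists are rejected", {
  expect_error(build_usem(c("A", "B"),
                          data.frame(source = c("A", "A"),
                                     target = c("B", "B"))), "duplicate")
  expect_error(build_usem(c("A", "B"),
                          data.frame(source = "A", target = "A")), "self")
  expect_error(build_usem(c("A", "B"),
                          data.frame(source = "A", target = "Z")),
               "not in node set")
})

test_that("implied covariance reproduces hand algebra", {
  expect_equal(implied_covariance(matrix(0, 3, 3), diag(3)), diag(3))
  a <- 0.4
  A <- matrix(c(0, 0, a, 0), 2, 2, byrow = TRUE)
  expect_equal(implied_covariance(A, diag(2)),
               matrix(c(1, a, a, 1 + a^2), 2, 2))
  # symmetry for arbitrary parameters
  set.seed(2)
  A2 <- matrix(rnorm(16, 0, 0.2), 4, 4); diag(A2) <- 0
  S2 <- diag(exp(rnorm(4)))
  Sig <- implied_covariance(A2, S2)
  expect_lt(max(abs(Sig - t(Sig))), 1e-12)
  # an ill-posed feedback loop is reported
  bad <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(implied_covariance(bad, diag(2)), "cycle")
})

test_that("a saturated model fits perfectly with zero degrees of freedom", {
  cfg <- sim_config("A", auto_coeffs = 0.5, n_cohorts = 1,
                    subjects_per_cohort = 2, timepoints_per_subject = 300,
                    seed = 4)
  covs <- covs_of(cfg)
  f <- fit_ml(build_usem("A"), covs, ci = FALSE)
  expect_equal(f$df, 0L)
  expect_lt(abs(f$chisq), 1e-5)
})

test_that("the fit is exact on a population covariance from the model family", {
  C <- matrix(0, 2, 2); C[2, 1] <- 0.5
  S_pop <- oracle_joint_cov(C, 0.3)
  covs <- structure(list(S = list(`1` = S_pop), n_per_cohort = c(`1` = 5000),
                         n_total = 5000, node_names = c("A", "B")),
                    class = "usem_covs")
  f <- fit_ml(build_usem(c("A", "B"), data.frame(source = "A", target = "B")),
              covs, ci = FALSE)
  expect_lt(f$chisq, 1e-6)
  d_hat <- f$estimates$estimate[f$estimates$path_type == "lagged"]
  sds <- sqrt(diag(oracle_stationary_cov(solve(diag(2) - C) %*% diag(0.3, 2),
                                         solve(diag(2) - C) %*% t(solve(diag(2) - C)))))
  expect_equal(d_hat, 0.5 * sds[1] / sds[2], tolerance = 1e-6)
})

test_that("parameters are recovered within 3 SE on model-generated data", {
  cfg <- three_node_config(nsub = 2, T = 5000, seed = 6)
  covs <- covs_of(cfg)
  f <- fit_ml(three_node_model(), covs)
  est <- f$estimates[f$estimates$path_type == "lagged", ]
  truth <- c(0.5, 0.4)   # unit stationary scale differs; rescale by sds
  C <- matrix(0, 3, 3); C[2, 1] <- 0.5; C[3, 2] <- 0.4
  IC <- solve(diag(3) - C)
  sds <- sqrt(diag(oracle_stationary_cov(IC %*% diag(0.3, 3), IC %*% t(IC))))
  truth_std <- c(0.5 * sds[1] / sds[2], 0.4 * sds[2] / sds[3])
  expect_true(all(abs(est$estimate - truth_std) <= 3 * est$se))
  # gradient at the reported optimum is numerically zero
  expect_lt(f$diagnostics$grad_norm, 1e-5)
})

test_that("chi-square is calibrated for a correctly specified null model", {
  set.seed(30)
  ratios <- suppressWarnings(replicate(20, {
    # white noise satisfies both the target and the independence null, so
    # the CFI clamp warning is expected
    mats <- lapply(1:2, function(i) matrix(rnorm(200 * 3), 200, 3))
    covs <- prepare_panel(make_panel(mats), censor = FALSE)$covs
    f <- fit_ml(build_usem(c("R1", "R2", "R3")), covs, se = FALSE, ci = FALSE)
    f$chisq / f$df
  }))
  expect_lt(abs(mean(ratios) - 1), 0.25)
})

test_that("freeing a path never worsens the fit (nesting monotonicity)", {
  set.seed(41)
  for (rep in 1:3) {
    cfg <- three_node_config(nsub = 2, T = 400, seed = 40 + rep)
    covs <- covs_of(cfg)
    base <- fit_ml(three_node_model(), covs, se = FALSE, ci = FALSE)
    bigger <- build_usem(c("A", "B", "C"),
                         data.frame(source = c("A", "B", "A"),
                                    target = c("B", "C", "C")))
    f2 <- fit_ml(bigger, covs, se = FALSE, ci = FALSE)
    expect_lte(f2$chisq, base$chisq + 1e-6)
    expect_equal(base$df - f2$df, 3L)
  }
})

test_that("equality constraints cost fit exactly as many df as they save parameters", {
  cfg <- sim_config(c("A", "B"), contemporaneous_coeffs = {
    C <- matrix(0, 2, 2); C[2, 1] <- 0.4; C
  }, auto_coeffs = 0.3, n_cohorts = 3, subjects_per_cohort = 3,
  timepoints_per_subject = 250, seed = 8)
  covs <- covs_of(cfg)
  m <- build_usem(c("A", "B"), data.frame(source = "A", target = "B"))
  free <- fit_ml(m, covs, "free", se = FALSE, ci = FALSE)
  eq <- fit_ml(m, covs, "equal", se = FALSE, ci = FALSE)
  expect_gte(eq$chisq, free$chisq - 1e-6)
  expect_equal(eq$df - free$df, free$q - eq$q)
})

test_that("orientation comparison prefers the generating direction", {
  cfg <- three_node_config(nsub = 4, T = 1500, seed = 10, w2 = 0)
  covs <- covs_of(cfg)
  m <- build_usem(c("A", "B", "C"),
                  data.frame(source = "A", target = "B"))
  cmp <- fit_bidirectional_variants(
    m, covs, data.frame(source = "A", target = "B"))
  tab <- cmp$comparison
  expect_lt(tab$bcc[tab$variant == "A -> B"],
            tab$bcc[tab$variant == "B -> A"])
  # the feedback variant nests both orientations
  expect_lte(tab$chisq[tab$variant == "feedback"],
             min(tab$chisq[tab$variant %in% c("A -> B", "B -> A")]) + 1e-6)
  # deterministic ranking
  cmp2 <- fit_bidirectional_variants(
    m, covs, data.frame(source = "A", target = "B"))
  expect_identical(cmp$comparison, cmp2$comparison)
})
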