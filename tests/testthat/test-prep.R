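make_noise_panel <- function(nsub = 1, T = 200, n = 9, seed = 1) {
  set.seed(seed)
  make_panel(lapply(seq_len(nsub), function(i) matrix(rnorm(T * n), T, n)))
}

test_that("spike ladder censors multi-ROI jumps and spares single-ROI ones", {
  panel <- make_noise_panel(T = 200, n = 9, seed = 21)
  y <- panel$subjects[[1]]
  sds <- apply(y, 2, sd)
  # pulse of ~15 SD in exactly 2 ROIs at t = 50 (series SD inflates a
  # little, leaving the jump still far above the 7-SD rung)
  y[50, 1:2] <- y[50, 1:2] + 15 * sds[1:2]
  panel$subjects[[1]] <- y
  out <- censor_spikes(panel)
  expect_false(out$mask[[1]][50])
  # data unchanged, only masks updated
  expect_identical(out$subjects, panel$subjects)

  panel2 <- make_noise_panel(T = 200, n = 9, seed = 22)
  y2 <- panel2$subjects[[1]]
  y2[50, 1] <- y2[50, 1] + 15 * sd(y2[, 1])
  panel2$subjects[[1]] <- y2
  out2 <- censor_spikes(panel2)
  expect_true(all(out2$mask[[1]]))   # one ROI is below every rung's count
})

test_that("the lowest ladder rung fires only with six affected ROIs", {
  # deterministic series: alternating +-1 (diffs are exactly 2 SDs), with a
  # jump added on top of the natural diff at t = 100 in six ROIs, sized so
  # the deviation lands between the 3-SD and 4-SD rungs
  base <- rep(c(-1, 1), length.out = 300)
  jump <- 1.5 * sign(base[295] - base[294])   # level shift over a short tail
  mats <- matrix(base, 300, 9)
  mats[295:300, 1:6] <- mats[295:300, 1:6] + jump
  out <- censor_spikes(make_panel(list(mats)))
  expect_false(out$mask[[1]][295])
  expect_equal(sum(!out$mask[[1]]), 1L)
  # the same jump across only five ROIs meets no rung
  mats5 <- matrix(base, 300, 9)
  mats5[295:300, 1:5] <- mats5[295:300, 1:5] + jump
  expect_true(all(censor_spikes(make_panel(list(mats5)))$mask[[1]]))
})

test_that("constant series make the censoring filter fail loudly", {
  panel <- make_noise_panel(T = 50, n = 3, seed = 2)
  panel$subjects[[1]][, 2] <- 1
  expect_error(censor_spikes(panel), "zero SD")
})

test_that("a 120-subject fixture with 84 two-point artifacts keeps 17832 points", {
  # 120 subjects x 150 time points = 18000; each isolated pulse censors the
  # spiked point and its successor, so 84 pulses remove 168 points
  spikes <- list()
  set.seed(99)
  subj <- sample(1:120, 84)
  for (i in seq_along(subj))
    spikes[[i]] <- list(subject = subj[i], time = 10 + i, rois = 1:3,
                        amplitude = 18)
  cfg <- sim_config(paste0("R", 1:9), n_cohorts = 6, subjects_per_cohort = 20,
                    timepoints_per_subject = 150, burn_in = 0,
                    spike_spec = spikes, seed = 31)
  panel <- censor_spikes(simulate_panel(cfg))
  expect_equal(sum(unlist(panel$mask)), 17832L)
  # injected spikes are recovered exactly: censored set is the union of
  # each spiked point and its successor
  for (sp in spikes) {
    m <- panel$mask[[sp$subject]]
    expect_false(m[sp$time])
    expect_false(m[sp$time + 1])
  }
})

test_that("standardization follows the worked convention and is idempotent", {
  panel <- make_panel(list(cbind(A = c(1, 2, 3), B = c(4, 6, 8))))
  out <- standardize_panel(panel)
  expect_equal(out$subjects[[1]][, "A"], c(-1, 0, 1))
  z <- standardize_panel(make_noise_panel(T = 100, n = 4, seed = 3))
  for (j in seq_len(4)) {
    expect_lt(abs(mean(z$subjects[[1]][, j])), 1e-12)
    expect_lt(abs(var(z$subjects[[1]][, j]) - 1), 1e-12)
  }
  expect_equal(standardize_panel(z)$subjects, z$subjects, tolerance = 1e-12)
  # population-variance convention remains available
  pop <- standardize_panel(panel, divisor = "n")
  expect_equal(pop$subjects[[1]][, "A"], c(-1, 0, 1) * sqrt(3 / 2))
})

test_that("standardization uses only uncensored points and rejects degenerate input", {
  panel <- make_noise_panel(T = 100, n = 2, seed = 4)
  panel$mask[[1]][1:10] <- FALSE
  out <- standardize_panel(panel)
  keep <- out$mask[[1]]
  expect_lt(abs(mean(out$subjects[[1]][keep, 1])), 1e-12)
  expect_gt(abs(mean(out$subjects[[1]][, 1])), 1e-12)
  bad <- make_noise_panel(T = 50, n = 2, seed = 5)
  bad$subjects[[1]][, 1] <- 7
  expect_error(standardize_panel(bad), "zero-variance")
})

test_that("lagged pairs respect censoring and subject boundaries", {
  panel <- standardize_panel(make_noise_panel(nsub = 2, T = 150, n = 3, seed = 6))
  lag0 <- build_lagged(panel)
  expect_equal(nrow(lag0$rows[[1]]), 149L)
  expect_equal(lag0$n_total, 2L * 149L)
  panel$mask[[1]][50] <- FALSE
  lag1 <- build_lagged(panel)
  expect_equal(nrow(lag1$rows[[1]]), 147L)  # pairs (49,50) and (50,51) drop
  expect_equal(sum(lag1$n_per_cohort), lag1$n_total)
})

test_that("white-noise cross-block covariances vanish at the sampling rate", {
  panel <- standardize_panel(make_noise_panel(nsub = 4, T = 500, n = 3, seed = 8))
  lag <- build_lagged(panel)
  S <- cov(do.call(rbind, lag$rows))
  cross <- S[1:3, 4:6]
  expect_lt(max(abs(cross)), 3 / sqrt(lag$n_total))
})

test_that("autoregressive order assessment matches known processes", {
  # AR(1) with a = 0.6: lag-1 explains ~36% of variance, lag-2 adds ~0
  cfg <- sim_config("A", auto_coeffs = 0.6, n_cohorts = 1,
                    subjects_per_cohort = 4, timepoints_per_subject = 2000,
                    seed = 13)
  tab <- assess_ar_order(standardize_panel(simulate_panel(cfg)), max_lag = 3)
  expect_lt(abs(tab["A", "lag1"] - 0.36), 0.03)
  expect_lt(tab["A", "lag2"], 0.01)
  # white noise: nothing explained at any lag
  wn <- assess_ar_order(standardize_panel(make_noise_panel(T = 2000, seed = 14)),
                        max_lag = 5)
  expect_lt(max(wn), 0.01)
  # AR(2): increments follow the closed-form partial autocorrelations
  set.seed(15)
  x <- as.numeric(arima.sim(list(ar = c(0.5, 0.3)), 5000))
  tab2 <- assess_ar_order(make_panel(list(cbind(A = x))), max_lag = 3)
  pacf_th <- ARMAacf(ar = c(0.5, 0.3), lag.max = 3, pacf = TRUE)
  incr_th <- pacf_th^2 * cumprod(c(1, (1 - pacf_th^2)[-3]))
  expect_gt(tab2["A", "lag2"], 0.03)   # theory: ~0.044
  expect_lt(max(abs(tab2["A", 1:3] - incr_th)), 0.05)
  expect_error(assess_ar_order(make_noise_panel(T = 4), max_lag = 5),
               "max_lag")
})

test_that("cohort covariances match hand computation and flag degeneracy", {
  rows <- matrix(c(1, 2, 0, 1,
                   2, 1, 1, 0,
                   0, 0, 2, 2,
                   1, 1, 1, 1), 4, 4, byrow = TRUE)
  lag <- structure(list(rows = list(rows),
                        meta = data.frame(id = "s1", cohort = 1, sex = "F"),
                        node_names = c("A", "B"),
                        n_per_cohort = c(`1` = 4L), n_total = 4L),
                   class = "usem_lagged")
  hand <- crossprod(sweep(rows, 2, colMeans(rows))) / 3
  expect_warning(cc <- cohort_covariances(lag), "singular")
  expect_equal(unname(cc$S[[1]]), hand)
  expect_true(isSymmetric(cc$S[[1]]))
})

test_that("simulated stationary panel covariance matches the Lyapunov oracle", {
  cfg <- three_node_config(nsub = 4, T = 4000, seed = 16)
  covs <- covs_of(cfg)
  C <- matrix(0, 3, 3); C[2, 1] <- 0.5; C[3, 2] <- 0.4
  joint <- oracle_joint_cov(C, 0.3)
  expect_lt(max(abs(covs$S[[1]] - joint)), 5 / sqrt(covs$n_total))
})

test_that("prep bookkeeping is order-independent", {
  panel <- make_noise_panel(nsub = 4, T = 100, n = 3, seed = 17)
  panel$subjects[[2]][30, 1:2] <- panel$subjects[[2]][30, 1:2] + 12
  masks1 <- censor_spikes(panel)$mask
  perm <- c(3, 1, 4, 2)
  pp <- usemnet:::new_panel(panel$subjects[perm], panel$meta[perm, ],
                            panel$node_names, panel$mask[perm])
  masks2 <- censor_spikes(pp)$mask
  expect_identical(masks1[perm], masks2)
  # covariance assembly commutes with subject permutation within a cohort
  c1 <- prepare_panel(panel, censor = FALSE)$covs
  pp$meta$cohort <- rep(1L, 4)
  c2 <- prepare_panel(pp, censor = FALSE)$covs
  expect_equal(c1$S[[1]], c2$S[[1]], tolerance = 1e-12)
})
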