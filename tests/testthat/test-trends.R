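ref_trend_table <- function() {
  ref <- dmn_reference_model()
  co <- ref$coefficients
  colnames(co) <- paste0("cohort_", seq_len(ncol(co)))
  cbind(ref$edges[, c("source", "target")], as.data.frame(co))
}

test_that("decade correlations reproduce the published coefficient vectors", {
  tr <- decade_trends(ref_trend_table())
  r_of <- function(s, t) tr$r[tr$source == s & tr$target == t]
  expect_equal(round(r_of("MPFG", "LMFG"), 2), 0.99)
  expect_equal(round(r_of("LIPL", "RIPL"), 2), -0.97)
  expect_equal(round(cor(c(0.11, 0.24, 0.30, 0.34, 0.36, 0.47), 1:6), 2),
               0.97)   # published female MPFG-LMFG series
})

test_that("eight of thirteen edges are classified as significant trends", {
  tr <- decade_trends(ref_trend_table())
  expect_equal(sum(tr$class != "flat"), 8L)
  pr <- pair_by_receiver(tr)
  expect_setequal(pr$paired, c("LMFG", "RIPL", "LMTG", "RMTG"))
  expect_length(pr$unpaired, 0)
})

test_that("trend correlation is invariant to affine cohort axes", {
  tab <- ref_trend_table()
  a <- decade_trends(tab, cohort_axis = 1:6)
  b <- decade_trends(tab, cohort_axis = 24.5 + 10 * (0:5))
  expect_equal(a$r, b$r, tolerance = 1e-12)
  expect_identical(a$class, b$class)
})

test_that("degenerate and unpaired trend tables are handled", {
  tab <- data.frame(source = c("A", "B"), target = c("B", "C"),
                    cohort_1 = c(0.3, 0.1), cohort_2 = c(0.3, 0.2),
                    cohort_3 = c(0.3, 0.3), cohort_4 = c(0.3, 0.4),
                    cohort_5 = c(0.3, 0.5), cohort_6 = c(0.3, 0.6))
  tr <- decade_trends(tab)
  expect_true(is.na(tr$r[1]))
  expect_equal(tr$class[1], "flat")
  expect_equal(tr$class[2], "rising")
  pr <- pair_by_receiver(tr)
  expect_length(pr$paired, 0)
  expect_equal(pr$unpaired, "C")
  allflat <- pair_by_receiver(decade_trends(tab[1, ]))
  expect_length(allflat$paired, 0)
  expect_length(allflat$unpaired, 0)
})

test_that("trend classes recover the sign of generating slopes", {
  # cohort drift on one edge: rising class expected nearly always
  set.seed(55)
  hits <- 0L
  for (rep in 1:20) {
    arr <- array(0, c(2, 2, 6))
    arr[2, 1, ] <- seq(0.1, 0.6, length.out = 6)
    cfg <- sim_config(c("A", "B"), contemporaneous_coeffs = arr,
                      auto_coeffs = 0.3, n_cohorts = 6,
                      subjects_per_cohort = 2, timepoints_per_subject = 150,
                      seed = 100 + rep)
    covs <- covs_of(cfg)
    f <- fit_ml(build_usem(c("A", "B"),
                           data.frame(source = "A", target = "B")),
                covs, se = FALSE, ci = FALSE)
    tr <- decade_trends(f)
    if (tr$class[1] == "rising") hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("sex-split trends flag only truly divergent edges", {
  arrF <- array(0, c(3, 3, 6)); arrM <- array(0, c(3, 3, 6))
  arrF[2, 1, ] <- seq(0.1, 0.6, length.out = 6)   # A -> B drifts for F only
  arrM[2, 1, ] <- 0.35
  arrF[3, 2, ] <- 0.4; arrM[3, 2, ] <- 0.4        # B -> C stable for both
  mk <- function(arr, seed) sim_config(c("A", "B", "C"),
    contemporaneous_coeffs = arr, auto_coeffs = 0.3, n_cohorts = 6,
    subjects_per_cohort = 4, timepoints_per_subject = 400, seed = seed)
  pF <- simulate_panel(mk(arrF, 61)); pM <- simulate_panel(mk(arrM, 62))
  pF$meta$sex <- "F"
  pM$meta$sex <- "M"; pM$meta$id <- paste0("m", pM$meta$id)
  panel <- usemnet:::new_panel(c(pF$subjects, pM$subjects),
                               rbind(pF$meta, pM$meta),
                               pF$node_names, c(pF$mask, pM$mask))
  m <- build_usem(c("A", "B", "C"),
                  data.frame(source = c("A", "B"), target = c("B", "C")))
  st <- sex_split_trends(panel, m, censor = FALSE)
  expect_equal(st$F$class[st$F$source == "A"], "rising")
  expect_equal(st$M$class[st$M$source == "A"], "flat")
  expect_equal(nrow(st$divergent), 1L)
  expect_equal(st$divergent$source, "A")
  # identical per-sex data give identical tables
  pM2 <- pF
  pF$meta$sex <- "F"
  pM2$meta$sex <- "M"; pM2$meta$id <- paste0("m", pM2$meta$id)
  same <- usemnet:::new_panel(c(pF$subjects, pM2$subjects),
                              rbind(pF$meta, pM2$meta),
                              pF$node_names, c(pF$mask, pM2$mask))
  st2 <- sex_split_trends(same, m, censor = FALSE)
  expect_equal(st2$F$r, st2$M$r, tolerance = 1e-10)
  # a cohort missing one sex errors
  broken <- usemnet:::new_panel(pF$subjects, pF$meta, pF$node_names, pF$mask)
  expect_error(sex_split_trends(broken, m), NA)  # single sex level is fine
  mixed <- panel; mixed$meta$sex[mixed$meta$cohort == 3 &
                                   mixed$meta$sex == "M"] <- "F"
  expect_error(sex_split_trends(mixed, m, censor = FALSE), "missing a sex")
})

test_that("edge-set overlap probability is exact and matches enumeration", {
  ref <- dmn_reference_model()
  shifted <- ref$edges[, c("source", "target")]
  # build a 13-edge comparison set sharing exactly 10 undirected pairs
  shifted$source[1] <- "vACC"; shifted$target[1] <- "RIPL"
  shifted$source[2] <- "vACC"; shifted$target[2] <- "LIPL"
  shifted$source[3] <- "RMTG"; shifted$target[3] <- "RIPL"
  ov <- edge_overlap_probability(ref$edges, shifted, 9)
  expect_equal(ov$n_possible, 36)
  expect_equal(ov$overlap, 10)
  expect_equal(signif(ov$p_value, 2), 2.3e-4)
  expect_equal(ov$p_value,
               phyper(9, 13, 36 - 13, 13, lower.tail = FALSE),
               tolerance = 1e-12)
  # zero overlap has probability 1
  disjoint <- data.frame(source = "vACC", target = "LMFG")
  base <- data.frame(source = "pC", target = "PCC")
  expect_equal(edge_overlap_probability(base, disjoint, 9)$p_value, 1)
  # exhaustive enumeration oracle on a small instance
  nodes4 <- c("a", "b", "c", "d")
  pairs4 <- t(combn(nodes4, 2))
  A <- data.frame(source = pairs4[1:3, 1], target = pairs4[1:3, 2])
  for (pick in list(1:3, c(1, 4, 6), 4:6)) {
    B <- data.frame(source = pairs4[pick, 1], target = pairs4[pick, 2])
    k <- edge_overlap_probability(A, B, 4)$overlap
    draws <- combn(6, 3)
    tail_exact <- mean(apply(draws, 2, function(d)
      length(intersect(d, 1:3)) >= k))
    expect_equal(edge_overlap_probability(A, B, 4)$p_value, tail_exact,
                 tolerance = 1e-12)
  }
  # tail probability is monotone decreasing in the observed overlap
  p_at <- function(k) sum(vapply(k:13, function(x)
    choose(13, x) * choose(23, 13 - x), 0)) / choose(36, 13)
  expect_true(all(diff(vapply(0:13, p_at, 0)) < 0))
  expect_error(edge_overlap_probability(
    data.frame(source = rep("a", 7), target = letters[2:8]),
    A, 3), "larger")
})
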