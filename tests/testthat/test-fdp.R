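toy_sheet <- function(n_case, n_control) {
  data.frame(sample_id = sprintf("s%d", seq_len(n_case + n_control)),
             group = rep(c("case", "control"), c(n_case, n_control)),
             stringsAsFactors = FALSE)
}

toy_beta <- function(n_probes, sheet, seed = 1) {
  set.seed(seed)
  matrix(runif(n_probes * nrow(sheet)), n_probes, nrow(sheet),
         dimnames = list(paste0("p", seq_len(n_probes)), sheet$sample_id))
}

test_that("exhaustive 2v2 null has exactly choose(4,2) = 6 rows", {
  sheet <- toy_sheet(2, 2)
  beta <- toy_beta(5, sheet)
  nul <- build_null(beta, sheet, exhaustive = TRUE)
  expect_equal(nul$B, 6)
  expect_true(nul$exhaustive)
  # every row ascending
  expect_true(all(apply(nul$sorted_p, 1, function(r) all(diff(r) >= 0))))
})

test_that("the identity permutation's row is the sorted observed p-vector", {
  sheet <- toy_sheet(3, 3)
  beta <- toy_beta(8, sheet)
  nul <- build_null(beta, sheet, exhaustive = TRUE)
  sc <- probe_scan(beta, sheet)
  obs_sorted <- sort(sc$p_value)
  hit <- apply(nul$sorted_p, 1, function(r) isTRUE(all.equal(r, obs_sorted)))
  expect_true(any(hit))
})

test_that("sampling mode is seed-reproducible", {
  sheet <- toy_sheet(5, 6)
  beta <- toy_beta(30, sheet)
  n1 <- build_null(beta, sheet, B = 50, seed = 9)
  n2 <- build_null(beta, sheet, B = 50, seed = 9)
  expect_identical(n1$sorted_p, n2$sorted_p)
})

test_that("exhaustive cutoffs are seed-invariant and matched by sampling
           with B = all assignments", {
  sheet <- toy_sheet(3, 3)   # C(6,3) = 20 assignments
  beta <- toy_beta(12, sheet)
  e1 <- build_null(beta, sheet, exhaustive = TRUE, seed = 1)
  e2 <- build_null(beta, sheet, exhaustive = TRUE, seed = 999)
  expect_identical(e1$sorted_p, e2$sorted_p)
  expect_warning(s1 <- build_null(beta, sheet, B = 20, seed = 5),
                 "exhaustive")
  expect_identical(s1$sorted_p, e1$sorted_p)
  for (al in c(0.1, 0.25, 0.5))
    expect_equal(fdp_cutoff(s1, 0, al), fdp_cutoff(e1, 0, al))
})

test_that("gamma = 0 cutoff is the ceil(alpha*B)-th smallest minimum", {
  sheet <- toy_sheet(4, 5)
  beta <- toy_beta(20, sheet)
  nul <- build_null(beta, sheet, B = 100, seed = 2)
  minima <- nul$sorted_p[, 1]
  expect_equal(fdp_cutoff(nul, 0, 0.05), sort(minima)[5])
  expect_equal(fdp_cutoff(nul, 0, 0.5), sort(minima)[50])
})

test_that("degenerate null: all permutation minima equal -> constant cutoff", {
  nul <- structure(list(sorted_p = matrix(c(0.25, 0.5), nrow = 10, ncol = 2,
                                          byrow = TRUE),
                        B = 10L, K = 2L, probe_ids = c("p1", "p2"),
                        n_case = 2L, n_control = 2L, exhaustive = FALSE,
                        seed = 1L),
                   class = "permutation_null")
  for (al in c(0.1, 0.3, 0.9))
    expect_equal(fdp_cutoff(nul, 0, al), 0.25)
})

test_that("alpha below 1/B is rejected with the minimum feasible alpha", {
  sheet <- toy_sheet(3, 3)
  nul <- build_null(toy_beta(5, sheet), sheet, exhaustive = TRUE)
  expect_error(fdp_cutoff(nul, 0, 1e-9), "minimum feasible alpha")
})

test_that("2v2 exhaustive toy: no probe beats the attainable floor", {
  # smallest attainable exact p is 1/3, and at alpha <= 1/6 the cutoff is
  # the smallest permutation minimum, which observed p cannot strictly beat
  sheet <- toy_sheet(2, 2)
  beta <- toy_beta(6, sheet, seed = 3)
  nul <- build_null(beta, sheet, exhaustive = TRUE)
  sc <- probe_scan(beta, sheet)
  res <- call_significant(sc, nul, gammas = 0, alphas = 1 / 6)
  expect_equal(unname(res$counts[1, 1]), 0L)
})

test_that("significant sets are monotone in alpha and gamma", {
  s <- small_cohort(n_probes = 300, n_spiked = 15)
  sc <- probe_scan(s$beta, s$sheet)
  nul <- build_null(s$beta, s$sheet, B = 200, seed = 4)
  res <- call_significant(sc, nul, gammas = c(0, 0.1, 0.3),
                          alphas = c(0.01, 0.05, 0.25))
  cnt <- res$counts
  expect_true(all(apply(cnt, 1, diff) >= 0))  # along alpha
  expect_true(all(apply(cnt, 2, diff) >= 0))  # along gamma
  # set inclusion along alpha at gamma = 0
  expect_true(all(res$significant[[1]][[1]] %in% res$significant[[1]][[3]]))
})

test_that("permutations exclude vus samples from the null", {
  s <- small_cohort(n_probes = 40, n_spiked = 0)
  nul <- build_null(s$beta, s$sheet, B = 25, seed = 1)
  expect_equal(nul$n_case + nul$n_control, 29)  # 31 samples minus 2 vus
})

test_that("probe-set mismatch between scan and null is an error", {
  s <- small_cohort(n_probes = 30, n_spiked = 0)
  sc <- probe_scan(s$beta, s$sheet)
  nul <- build_null(s$beta[1:20, ], s$sheet, B = 10, seed = 1)
  expect_error(call_significant(sc, nul), "probe sets")
})

test_that("spiked probes are recovered with no false calls", {
  s <- simulate_cohort(cohort_config(n_probes = 1000, n_spiked = 25,
                                     spike_delta = -0.4, seed = 13))
  sc <- probe_scan(s$beta, s$sheet)
  nul <- build_null(s$beta, s$sheet, B = 400, seed = 13)
  res <- call_significant(sc, nul, gammas = 0, alphas = 0.005)
  called <- res$significant[[1]][[1]]
  spiked <- s$truth$probe_id[s$truth$is_spiked]
  expect_gte(sum(called %in% spiked), 23)
  expect_equal(sum(!called %in% spiked), 0)
})
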