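make_sheet <- function(n_case, n_control, n_vus = 0) {
  data.frame(
    sample_id = c(sprintf("ca%d", seq_len(n_case)),
                  sprintf("co%d", seq_len(n_control)),
                  if (n_vus > 0) sprintf("v%d", seq_len(n_vus))),
    group = rep(c("case", "control", "vus"), c(n_case, n_control, n_vus)),
    stringsAsFactors = FALSE)
}

test_that("constant probes give p = 1 and zero effects", {
  sheet <- make_sheet(4, 5)
  beta <- matrix(0.5, 2, 9, dimnames = list(c("p1", "p2"), sheet$sample_id))
  sc <- probe_scan(beta, sheet)
  expect_equal(sc$p_value, c(1, 1))
  expect_equal(sc$delta_beta, c(0, 0))
  expect_equal(sc$delta_z, c(0, 0))
})

test_that("delta beta is reproduced from printed group means", {
  # top published loci: case/control means 0.41/0.89, 0.26/0.71, 0.24/0.52
  sheet <- make_sheet(10, 19)
  mk <- function(mc, mo) {
    # vectors with exactly those means
    c(rep(mc, 9), mc, rep(mo, 18), mo)
  }
  beta <- rbind(cg02630888 = mk(0.41, 0.89),
                cg03387723 = mk(0.26, 0.71),
                cg16743289 = mk(0.24, 0.52))
  colnames(beta) <- sheet$sample_id
  sc <- probe_scan(beta, sheet)
  expect_equal(sc$delta_beta, c(-0.48, -0.45, -0.28))
})

test_that("vus samples are excluded from the test but summarised", {
  sheet <- make_sheet(3, 3, 2)
  set.seed(1)
  base <- matrix(runif(8), 1, 8, dimnames = list("p1", sheet$sample_id))
  sc1 <- probe_scan(base, sheet)
  # perturbing only the vus values leaves p and delta untouched
  base2 <- base
  base2[1, 7:8] <- c(0.99, 0.98)
  sc2 <- probe_scan(base2, sheet)
  expect_equal(sc1$p_value, sc2$p_value)
  expect_equal(sc1$delta_beta, sc2$delta_beta)
  expect_false(isTRUE(all.equal(sc1$mean_vus, sc2$mean_vus)))
})

test_that("scan p-values match the enumeration oracle probe by probe", {
  sheet <- make_sheet(4, 5)
  set.seed(8)
  beta <- matrix(runif(9 * 6), 6, 9,
                 dimnames = list(paste0("p", 1:6), sheet$sample_id))
  sc <- probe_scan(beta, sheet)
  for (i in 1:6)
    expect_equal(sc$p_value[i],
                 mwu_enum_p(beta[i, 1:4], beta[i, 5:9]))
})

test_that("scan is invariant to row and column order", {
  s <- small_cohort(n_probes = 60, n_spiked = 5)
  sc <- probe_scan(s$beta, s$sheet)
  perm_rows <- sample(nrow(s$beta)); perm_cols <- sample(ncol(s$beta))
  sc2 <- probe_scan(s$beta[perm_rows, perm_cols], s$sheet)
  sc2 <- sc2[match(sc$probe_id, sc2$probe_id), ]
  expect_equal(sc$p_value, sc2$p_value)
  expect_equal(sc$delta_beta, sc2$delta_beta)
})

test_that("relabelling case and control negates effects, preserves p", {
  sheet <- make_sheet(4, 6)
  flipped <- sheet
  flipped$group <- ifelse(sheet$group == "case", "control", "case")
  set.seed(2)
  beta <- matrix(runif(10 * 5), 5, 10,
                 dimnames = list(paste0("p", 1:5), sheet$sample_id))
  a <- probe_scan(beta, sheet); b <- probe_scan(beta, flipped)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$delta_beta, -b$delta_beta)
  expect_equal(a$delta_z, -b$delta_z)
})

test_that("probes with too few values are flagged untestable, not dropped", {
  sheet <- make_sheet(3, 3)
  beta <- matrix(runif(12), 2, 6,
                 dimnames = list(c("p1", "p2"), sheet$sample_id))
  beta[2, 1:2] <- NA  # one case value left
  sc <- probe_scan(beta, sheet)
  expect_equal(nrow(sc), 2)
  expect_true(sc$testable[1]); expect_false(sc$testable[2])
  expect_true(is.na(sc$p_value[2]))
})

test_that("delta_z is positive for methylation loss, near published scale", {
  # complete separation at the 10v19 design gives delta_z around 1.8-2.0
  sheet <- make_sheet(10, 19)
  set.seed(4)
  beta <- matrix(c(runif(10, 0.35, 0.47), runif(19, 0.84, 0.94)), 1, 29,
                 dimnames = list("p1", sheet$sample_id))
  sc <- probe_scan(beta, sheet)
  expect_gt(sc$delta_z, 1.5); expect_lt(sc$delta_z, 2.2)
  expect_lt(sc$delta_beta, 0)
})

test_that("robustness enumeration counts the case x relative product", {
  # two one-case families, one relative: a single combination
  sheet <- data.frame(
    sample_id = c("c1", "c2", paste0("u", 1:4), "r1"),
    group = c("case", "case", rep("control", 5)),
    family_id = c("F1", "F2", rep(NA, 5)),
    relative_pool = c(FALSE, FALSE, rep(FALSE, 4), TRUE))
  set.seed(5)
  beta <- matrix(runif(7 * 3), 3, 7,
                 dimnames = list(paste0("p", 1:3), sheet$sample_id))
  rb <- subset_robustness(beta, sheet, alpha_levels = 0.5)
  expect_equal(rb$n_combinations, 1)

  # study design: families (3,2,2,2,1) x 3 relatives = 72 combinations
  s <- small_cohort(n_probes = 30, n_spiked = 3)
  rb2 <- subset_robustness(s$beta, s$sheet, alpha_levels = 0.05)
  expect_equal(rb2$n_combinations, 72)
  expect_equal(length(rb2$combinations[[1]]$cases), 5)
  expect_equal(length(rb2$combinations[[1]]$controls), 17)
})

test_that("strong spikes survive every robustness combination", {
  s <- simulate_cohort(cohort_config(n_probes = 150, n_spiked = 8,
                                     spike_delta = -0.5,
                                     baseline_dispersion = 0.15, seed = 21))
  # full-cohort significant set at the exact-floor level
  sc <- probe_scan(s$beta, s$sheet)
  full_sig <- sc$probe_id[sc$p_value < 1e-4]
  spiked <- s$truth$probe_id[s$truth$is_spiked]
  expect_true(all(spiked %in% full_sig))
  rb <- subset_robustness(s$beta, s$sheet, alpha_levels = 1e-4)
  inter <- rb$intersection[["1e-04"]]
  expect_true(all(spiked %in% inter))
})
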