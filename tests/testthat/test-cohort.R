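test_that("Kruskal-Wallis basics: degenerate and two-group behaviour", {
  out <- kruskal_wallis(list(rep(1, 3), rep(1, 4)))
  expect_equal(out$H, 0); expect_equal(out$p_value, 1)

  # two groups: asymptotically equivalent to the MWU normal approximation
  set.seed(15)
  a <- rnorm(50); b <- rnorm(50, 0.4)
  kw <- kruskal_wallis(list(a, b))
  mw <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                     correct = FALSE)$p.value)
  expect_lt(abs(kw$p_value - mw) / mw, 0.05)
  expect_error(kruskal_wallis(list(rnorm(3))), ">= 2 groups")
})

test_that("exact Kruskal-Wallis matches the enumeration oracle", {
  set.seed(25)
  x <- list(rnorm(3), rnorm(3), rnorm(2))
  out <- kruskal_wallis(x, exact = TRUE)
  # independent oracle: enumerate label assignments directly
  pooled <- unlist(x)
  sizes <- lengths(x)
  h_of <- function(assign) {
    g <- integer(length(pooled))
    for (j in seq_along(assign)) g[assign[[j]]] <- j
    unname(kruskal.test(pooled, factor(g))$statistic)
  }
  splits <- combn(8, 3, simplify = FALSE)
  hs <- c()
  for (f in splits) {
    remaining <- setdiff(1:8, f)
    for (s2 in combn(remaining, 3, simplify = FALSE))
      hs <- c(hs, h_of(list(f, s2, setdiff(remaining, s2))))
  }
  expect_equal(out$p_exact, mean(hs >= out$H - 1e-12))
})

test_that("BH q-values follow the step-up arithmetic", {
  sheet <- data.frame(sample_id = paste0("s", 1:8),
                      sex = rep(c("F", "M"), each = 4))
  set.seed(5)
  beta <- matrix(runif(4 * 8), 4, 8,
                 dimnames = list(paste0("p", 1:4), sheet$sample_id))
  sx <- sex_scan(beta, sheet)
  expect_equal(sx$q_value, p.adjust(sx$p_value, "BH"))
  # frozen step-up example: p = (.01,.02,.03,.04) -> q all 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  # q monotone with p
  ord <- order(sx$p_value)
  expect_true(all(diff(sx$q_value[ord]) >= 0))
})

test_that("identical sexes give q = 1 everywhere", {
  sheet <- data.frame(sample_id = paste0("s", 1:8),
                      sex = rep(c("F", "M"), each = 4))
  beta <- matrix(rep(c(0.3, 0.7), each = 8), 2, 8, byrow = TRUE,
                 dimnames = list(c("p1", "p2"), sheet$sample_id))
  sx <- sex_scan(beta, sheet)
  expect_equal(sx$q_value, c(1, 1))
  expect_error(sex_scan(beta, transform(sheet, sex = "F")), "both sexes")
})

test_that("spiked sex effects attain the smallest q-values", {
  # 48 males vs 51 females, +0.03 shift at 5 of 9 probes
  set.seed(35)
  sheet <- data.frame(sample_id = paste0("s", 1:99),
                      sex = rep(c("M", "F"), c(48, 51)))
  beta <- matrix(rnorm(9 * 99, 0.6, 0.02), 9, 99,
                 dimnames = list(paste0("p", 1:9), sheet$sample_id))
  beta[1:5, sheet$sex == "F"] <- beta[1:5, sheet$sex == "F"] + 0.03
  sx <- sex_scan(beta, sheet)
  expect_equal(sort(order(sx$q_value)[1:5]), 1:5)
  expect_true(all(sx$delta_beta[1:5] > 0))
})

test_that("dosage trend recovers the generating order and direction", {
  d <- simulate_dosage_cohort(dosage_config(seed = 41))
  tr <- dosage_trend(d$beta[1, ], d$sheet, seed = 41)
  expect_gt(tr$rho, 0.7)
  expect_lt(tr$jt_p, 0.01)
  gm <- tr$group_means
  # dose-ordered means: mutation male lowest, then the one-copy groups,
  # 47,XXX highest (45,X and carrier share a dose; either order is fine)
  expect_equal(names(gm)[1], "mutation_male")
  expect_setequal(names(gm)[2:3], c("45,X", "carrier"))
  expect_equal(names(gm)[7], "47,XXX")
  expect_lt(gm[["mutation_male"]], min(gm[["45,X"]], gm[["carrier"]]))
  expect_gt(gm[["47,XXX"]], gm[["46,XY"]])
})

test_that("trend statistics behave under degenerate doses", {
  d <- simulate_dosage_cohort(dosage_config(seed = 1))
  sheet_const <- d$sheet; sheet_const$effective_dose <- 1
  expect_error(dosage_trend(d$beta[1, ], sheet_const, seed = 1), "constant")
  # monotone transform of dose leaves rho unchanged
  tr1 <- dosage_trend(d$beta[1, ], d$sheet, seed = 2)
  sheet2 <- d$sheet; sheet2$effective_dose <- exp(d$sheet$effective_dose)
  tr2 <- dosage_trend(d$beta[1, ], sheet2, seed = 2)
  expect_equal(tr1$rho, tr2$rho)
})

test_that("perfectly monotone betas give rho = 1", {
  gs <- data.frame(label = letters[1:4], kdm5c_copies = 0:3,
                   kdm5d_copies = 0L, n_samples = rep(1L, 4))
  sheet <- simulate_dosage_cohort(dosage_config(group_spec = gs,
                                                noise_sd = 1e-9))$sheet
  beta <- sheet$effective_dose / 10 + 0.1  # strictly increasing with dose
  names(beta) <- sheet$sample_id
  expect_equal(dosage_trend(beta, sheet)$rho, 1)
})

test_that("outlier screen flags case-level losses only", {
  set.seed(45)
  reference <- matrix(rnorm(946, 0.85, 0.03), 1, 946)
  cases <- matrix(rnorm(10, 0.4, 0.05), 1, 10)
  scr <- population_outlier_screen(cases, reference)
  expect_true(all(scr$flags))
  expect_equal(scr$n_flagged, 10)
  # leave-one-out self-screen: under the strict minimum rule only the
  # boundary sample (the global minimum) can flag itself; the robust MAD
  # rule yields no self flags at all
  self_min <- vapply(seq_len(946), function(i)
    any(population_outlier_screen(reference[, i, drop = FALSE],
                                  reference[, -i, drop = FALSE])$flags),
    logical(1))
  expect_lte(sum(self_min), 1)
  self_mad <- vapply(seq_len(946), function(i)
    any(population_outlier_screen(reference[, i, drop = FALSE],
                                  reference[, -i, drop = FALSE],
                                  rule = "mad")$flags),
    logical(1))
  expect_equal(sum(self_mad), 0)
  # query at the reference median is never flagged
  med <- matrix(median(reference), 1, 1)
  expect_false(any(population_outlier_screen(med, reference)$flags))
  # robust MAD rule also separates the two
  scr2 <- population_outlier_screen(cases, reference, rule = "mad")
  expect_true(all(scr2$flags))
  expect_warning(population_outlier_screen(cases, reference[, 1:10,
                                                            drop = FALSE]),
                 "only 10 samples")
})
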