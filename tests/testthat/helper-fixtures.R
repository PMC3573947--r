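# Small simulated cohorts shared across test files. Sizes are kept small so
# the default test run stays fast; the statistical behaviour is the same as
# at array scale.

small_cohort <- function(n_probes = 400, n_spiked = 20, spike_delta = -0.4,
                         seed = 11, ...) {
  simulate_cohort(cohort_config(n_probes = n_probes, n_spiked = n_spiked,
                                spike_delta = spike_delta, seed = seed, ...))
}

# independent oracle: exact two-sided Mann-Whitney p by enumerating every
# assignment of group labels to the pooled observations
mwu_enum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); n_a <- length(a)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n_a * (n_a + 1) / 2
  u_obs <- u_of(seq_len(n_a))
  us <- vapply(combn(n, n_a, simplify = FALSE), u_of, numeric(1))
  lower <- mean(us <= u_obs)
  upper <- mean(us >= u_obs)
  min(1, 2 * min(lower, upper))
}

# independent oracle: two-sided Fisher exact p for a 2x2 table by summing
# hypergeometric probabilities of tables at most as probable
fisher_enum_p <- function(tab) {
  m <- tab[1, 1] + tab[1, 2]   # row 1 margin
  k <- tab[1, 1] + tab[2, 1]   # col 1 margin
  n_tot <- sum(tab)
  xs <- max(0, k - (n_tot - m)):min(m, k)
  probs <- dhyper(xs, m, n_tot - m, k)
  p_obs <- dhyper(tab[1, 1], m, n_tot - m, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
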