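# Shared fixtures and independent oracles, built in code at test time.

# Exhaustive O(n^2) pairwise concordance oracle: comparable pair = the
# strictly shorter observed time ends in an event; concordant when the
# higher-rank subject has the shorter time; rank ties count 1/2.
brute_force_c <- function(time, event, rank) {
  conc <- disc <- tied <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    for (j in seq_len(n)) {
      if (i == j || time[i] >= time[j]) next
      if (rank[i] > rank[j]) conc <- conc + 1
      else if (rank[i] < rank[j]) disc <- disc + 1
      else tied <- tied + 1
    }
  }
  np <- conc + disc + tied
  list(c = if (np == 0) 0.5 else (conc + 0.5 * tied) / np, n_pairs = np)
}

# Breslow partial log-likelihood for a single binary covariate, maximized
# independently of survival::coxph (oracle for cox_two_group).
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (tt in unique(time[event == 1])) {
    at <- time >= tt
    d_idx <- event == 1 & time == tt
    ll <- ll + beta * sum(x[d_idx]) -
      sum(d_idx) * log(sum(exp(beta * x[at])))
  }
  ll
}

# Cohort with planted exponential hazard tiers across labelled subgroups.
# `tiers` assigns each subgroup (row of `keys`) a rate; event times are
# exponential, uncensored unless censor_max is given.
planted_cohort <- function(keys, rates, n_per_subgroup, seed,
                           censor_max = NULL) {
  set.seed(seed)
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    et <- rexp(n_per_subgroup, rates[i])
    ct <- if (is.null(censor_max)) Inf else runif(n_per_subgroup, 0,
                                                  censor_max)
    data.frame(patient_id = sprintf("S%02d_%04d", i,
                                    seq_len(n_per_subgroup)),
               histology = keys$histology[i], t = keys$t[i], n = keys$n[i],
               m = keys$m[i],
               time_months = pmin(et, ct),
               event = as.integer(et <= ct), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# 16 coarse ADC subgroup keys (T x N at M0) for planted-tier clustering.
coarse_keys_16 <- function() {
  g <- expand.grid(t = c("T1", "T2", "T3", "T4"),
                   n = c("N0", "N1", "N2", "N3"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(histology = "ADC", t = g$t, n = g$n, m = "M0",
             stringsAsFactors = FALSE)
}

# 32 coarse subgroup keys: both histologies over the 16 T x N cells.
coarse_keys_32 <- function() {
  k <- coarse_keys_16()
  rbind(k, transform(k, histology = "SCC"))
}

# One fine TNM representative cell per 8th-edition sub-stage, IA..IV.
substage_representatives <- function() {
  data.frame(
    substage = c("IA", "IB", "IIA", "IIB", "IIIA", "IIIB", "IIIC", "IV"),
    t = c("T1a", "T2a", "T2b", "T3", "T4", "T3", "T3", "T3"),
    n = c("N0", "N0", "N0", "N0", "N0", "N2", "N3", "N0"),
    m = c("M0", "M0", "M0", "M0", "M0", "M0", "M0", "M1a"),
    stringsAsFactors = FALSE)
}

# Adjusted Rand index between two partitions (closed-form pair counting).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

random_cohort <- function(n, seed, p_censor = 0.3, lambda = 0.05) {
  set.seed(seed)
  data.frame(time_months = rexp(n, lambda),
             event = rbinom(n, 1, 1 - p_censor))
}

# Every published coarse-granularity reassignment of the modified
# grouping, diffed against the 8th edition.
published_moves <- function() {
  rbind(
    data.frame(histology = "ADC", t = "T1", n = "N1", m = "M0",
               from = "IIB", to = "IB"),
    data.frame(histology = "ADC", t = "T1", n = "N2", m = "M0",
               from = "IIIA", to = "IIA"),
    data.frame(histology = "ADC", t = "T2", n = "N1", m = "M0",
               from = "IIB", to = "IIA"),
    data.frame(histology = "ADC", t = "T3", n = "N0", m = "M0",
               from = "IIB", to = "IIA"),
    data.frame(histology = "ADC", t = "T4", n = "N0", m = "M0",
               from = "IIIA", to = "IIB"),
    data.frame(histology = "ADC", t = "T3", n = "N1", m = "M0",
               from = "IIIA", to = "IIB"),
    data.frame(histology = "ADC", t = "T4", n = "N1", m = "M0",
               from = "IIIA", to = "IIB"),
    data.frame(histology = "ADC", t = "T2", n = "N2", m = "M0",
               from = "IIIA", to = "IIB"),
    data.frame(histology = "ADC", t = "T3", n = "N2", m = "M0",
               from = "IIIB", to = "IIIA"),
    data.frame(histology = "ADC", t = "T4", n = "N2", m = "M0",
               from = "IIIB", to = "IIIA"),
    data.frame(histology = "ADC", t = "T2", n = "N3", m = "M0",
               from = "IIIB", to = "IIIA"),
    data.frame(histology = "ADC", t = "T3", n = "N3", m = "M0",
               from = "IIIC", to = "IIIB"),
    data.frame(histology = "ADC", t = "T4", n = "N3", m = "M0",
               from = "IIIC", to = "IIIB"),
    data.frame(histology = "SCC", t = "T1", n = "N0", m = "M0",
               from = "IA", to = "IB"))
}
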