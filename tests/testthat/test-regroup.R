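test_that("curve sets split by coarse subgroup and enforce the size floor", {
  set.seed(41)
  one <- data.frame(patient_id = sprintf("P%03d", 1:50), histology = "ADC",
                    t = "T1", n = "N0", m = "M0",
                    time_months = rexp(50, 0.05), event = 1)
  s <- build_curve_set(one, min_group_size = 30)
  expect_length(s$curves, 1)
  expect_identical(names(s$curves), "ADC_T1_N0_M0")

  two <- rbind(one,
               data.frame(patient_id = sprintf("Q%03d", 1:10),
                          histology = "SCC", t = "T2", n = "N1", m = "M0",
                          time_months = rexp(10, 0.05), event = 1))
  s2 <- build_curve_set(two, min_group_size = 30)
  expect_length(s2$curves, 1)
  expect_identical(s2$excluded$label, "SCC_T2_N1_M0")
  expect_identical(s2$excluded$n, 10L)
  expect_error(build_curve_set(one, min_group_size = 100),
               "below min_group_size")
  # fine subdescriptors collapse into one coarse subgroup
  fine <- one
  fine$t <- rep(c("T1a", "T1b", "T1c"), length.out = 50)
  expect_identical(names(build_curve_set(fine, 30)$curves), "ADC_T1_N0_M0")
})

test_that("all subgroup curves share the common monthly grid", {
  keys <- coarse_keys_16()
  coh <- planted_cohort(keys, rep(c(0.01, 0.1), each = 8),
                        n_per_subgroup = 40, seed = 42)
  s <- build_curve_set(coh, min_group_size = 30)
  expect_length(s$curves, 16)
  for (cv in s$curves) expect_equal(cv$time, s$grid)
})

test_that("distance matrix is symmetric, zero-diagonal, and orders separations", {
  keys <- coarse_keys_16()[1:3, ]
  coh <- planted_cohort(keys, c(0.01, 0.01, 0.10), n_per_subgroup = 5000,
                        seed = 7)
  s <- build_curve_set(coh)
  d <- build_distance_matrix(s)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0))
  # the two same-rate groups sit much closer than either is to the third
  expect_lt(d[1, 2], d[1, 3])
  expect_lt(d[1, 2], d[2, 3])
  one <- s; one$curves <- one$curves[1]
  one$n_patients <- one$n_patients[1]
  expect_error(build_distance_matrix(one), "at least 2")
  # identical curves at zero distance
  s2 <- s; s2$curves[[2]] <- s2$curves[[1]]
  expect_equal(unname(build_distance_matrix(s2)[1, 2]), 0)
})

test_that("agglomeration merges nearest pairs first", {
  m <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- agglomerate(m)
  expect_identical(sort(tr$labels[-tr$merge[1, ]]), c("A", "B"))
  expect_equal(tr$height[1], 1)
  m2 <- m[1:2, 1:2]
  tr2 <- agglomerate(m2)
  expect_length(tr2$height, 1)
  expect_equal(tr2$height, m2[1, 2])
})

test_that("planted hazard tiers are recovered exactly at the planted k", {
  keys <- coarse_keys_16()
  tier <- rep(1:4, each = 4)
  rates <- c(0.005, 0.02, 0.06, 0.15)[tier]
  coh <- planted_cohort(keys, rates, n_per_subgroup = 500, seed = 99)
  s <- build_curve_set(coh)
  d <- build_distance_matrix(s)
  cl <- stats::cutree(agglomerate(d, "average"), k = 4)
  planted <- tier[match(names(cl), subgroup_label(keys$histology, keys$t,
                                                  keys$n, keys$m))]
  expect_equal(adjusted_rand(cl, planted), 1)
  if (requireNamespace("mclust", quietly = TRUE)) {
    expect_equal(mclust::adjustedRandIndex(cl, planted), 1)
  }
  # multiplying the matrix by a positive constant changes nothing
  cl2 <- stats::cutree(agglomerate(d * 137, "average"), k = 4)
  expect_equal(adjusted_rand(cl, cl2), 1)
})

test_that("cut_and_label orders clusters by survival and nests stages", {
  keys <- coarse_keys_32()
  tier <- rep(1:8, each = 4)
  rates <- rate_from_css(c(0.75, 0.60, 0.45, 0.33, 0.22, 0.14, 0.08,
                           0.04), 60)[tier]
  coh <- planted_cohort(keys, rates, n_per_subgroup = 300, seed = 13,
                        censor_max = 120)
  s <- build_curve_set(coh)
  tr <- agglomerate(build_distance_matrix(s))
  rg <- cut_and_label(tr, s, k_substage = 8)
  expect_identical(names(rg$substage_css),
                   c("IA", "IB", "IIA", "IIB", "IIIA", "IIIB", "IIIC",
                     "IV"))
  expect_true(all(diff(rg$substage_css) < 0))
  expect_identical(rg$assignment$stage,
                   substage_to_stage(rg$assignment$substage))
  # record order cannot change the regrouping
  coh2 <- coh[sample(nrow(coh)), ]
  s2 <- build_curve_set(coh2)
  rg2 <- cut_and_label(agglomerate(build_distance_matrix(s2)), s2, 8)
  a1 <- rg$assignment[order(rg$assignment$label), ]
  a2 <- rg2$assignment[order(rg2$assignment$label), ]
  expect_identical(a1$substage, a2$substage)
  expect_error(cut_and_label(tr, s, k_substage = 8,
                             stage_pattern = c(2, 2, 3)), "sum")
  expect_error(cut_and_label(tr, s, k_substage = 64,
                             stage_pattern = c(16, 16, 16, 16)), "exceeds")
})

test_that("derived stage maps are total, provenance-flagged and histology-aware", {
  # ADC strictly better than SCC inside every TNM cell
  keys <- coarse_keys_32()
  base <- rep(rep(c(0.004, 0.012, 0.035, 0.10), each = 4), 2)
  rates <- ifelse(keys$histology == "SCC", base * 3, base)
  coh <- planted_cohort(keys, rates, n_per_subgroup = 400, seed = 17)
  s <- build_curve_set(coh)
  rg <- cut_and_label(agglomerate(build_distance_matrix(s)), s, 8)
  mp <- derive_stage_map(rg, complete = TRUE)
  expect_identical(mp$system, "derived_modified")
  expect_equal(nrow(mp$entries), 2 * 4 * 4 * 2)  # total coarse domain
  expect_setequal(unique(mp$entries$source), c("derived", "default"))
  a <- rg$assignment
  adc <- a[a$histology == "ADC", ]
  scc <- a[a$histology == "SCC", ]
  m <- match(paste(adc$t, adc$n, adc$m), paste(scc$t, scc$n, scc$m))
  ok <- !is.na(m)
  expect_true(all(stage_rank(scc$substage[m[ok]]) >=
                    stage_rank(adc$substage[ok])))
})

test_that("Newick export round-trips through ape", {
  m <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3, 3,
              dimnames = list(c("ADC_T1_N0_M0", "ADC_T2_N0_M0",
                                "SCC_T1_N0_M0"), NULL))
  colnames(m) <- rownames(m)
  tr <- agglomerate(m)
  nwk <- export_newick(tr)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, rownames(m))
  expect_equal(length(phy$tip.label), nrow(m))
  # two-leaf tree: single cherry at half the merge height per branch
  tr2 <- agglomerate(m[1:2, 1:2])
  phy2 <- ape::read.tree(text = export_newick(tr2))
  expect_equal(sum(phy2$edge.length), m[1, 2])
})
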