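# builds a two-plan patient with a controllable uniform PTV dose drop
make_record <- function(id = "P01", location = "peripheral", drop = 1,
                        ptv_cc = 50, lung_mean = 5, lung_mean_recalc = NULL) {
  sch <- fractionation_scheme(60, 5)
  bundle <- study_parameter_bundle()
  sel <- list(tcp = bundle$tcp, ntcp = bundle$ntcp["lung"])
  if (is.null(lung_mean_recalc)) lung_mean_recalc <- lung_mean
  ref <- evaluate_plan(list(ptv = uniform_ptv(60),
                            lung = simple_lung(lung_mean)), sch, sel)
  rec <- evaluate_plan(list(ptv = uniform_ptv(60 - drop),
                            lung = simple_lung(lung_mean_recalc)), sch, sel)
  patient_record(id, location, ptv_cc, ref, rec)
}

test_that("paired comparison computes antisymmetric reference-minus-recalculated deltas", {
  r <- make_record(drop = 1)
  cmp <- compare_pair(r)
  expect_equal(unname(cmp$deltas["delta_d95_gy"]), 1, tolerance = 1e-6)
  expect_equal(unname(cmp$deltas["delta_mean_gy"]), 1, tolerance = 1e-9)
  expect_true(all(cmp$deltas[grep("delta_tcp", names(cmp$deltas))] > 0))

  # identical plans: all deltas zero
  cmp0 <- compare_pair(make_record(drop = 0))
  expect_true(all(abs(cmp0$deltas) < 1e-12))

  # swapping the plan roles negates every delta
  swapped <- patient_record(r$patient_id, r$location, r$ptv_cc,
                            r$recalculated, r$reference)
  expect_equal(compare_pair(swapped)$deltas, -cmp$deltas)
})

test_that("structure-set or bundle mismatches are rejected", {
  sch <- fractionation_scheme(60, 5)
  bundle <- study_parameter_bundle()
  sel <- list(tcp = bundle$tcp, ntcp = list())
  a <- evaluate_plan(list(ptv = uniform_ptv(), lung = simple_lung()), sch,
                     sel)
  b <- evaluate_plan(list(ptv = uniform_ptv()), sch, sel)
  expect_error(patient_record("P", "peripheral", 10, a, b),
               "different structure sets")
  b2 <- evaluate_plan(list(ptv = uniform_ptv(), lung = simple_lung()), sch,
                      list(tcp = bundle$tcp["tcp.martel_30mo"],
                           ntcp = list()))
  expect_error(compare_pair(patient_record("P", "peripheral", 10, a, b2)),
               "parameter bundles")
})

test_that("cohort summary reports per-group medians and ranges, order-invariant", {
  recs <- list(make_record("P1", "peripheral", drop = 1),
               make_record("P2", "peripheral", drop = 2),
               make_record("P3", "peripheral", drop = 3))
  cmps <- lapply(recs, compare_pair)
  expect_warning(s <- cohort_summary(cmps), "central")
  row <- s[s$metric == "delta_d95_gy" & s$group == "peripheral", ]
  expect_equal(row$median, 2, tolerance = 1e-6)
  expect_equal(c(row$min, row$max), c(1, 3), tolerance = 1e-6)
  expect_true(all(s$min <= s$median & s$median <= s$max))

  s2 <- suppressWarnings(cohort_summary(rev(cmps)))
  expect_equal(s2, s)

  one <- suppressWarnings(cohort_summary(cmps[1]))
  r1 <- one[one$metric == "delta_d95_gy", ]
  expect_equal(r1$min, r1$max)
  expect_equal(r1$median, r1$min)
})

test_that("Kruskal-Wallis matches the hand-ranked statistic and degenerate rules", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(10, 11, 12)), exact = "never")
  expect_equal(kw$statistic, 3.857, tolerance = 1e-3)
  expect_equal(kw$df, 1)
  expect_equal(kw$p_value,
               stats::kruskal.test(list(c(1, 2, 3), c(10, 11, 12)))$p.value)

  same <- kruskal_wallis(list(c(2, 2, 2), c(2, 2)), exact = "never")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "nonempty")

  # invariance under strictly monotone transforms of the pooled data
  g <- list(c(0.3, 1.2, 2.5, 0.9), c(1.7, 3.1, 0.1))
  kw1 <- kruskal_wallis(g)
  kw2 <- kruskal_wallis(lapply(g, function(v) exp(3 * v)))
  expect_equal(kw1$statistic, kw2$statistic)
  expect_equal(kw1$p_value, kw2$p_value)
})

test_that("exact permutation p-value matches brute-force enumeration", {
  g <- list(c(1.3, 4.2, 2.2), c(5.1, 6.0, 3.3))
  kw <- kruskal_wallis(g, exact = "always")
  # independent brute force: recompute H for every subset assignment
  pooled <- unlist(g)
  idx_sets <- combn(6, 3, simplify = FALSE)
  h_obs <- unname(stats::kruskal.test(pooled,
                                      factor(rep(1:2, each = 3)))$statistic)
  hs <- vapply(idx_sets, function(ix) {
    grp <- rep(2, 6); grp[ix] <- 1
    unname(stats::kruskal.test(pooled, factor(grp))$statistic)
  }, 0)
  expect_equal(kw$p_value, mean(hs >= h_obs - 1e-9))
  expect_match(kw$method, "exact permutation")
  # with ties the tie-corrected H is still used
  gt <- list(c(1, 1, 2), c(2, 3, 3))
  expect_equal(kruskal_wallis(gt, exact = "always")$statistic,
               unname(stats::kruskal.test(unlist(gt),
                                          factor(rep(1:2, each = 3)))$statistic))
})

test_that("delta-vs-covariate screening reports Spearman rho and permutation p", {
  recs <- lapply(1:6, function(i)
    make_record(sprintf("P%d", i), "peripheral", drop = i / 2,
                ptv_cc = 10 * i))
  cmps <- lapply(recs, compare_pair)
  # delta_tcp is a strictly increasing function of delta_d95 here
  tr <- delta_vs_covariate(cmps, "delta_tcp.martel_30mo", "delta_d95_gy",
                           n_perm = 500, seed = 4)
  expect_equal(tr$rho, 1)
  expect_lt(tr$p_perm, 0.05)
  # reversing the covariate sign negates rho
  tr2 <- delta_vs_covariate(cmps, "delta_tcp.martel_30mo", "ptv_cc",
                            n_perm = 200, seed = 4)
  neg <- cmps
  for (i in seq_along(neg)) neg[[i]]$ptv_cc <- -neg[[i]]$ptv_cc
  tr3 <- delta_vs_covariate(neg, "delta_tcp.martel_30mo", "ptv_cc",
                            n_perm = 200, seed = 4)
  expect_equal(tr3$rho, -tr2$rho)
  # constant covariate: undefined, reported as such
  trc <- delta_vs_covariate(cmps, "delta_tcp.martel_30mo", "location",
                            n_perm = 100, seed = 1)
  expect_true(is.na(trc$rho))
  expect_match(trc$note, "undefined")
  # same seed reproduces the permutation p exactly
  tr4 <- delta_vs_covariate(cmps, "delta_tcp.martel_30mo", "delta_d95_gy",
                            n_perm = 500, seed = 4)
  expect_identical(tr$p_perm, tr4$p_perm)
})

test_that("independent covariates give small correlations on seeded draws", {
  set.seed(17)
  recs <- lapply(1:12, function(i)
    make_record(sprintf("P%d", i), "peripheral", drop = runif(1, 0.3, 6),
                ptv_cc = runif(1, 15, 145)))
  cmps <- lapply(recs, compare_pair)
  tr <- delta_vs_covariate(cmps, "delta_tcp.martel_30mo", "ptv_cc",
                           n_perm = 1000, seed = 2)
  expect_lt(abs(tr$rho), 0.75)
  expect_gt(tr$p_perm, 0.01)
})
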