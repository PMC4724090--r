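test_that("EQD2 matches hand values and is the identity at 2 Gy per fraction", {
  expect_equal(eqd2(60, 12, 10), 110)
  expect_equal(round(eqd2(6.5, 12, 10), 1), 11.9)
  for (ab in c(1.3, 3, 10))
    for (D in c(0.5, 20, 60))
      expect_equal(eqd2(D, 2, ab), D)
  # linear in D at fixed d
  expect_equal(eqd2(40, 8, 3), 2 * eqd2(20, 8, 3))
  expect_error(eqd2(10, 5, 0), "alpha_beta")
  expect_error(eqd2(10, 0, 3), "dose_per_fraction")
  expect_error(eqd2(-1, 5, 3), ">= 0")
})

test_that("EQD2 DVH correction maps the dose axis monotonically, conserving volume", {
  u <- uniform_ptv(60, 0.2)
  sch <- fractionation_scheme(60, 5)
  xe <- eqd2_correct_dvh(u, sch, 10)
  expect_equal(summary(xe)$mean_gy, 110, tolerance = 1e-4)
  expect_equal(sum(to_differential(xe)$volume), 1, tolerance = 1e-12)

  # per-fraction dose 2 Gy at the uniform dose level: identity
  u40 <- uniform_ptv(40, 0.2)
  id <- eqd2_correct_dvh(u40, fractionation_scheme(40, 20), 10)
  expect_equal(summary(id)$mean_gy, 40, tolerance = 1e-3)

  # monotone: higher physical dose, higher EQD2, for a non-uniform DVH
  set.seed(5)
  v <- runif(30); v <- v / sum(v)
  x <- dvh(seq(0, 75, length.out = 31), v, "differential")
  xe <- eqd2_correct_dvh(x, sch, 3)
  expect_true(all(diff(xe$dose_edges) > 0))
  expect_equal(xe$volume, x$volume)
  expect_error(eqd2_correct_dvh(x, "not a scheme", 3))
})

test_that("Poisson-LQ response passes its closed-form anchors", {
  for (key in c("tcp.willner_24mo", "tcp.martel_24mo", "tcp.martel_30mo")) {
    p <- model_parameters(key)
    expect_equal(poisson_response(p$d50_gy, p), 0.5)
  }
  p <- model_parameters("tcp.martel_30mo")
  expect_lt(poisson_response(0.001, p), 1e-6)
  expect_gt(poisson_response(10 * p$d50_gy, p), 1 - 1e-6)
  expect_equal(poisson_response(110, p), 0.8166803, tolerance = 1e-6)
  expect_error(poisson_response(-1, p), ">= 0")
})

test_that("TCP aggregation matches brute-force voxel products", {
  p <- model_parameters("tcp.martel_30mo")
  u <- uniform_ptv(p$d50_gy, 0.01)
  expect_equal(tcp_from_dvh(u, p), 0.5, tolerance = 1e-4)

  # two equal bins at P = 0.9 and 0.4
  d <- dvh_from_doses(c(response_inverse(0.9, p), response_inverse(0.4, p)))
  expect_equal(tcp_from_dvh(d, p), sqrt(0.9 * 0.4), tolerance = 1e-9)

  # single-bin DVH equals the bare response
  one <- dvh_from_doses(72)
  expect_equal(tcp_from_dvh(one, p), poisson_response(72, p))

  set.seed(21)
  for (i in 1:10) {
    # doses kept above 10 Gy so the documented 1e-12 response clip is inert
    vx <- random_voxel_dvh(n = sample(5:100, 1), max_dose = 120,
                           min_dose = 10)
    expect_equal(tcp_from_dvh(vx$dvh, p), brute_tcp(vx$doses, p),
                 tolerance = 1e-9)
  }
})

test_that("generalized EUD matches hand values and brute force", {
  d <- dvh_from_doses(c(10, 20))
  expect_equal(eud(d, 1), 15)
  expect_equal(eud(d, 0.5), sqrt(0.5 * 100 + 0.5 * 400), tolerance = 1e-9)
  u <- uniform_ptv(50, 0.01)
  for (n in c(1, 0.5, 0.12)) expect_equal(eud(u, n), 50, tolerance = 0.01)
  expect_error(eud(d, 0), "positive")

  set.seed(31)
  for (i in 1:10) {
    vx <- random_voxel_dvh(n = 40)
    for (n in c(1, 0.64, 0.25))
      expect_equal(eud(vx$dvh, n), brute_eud(vx$doses, n), tolerance = 1e-9)
  }
})

test_that("EUD stays within the dose range, decreases in n, tends to max dose", {
  set.seed(8)
  for (i in 1:10) {
    vx <- random_voxel_dvh(n = 30)
    ns <- c(1, 0.7, 0.4, 0.2, 0.05)
    es <- vapply(ns, function(n) eud(vx$dvh, n), 0)
    expect_true(all(diff(es) >= -1e-9))  # non-increasing in n along ns desc
    expect_true(all(es >= min(vx$doses) - 1e-6 &
                    es <= max(vx$doses) + 1e-6))
    # n -> 0+ limit: deviation from the max dose scales as max * n * log(N)
    expect_lt(abs(eud(vx$dvh, 1e-5) - max(vx$doses)), 0.01)
  }
})

test_that("LKB probit passes anchors and agrees with numerical quadrature", {
  for (key in c("lung_lkb.kwa", "lung_lkb.seppenwoolde_ab1.3",
                "lung_lkb.seppenwoolde_ab3", "lung_lkb.burman",
                "lkb.esophagus", "lkb.heart")) {
    p <- model_parameters(key)
    expect_equal(lkb_ntcp(p$d50_gy, p), 0.5)
    expect_equal(lkb_ntcp(p$d50_gy * (1 + p$m_slope), p), pnorm(1),
                 tolerance = 1e-12)
  }
  p <- model_parameters("lung_lkb.kwa")
  expect_lt(lkb_ntcp(0, p), 1e-3)
  expect_error(lkb_ntcp(-5, p), ">= 0")
  # quadrature oracle for the probit integral over t in [-6, 6]; a slope
  # with 6 m < 1 keeps the whole sweep at non-negative EUD
  probit_quad <- function(t)
    stats::integrate(function(x) exp(-x^2 / 2) / sqrt(2 * pi), -Inf, t,
                     rel.tol = 1e-12)$value
  psweep <- lkb_params(50, 0.5, 0.15, 3)
  for (t in seq(-6, 6, by = 1.5)) {
    eud_t <- psweep$d50_gy * (1 + psweep$m_slope * t)
    expect_equal(lkb_ntcp(eud_t, psweep), probit_quad(t), tolerance = 1e-7)
  }
})

test_that("relative-seriality NTCP passes anchors and a hand-computed case", {
  for (key in c("seriality.cord_myelitis", "seriality.esophagus_stricture")) {
    p <- model_parameters(key)
    u <- uniform_ptv(p$d50_gy, 0.01)
    expect_equal(seriality_ntcp(u, p), 0.5, tolerance = 1e-4)
  }
  # s = 1 at uniform dose collapses to the bare response
  p1 <- seriality_params(68.6, 1.9, 1, 3)
  u <- uniform_ptv(50, 0.01)
  expect_equal(seriality_ntcp(u, p1), poisson_response(50, p1),
               tolerance = 1e-4)
  # two equal bins with P = 0.8 / 0.2 at s = 2:
  # (1 - sqrt((1 - 0.64) * (1 - 0.04)))^(1/2) = 0.6419684...
  p2 <- seriality_params(68.6, 1.9, 2, 3)
  d <- dvh_from_doses(c(response_inverse(0.8, p2),
                        response_inverse(0.2, p2)))
  expect_equal(seriality_ntcp(d, p2), sqrt(1 - sqrt(0.36 * 0.96)),
               tolerance = 1e-9)
  expect_error(seriality_params(68.6, 1.9, 0, 3))
})

test_that("TCP and NTCP are monotone under pointwise dose increase", {
  set.seed(13)
  ptcp <- model_parameters("tcp.martel_30mo")
  plkb <- model_parameters("lung_lkb.seppenwoolde_ab1.3")
  pser <- model_parameters("seriality.cord_myelitis")
  for (i in 1:8) {
    nb <- sample(5:30, 1)
    v <- runif(nb); v <- v / sum(v)
    e <- sort(runif(nb + 1, 0, 80))
    x <- dvh(e, v, "differential")
    shift <- runif(1, 0.5, 10)
    y <- dvh(e + shift, v, "differential")
    expect_gte(tcp_from_dvh(y, ptcp), tcp_from_dvh(x, ptcp))
    expect_gte(lkb_ntcp(eud(y, plkb$n_volume), plkb),
               lkb_ntcp(eud(x, plkb$n_volume), plkb))
    expect_gte(seriality_ntcp(y, pser), seriality_ntcp(x, pser))
    expect_true(all(c(tcp_from_dvh(x, ptcp), seriality_ntcp(x, pser),
                      lkb_ntcp(eud(x, plkb$n_volume), plkb)) >= 0))
    expect_true(all(c(tcp_from_dvh(y, ptcp), seriality_ntcp(y, pser),
                      lkb_ntcp(eud(y, plkb$n_volume), plkb)) <= 1))
  }
})

test_that("evaluate_plan assembles metrics, TCP and NTCP deterministically", {
  sch <- fractionation_scheme(60, 5)
  bundle <- study_parameter_bundle()
  # PTV-only plan: one TCP per requested set, zero NTCPs, with warnings
  expect_warning(ev <- evaluate_plan(list(ptv = uniform_ptv()), sch,
                                     list(tcp = bundle$tcp["tcp.martel_30mo"],
                                          ntcp = bundle$ntcp["lung"])),
                 "skipped")
  expect_equal(nrow(ev$tcp), 1)
  expect_equal(nrow(ev$ntcp), 0)
  expect_error(evaluate_plan(list(lung = simple_lung()), sch, bundle),
               "missing PTV")

  dvhs <- list(ptv = uniform_ptv(), lung = simple_lung())
  ev1 <- evaluate_plan(dvhs, sch, list(tcp = bundle$tcp,
                                       ntcp = bundle$ntcp["lung"]))
  ev2 <- evaluate_plan(dvhs, sch, list(tcp = bundle$tcp,
                                       ntcp = bundle$ntcp["lung"]))
  expect_identical(ev1$tcp, ev2$tcp)
  expect_identical(ev1$ntcp, ev2$ntcp)
  expect_equal(nrow(ev1$ntcp), 4)  # three lung studies + alpha/beta variant
  # each NTCP row equals the direct per-set computation
  for (i in seq_len(nrow(ev1$ntcp))) {
    ps <- bundle$ntcp$lung[[paste0("lung_lkb.", ev1$ntcp$label[i])]]
    xe <- eqd2_correct_dvh(dvhs$lung, sch, ps$alpha_beta_gy)
    expect_equal(ev1$ntcp$value[i], lkb_ntcp(eud(xe, ps$n_volume), ps))
  }
})

test_that("lung parameter sets order NTCP as expected on low-dose lung DVHs", {
  sch <- fractionation_scheme(60, 5)
  bundle <- study_parameter_bundle()
  set.seed(99)
  for (mean_gy in c(4, 6, 8)) {
    lung <- simple_lung(mean_gy = mean_gy)
    ev <- evaluate_plan(list(ptv = uniform_ptv(), lung = lung), sch,
                        list(tcp = bundle$tcp["tcp.martel_30mo"],
                             ntcp = bundle$ntcp["lung"]))
    n <- setNames(ev$ntcp$value, ev$ntcp$label)
    expect_lte(n[["burman"]], n[["kwa"]])
    expect_lte(n[["kwa"]], n[["seppenwoolde_ab1.3"]])
  }
})
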