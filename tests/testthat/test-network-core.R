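# Equilibrium network: state enumeration, effective affinity, closed
# form, limits and titration curves.

test_that("state enumeration respects model truncations and lobe knockouts", {
  expect_equal(nrow(enumerate_states(model_variant(1, "WT"))), 8)
  # partially ordered: MLCK-bound states require a loaded C-lobe
  s2 <- enumerate_states(model_variant(2, "WT"))
  expect_equal(nrow(s2), 6)
  expect_true(all(s2$c_occupied[s2$mlck_bound]))
  # fully ordered + N-lobe knockout: only apo and C-occupied remain
  s3n <- enumerate_states(model_variant(3, "N"))
  expect_equal(nrow(s3n), 2)
  expect_false(any(s3n$mlck_bound))
  expect_false(any(s3n$n_occupied))
  # states are unique
  for (m in 1:3) for (mu in c("WT", "N", "C", "NC")) {
    s <- enumerate_states(model_variant(m, mu))
    expect_equal(nrow(unique(s)), nrow(s))
  }
  expect_error(model_variant(4), "model must be")
})

test_that("effective affinity interpolates between the limiting constants", {
  p <- ref_params()
  # structural zero at x = 0 for the ordered mechanisms
  expect_identical(effective_affinity(p, model_variant(2, "WT"), 0), 0)
  expect_identical(effective_affinity(p, model_variant(3, "WT"), 0), 0)
  # Model 1 at x = 0 is pure apo binding (K9)
  expect_equal(effective_affinity(p, model_variant(1, "WT"), 0),
               p$k_mlck[["apo"]])
  # saturation: K2 for wild type, K4 for the N-lobe knockout
  expect_equal(effective_affinity(p, model_variant(2, "WT"), 1e8),
               p$k_mlck[["NC"]], tolerance = 1e-6)
  expect_equal(effective_affinity(p, model_variant(2, "N"), 1e8),
               p$k_mlck[["C"]], tolerance = 1e-6)
  # bounded by the admissible constants
  k <- effective_affinity(p, model_variant(1, "WT"), c(0.01, 0.1, 1, 10))
  expect_true(all(k >= min(p$k_mlck) & k <= max(p$k_mlck)))
  expect_error(effective_affinity(p, model_variant(1, "WT"), -1), "ca_free")
})

test_that("effective affinity equals an explicit partition-sum evaluation", {
  # independent oracle: enumerate the four Ca states by hand
  p <- ref_params()
  v <- model_variant(1, "WT")
  for (x in c(0.05, 0.7, 5, 39)) {
    w <- c(1, p$ca_assoc_N * x^2, p$ca_assoc_C * x^2,
           p$ca_assoc_N * p$ca_assoc_C * x^4)
    k <- p$k_mlck[c("apo", "N", "C", "NC")]
    expect_equal(effective_affinity(p, v, x), sum(w * k) / sum(w),
                 tolerance = 1e-12)
  }
})

test_that("closed-form fraction bound reproduces the reference calculations", {
  # zero-Ca binding under the random mechanism, via K9
  expect_equal(100 * fraction_bound(0.078, 0.713, 0.0237), 5.26,
               tolerance = 0.01)
  expect_equal(100 * fraction_bound(0.078, 35.65, 0.0237), 73.5,
               tolerance = 0.001)
  expect_equal(100 * fraction_bound(0.0078, 35.65, 0.0237), 21.75,
               tolerance = 0.001)
  expect_identical(fraction_bound(0, 10, 1), 0)
  expect_identical(fraction_bound(5, 0, 1), 0)
  expect_error(fraction_bound(-1, 1, 1))
  expect_error(fraction_bound(1, -1, 1))
})

test_that("fraction bound is strictly increasing in the association constant", {
  k <- c(1e-4, 1e-3, 1e-2, 0.1, 1, 10, 100, 1e3, 1e4)
  f <- fraction_bound(k, 0.713, 0.0237)
  expect_true(all(diff(f) > 0))
  expect_true(all(f > 0 & f < 1))
})

test_that("closed form and mass-action root-finding oracle agree", {
  set.seed(101)
  for (i in 1:200) {
    inst <- random_instance()
    a <- fraction_bound(
      effective_affinity(inst$params, inst$variant, inst$x),
      inst$conc$cam_tot, inst$conc$mlck_tot)
    b <- fraction_bound_numeric(inst$params, inst$variant, inst$conc, inst$x)
    if (a == 0) expect_identical(b, 0)
    else expect_lt(abs(a - b) / a, 1e-9)
  }
  # degenerate totals
  p <- ref_params()
  expect_identical(
    fraction_bound_numeric(p, model_variant(1, "WT"),
                           concentrations(0, 1), 5), 0)
  expect_identical(
    fraction_bound_numeric(p, model_variant(1, "WT"),
                           concentrations(1, 0), 5), 0)
})

test_that("limiting fractions match the reference predictions", {
  p <- ref_params(); conc <- main_conc()
  # random mechanism binds apo CaM: ~5.2% at zero Ca
  expect_equal(100 * limit_binding(p, model_variant(1, "WT"), conc, "low"),
               5.26, tolerance = 0.01)
  # ordered mechanisms: exact structural zero at zero Ca
  expect_identical(limit_binding(p, model_variant(2, "WT"), conc, "low"), 0)
  expect_identical(limit_binding(p, model_variant(3, "N"), conc, "low"), 0)
  # high-Ca limits: 99.9% (WT, K2) and 92.0% (N-lobe knockout, K4)
  expect_equal(100 * limit_binding(p, model_variant(2, "WT"), conc, "high"),
               99.86, tolerance = 0.01)
  expect_equal(100 * limit_binding(p, model_variant(2, "N"), conc, "high"),
               92.03, tolerance = 0.01)
  # fully ordered + N knockout: zero at both ends
  expect_identical(limit_binding(p, model_variant(3, "N"), conc, "high"), 0)
})

test_that("low- and high-Ca limits share one algebraic structure", {
  # swapping which named constant is passed reproduces the other limit
  p <- ref_params(); conc <- main_conc()
  lo_with_k4 <- fraction_bound(p$k_mlck[["C"]], conc$cam_tot, conc$mlck_tot)
  hi_n_mut <- limit_binding(p, model_variant(2, "N"), conc, "high")
  expect_identical(lo_with_k4, hi_n_mut)
  lo_with_k9 <- fraction_bound(p$k_mlck[["apo"]], conc$cam_tot, conc$mlck_tot)
  expect_identical(lo_with_k9,
                   limit_binding(p, model_variant(1, "C"), conc, "low"))
})

test_that("titration curves are monotone and converge to the limits", {
  m <- cam_mlck_model(2, "WT")
  grid <- c(0, 10^seq(-3, 3, length.out = 60))
  cur <- titration_curve(m, grid)
  expect_equal(nrow(cur), length(grid))
  expect_true(all(cur$fraction_bound >= 0 & cur$fraction_bound <= 1))
  expect_true(all(diff(cur$fraction_bound) >= 0))
  expect_identical(cur$fraction_bound[1],
                   limit_binding(m$params, m$variant, m$conc, "low"))
  expect_equal(cur$fraction_bound[length(grid)],
               limit_binding(m$params, m$variant, m$conc, "high"),
               tolerance = 1e-6)
  # WT partially ordered curve on the experimental ladder ends near 99.9%
  lad <- titration_curve(m, default_ladder())
  expect_equal(lad$fraction_bound[14], 0.999, tolerance = 0.002)
  expect_error(titration_curve(m, c(1, 0.5)), "sorted")
})

test_that("variants with no MLCK-competent state give a flagged zero curve", {
  m <- cam_mlck_model(2, "NC")  # all EF hands dead: C-lobe can never load
  expect_true(m$structural_zero_curve)
  cur <- titration_curve(m, default_ladder())
  expect_identical(cur$fraction_bound, rep(0, 14))
  expect_false(cam_mlck_model(2, "WT")$structural_zero_curve)
})

test_that("model object methods are coherent", {
  m <- cam_mlck_model(2, "N")
  cf <- coef(m)
  expect_equal(unname(cf["K4"]), 16.7)
  expect_equal(unname(cf["K2"]), 1000)
  expect_equal(predict(m, c(0, 39)),
               fraction_bound(effective_affinity(m$params, m$variant, c(0, 39)),
                              0.713, 0.0237))
  expect_output(print(m), "partially ordered")
})
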