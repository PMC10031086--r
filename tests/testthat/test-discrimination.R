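# Ratio computation, rank tests, AUC, on-bead quantification,
# dose-response fits and model scoring.

test_that("ratio computation divides channels and keeps the bookkeeping", {
  d <- data.frame(condition = "WT", replicate = 1, ca_free_uM = 0,
                  em480 = 50, em535 = 100)
  expect_equal(compute_ratios(d)$ratio, 0.5)
  full <- small_plate(seed = 2)
  r <- compute_ratios(full)
  expect_equal(nrow(r), nrow(full))
  bad <- full; bad$em480[1] <- -1
  expect_warning(rb <- compute_ratios(bad), "dropped")
  expect_equal(nrow(rb), nrow(full) - 1)
})

test_that("one-tailed Mann-Whitney matches exact enumeration", {
  # {3,4} vs {1,2}: only 1 of the 6 rank arrangements is as extreme
  t1 <- mann_whitney(c(3, 4), c(1, 2), "greater")
  expect_equal(t1$p_value, 1 / 6, tolerance = 1e-12)
  expect_lte(t1$statistic, t1$n1 * t1$n2)
  # identical samples carry no evidence in the tested direction
  expect_gte(mann_whitney(c(1, 2, 3), c(1, 2, 3), "greater")$p_value, 0.5)
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("Mann-Whitney p is invariant under strictly monotone transforms", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(6, 0.5)
    p0 <- mann_whitney(x, y)$p_value
    expect_equal(mann_whitney(exp(x), exp(y))$p_value, p0)
    expect_equal(mann_whitney(x^3 + 5 * x, y^3 + 5 * y)$p_value, p0)
  }
})

test_that("the endpoint test separates bound from baseline at high calcium", {
  # simulated WT at 39 uM against reporter-only baseline, study sizes
  pvals <- sapply(1:25, function(s) {
    d <- simulate_fret(mutants = "WT",
                       n_replicates = c(WT = 15L, baseline = 13L), seed = s)
    r <- compute_ratios(d)
    mann_whitney(r$ratio[r$condition == "WT" & r$ca_free_uM == 39],
                 r$ratio[r$condition == "baseline" & r$ca_free_uM == 39])$p_value
  })
  expect_true(all(pvals < 0.05))
})

test_that("trapezoidal AUC matches hand calculations and is additive", {
  expect_equal(auc_trapezoid(c(0, 1, 2), c(0, 1, 0)), 1)
  expect_equal(auc_trapezoid(c(0, 2), c(3, 3)), 6)  # constant c over width w
  x <- sort(runif(20, 0, 10)); y <- runif(20)
  expect_equal(auc_trapezoid(x, y), pracma::trapz(x, y), tolerance = 1e-12)
  a <- auc_trapezoid(x, y, range = c(x[1], x[10]))
  b <- auc_trapezoid(x, y, range = c(x[10], x[20]))
  expect_equal(a + b, auc_trapezoid(x, y), tolerance = 1e-12)
  expect_gte(auc_trapezoid(x, y), 0)
  expect_error(auc_trapezoid(c(0, 1), c(1, 1), range = c(0, 5)), "within")
  expect_error(auc_trapezoid(0.5, 1), "2 points")
})

test_that("AUC restricted to the low range uses only ladder points below it", {
  lad <- default_ladder()
  y <- ifelse(lad <= 0.038, 1, 1000)  # poison points above the range
  expect_equal(auc_trapezoid(lad, y, range = c(0, 0.038)), 0.038)
})

test_that("per-replicate AUCs are computed for every series", {
  d <- small_plate(seed = 3)
  r <- compute_ratios(d)
  a <- replicate_auc(r)
  expect_equal(nrow(a), 3 * 3)  # 3 conditions x 3 replicates
  one <- r[r$condition == "WT" & r$replicate == 1, ]
  one <- one[order(one$ca_free_uM), ]
  expect_equal(a$auc[a$condition == "WT" & a$replicate == 1],
               auc_trapezoid(one$ca_free_uM, one$ratio))
})

test_that("on-bead percent binding is background-corrected and clipped", {
  expect_equal(onbead_percent_binding(500, 500, 0), 50)
  expect_equal(onbead_percent_binding(0, 800, 0), 0)
  expect_equal(onbead_percent_binding(850, 50, 50), 100)
  expect_warning(out <- onbead_percent_binding(10, 10, 50), "nonpositive")
  expect_true(is.na(out))
  # known F = 0.8 recovered in expectation
  d <- simulate_onbead(rep(0.8, 200), seq_len(200), cv = 0.02, seed = 9)
  est <- onbead_percent_binding(d$bound_intensity, d$unbound_intensity,
                                d$background)
  expect_equal(mean(est), 80, tolerance = 0.5)
})

test_that("normalization pins the 0 and 39 uM endpoints to 0 and 100", {
  expect_equal(normalize_onbead(c(10, 35, 60), c(0, 3, 39)), c(0, 50, 100))
  already <- normalize_onbead(c(0, 50, 100), c(0, 3, 39))
  expect_equal(already, c(0, 50, 100))
  mono <- normalize_onbead(c(5, 8, 20, 40), c(0, 1, 3, 39))
  expect_true(all(diff(mono) > 0))
  expect_warning(out <- normalize_onbead(c(5, 5), c(0, 39)), "degenerate")
  expect_true(all(is.na(out)))
  expect_error(normalize_onbead(c(1, 2), c(0, 3)), "39")
})

test_that("Hill dose-response fits recover noise-free curves exactly", {
  x <- c(0, 0.05, 0.1, 0.35, 1, 3, 10, 39)
  truth <- c(bottom = 0.5, top = 0.98, ec50 = 0.8, hill = 1.7)
  y <- truth["bottom"] + (truth["top"] - truth["bottom"]) *
    x^truth["hill"] / (truth["ec50"]^truth["hill"] + x^truth["hill"])
  fit <- fit_dose_response(x, y)
  expect_true(fit$converged)
  expect_equal(coef(fit), truth, tolerance = 1e-6, ignore_attr = "names")
  expect_equal(predict(fit, x), y, tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(fit$residual_norm, 1e-8)
})

test_that("flat dose-response series are flagged unidentifiable", {
  fit <- fit_dose_response(c(0, 1, 2, 3, 39), rep(0.5, 5))
  expect_true(fit$flagged)
  expect_true(is.na(coef(fit)["ec50"]))
  expect_error(fit_dose_response(c(0, 1, 1, 1, 1), 1:5), "5 distinct")
})

test_that("fitted plateau of simulated WT data matches the model prediction", {
  d <- simulate_fret(mutants = "WT",
                     n_replicates = c(WT = 15L, baseline = 13L), seed = 21)
  r <- compute_ratios(d)
  wt <- r[r$condition == "WT", ]
  means <- tapply(wt$ratio, wt$ca_free_uM, mean)
  x <- as.numeric(names(means))
  fit <- fit_dose_response(x, as.vector(means))
  expect_true(fit$converged)
  span <- coef(fit)["top"] - coef(fit)["bottom"]
  # per-point SE of the mean ratio at cv = 0.02
  se <- 0.02 * mean(means) * sqrt(2) / sqrt(15)
  expect_lt(abs(span - 0.5 * 0.999), 2 * se)
})

test_that("model scoring reproduces the study's falsification pattern", {
  tab <- predict_table(ref_params(), conc = main_conc())
  rep_ <- classify_models(observed_study_calls(), tab)
  s <- rep_$summary
  expect_equal(s$n_falsified[s$model == 1], 2)  # zero-Ca claim + C at high Ca
  expect_equal(s$n_falsified[s$model == 2], 0)
  expect_equal(s$n_falsified[s$model == 3], 1)  # N-mutant binds at high Ca
  expect_equal(s$n_correct[s$model == 2], 6)
  expect_identical(s$unfalsified, c(FALSE, TRUE, FALSE))
  # observed equal to a model's own predictions: nothing falsified
  m1_obs <- observed_study_calls()
  pred1 <- tab[tab$model == 1, ]
  m1_obs$call <- pred1$call[match(paste(m1_obs$mutant, m1_obs$regime),
                                  paste(pred1$mutant, pred1$regime))]
  s1 <- classify_models(m1_obs, tab)$summary
  expect_equal(s1$n_falsified_conditions[s1$model == 1], 0)
  # all-B observed: per-condition falsifications = a model's NB count
  all_b <- observed_study_calls(); all_b$call <- "B"
  s2 <- classify_models(all_b, tab)$summary
  nb2 <- sum(tab$call[tab$model == 2] == "NB")
  expect_equal(s2$n_falsified_conditions[s2$model == 2], nb2)
  # per-model counts always partition the conditions
  expect_true(all(s$n_correct + s$n_falsified_conditions == s$n_conditions))
  expect_error(classify_models(observed_study_calls()[-1, ], tab), "differ")
})
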