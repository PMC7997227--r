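test_that("sensitivity and specificity match the normal closed forms", {
  dis <- population_sample(2.99, 0.75, 179)
  nd  <- population_sample(0, 1, 2488)

  # threshold at a population mean gives one half, by symmetry
  expect_equal(sensitivity(2.99, dis), 0.5)
  expect_equal(specificity(0, nd), 0.5)

  # frozen values computed from the standard-normal CDF at the
  # standardized deviates (d - mean)/sd = -0.97333... and 2.26
  expect_equal(sensitivity(2.26, dis), pnorm(0.97333333333333333),
               tolerance = 1e-12)
  expect_equal(sensitivity(2.26, dis), 0.83480624, tolerance = 1e-7)
  expect_equal(specificity(2.26, nd), 0.98808937, tolerance = 1e-7)

  # one-sd offset and tail limits
  sig <- population_sample(5, 2, 50)
  expect_equal(specificity(5 + 2, sig), pnorm(1))
  expect_equal(sensitivity(Inf, dis), 0)
  expect_equal(sensitivity(-Inf, dis), 1)
  expect_equal(specificity(Inf, nd), 1)
  expect_equal(specificity(-Inf, nd), 0)
})

test_that("Se is non-increasing and Sp non-decreasing in the threshold", {
  for (seed in 1:20) {
    s <- random_scenario(seed)
    d <- seq(s$non_diseased$mean - 2, s$diseased$mean + 2, length.out = 40)
    se <- sensitivity(d, s$diseased)
    sp <- specificity(d, s$non_diseased)
    expect_true(all(diff(se) < 0))
    expect_true(all(diff(sp) > 0))
  }
})

test_that("measure_value implements the probability definitions", {
  # perfect and uninformative tests
  expect_equal(measure_value("J", 1, 1), 1)
  expect_equal(measure_value("ED", 1, 1), 0)
  expect_equal(measure_value("ODA", 0.5, 0.5, r = 0.3), 0.5)
  expect_equal(measure_value("ODA", 0.5, 0.5, r = 0.8), 0.5)

  # DOR from the frozen Se/Sp values above: (se*sp)/((1-se)*(1-sp))
  se <- 0.8348; sp <- 0.98809
  expect_equal(measure_value("DOR", se, sp),
               se * sp / ((1 - se) * (1 - sp)), tolerance = 1e-12)
  expect_equal(measure_value("DOR", se, sp), 419.2346, tolerance = 1e-6)

  # prevalence is demanded only where it matters
  expect_error(measure_value("PPV", 0.8, 0.9), "`r`")
  expect_silent(measure_value("DOR", 0.8, 0.9))

  # degenerate values are infinities with flags, not silent NaN
  expect_identical(measure_value("DOR", 1, 0.9), Inf)
  expect_identical(measure_value("LRpos", 0.8, 1), Inf)
  expect_identical(dam_flag(Inf), "unbounded")
  expect_identical(dam_flag(NaN), "undefined")
})

test_that("all_measures is consistent and satisfies the algebraic identities", {
  m <- all_measures(glucose)
  v <- setNames(m$value, m$measure)
  expect_equal(unname(v["Se"]), 0.83480624, tolerance = 1e-7)
  expect_equal(unname(v["Sp"]), 0.98808937, tolerance = 1e-7)
  expect_true(all(m$flag == "ok"))

  # identical populations with the threshold at the common mean
  v0 <- all_measures(identical_populations())
  v0 <- setNames(v0$value, v0$measure)
  expect_equal(unname(v0["J"]), 0)
  expect_equal(unname(v0["DOR"]), 1)

  # exact algebra on random scenarios: DOR = LR+/LR-, CZ = Se*Sp,
  # J = Se + Sp - 1, ODA = r*Se + (1-r)*Sp, plus range bounds
  for (seed in 1:25) {
    s <- random_scenario(seed)
    m <- all_measures(s)
    v <- setNames(m$value, m$measure)
    expect_equal(unname(v["DOR"]), unname(v["LRpos"] / v["LRneg"]),
                 tolerance = 1e-12)
    expect_equal(unname(v["CZ"]), unname(v["Se"] * v["Sp"]),
                 tolerance = 1e-12)
    expect_equal(unname(v["J"]), unname(v["Se"] + v["Sp"] - 1),
                 tolerance = 1e-12)
    expect_equal(unname(v["ODA"]),
                 s$prevalence * v[["Se"]] + (1 - s$prevalence) * v[["Sp"]],
                 tolerance = 1e-12)
    probs <- v[c("Se", "Sp", "PPV", "NPV", "ODA", "CZ")]
    expect_true(all(probs >= 0 & probs <= 1))
    expect_true(v[["ED"]] >= 0 && v[["ED"]] <= sqrt(2))
    expect_true(v[["J"]] >= -1 && v[["J"]] <= 1)
    expect_true(all(v[c("DOR", "LRpos", "LRneg")] >= 0))
  }
})

test_that("dams_from_counts matches hand arithmetic and flags zero margins", {
  # balanced table: every proportion one half
  b <- dams_from_counts(contingency_table(25, 25, 25, 25))
  v <- setNames(b$measures$value, b$measures$measure)
  expect_equal(unname(v[c("Se", "Sp", "PPV", "NPV", "ODA")]),
               rep(0.5, 5))
  expect_equal(unname(v["DOR"]), 1)
  expect_equal(unname(v["J"]), 0)
  expect_equal(b$prevalence, 0.5)

  # hand-computed natural frequencies
  h <- dams_from_counts(contingency_table(tn = 90, fp = 10, fn = 20,
                                          tp = 80))
  v <- setNames(h$measures$value, h$measures$measure)
  expect_equal(unname(v["Se"]), 0.8)
  expect_equal(unname(v["Sp"]), 0.9)
  expect_equal(unname(v["DOR"]), 36)
  expect_equal(unname(v["LRpos"]), 8)
  expect_equal(unname(v["PPV"]), 80 / 90)
  expect_equal(h$prevalence, 0.5)

  # zero marginals poison only the affected measures
  z <- dams_from_counts(contingency_table(tn = 10, fp = 0, fn = 0, tp = 10))
  flags <- setNames(z$measures$flag, z$measures$measure)
  expect_identical(unname(flags["DOR"]), "unbounded")
  expect_identical(unname(flags["Se"]), "ok")
  expect_identical(unname(flags["ODA"]), "ok")
})

test_that("counts-based and probability-based measures coincide", {
  tabs <- list(c(90, 10, 20, 80), c(400, 37, 11, 52), c(12, 5, 7, 30))
  for (tb in tabs) {
    ct <- contingency_table(tb[1], tb[2], tb[3], tb[4])
    nf <- dams_from_counts(ct)
    v <- setNames(nf$measures$value, nf$measures$measure)
    se <- v[["Se"]]; sp <- v[["Sp"]]; r <- nf$prevalence
    for (id in dam_ids())
      expect_equal(unname(v[id]), measure_value(id, se, sp, r),
                   tolerance = 1e-12, label = id)
  }
})

test_that("thresholded simulated data converge to the generating measures", {
  s <- scenario(population_sample(0, 1, 200000),
                population_sample(2, 1, 200000),
                measurement_model(0, 50), threshold = 1)
  raw <- simulate_samples(s, seed = 42)
  ct <- tabulate_samples(raw, s$threshold)
  emp <- dams_from_counts(ct)
  v_emp <- setNames(emp$measures$value, emp$measures$measure)
  v_true <- all_measures(s)
  v_true <- setNames(v_true$value, v_true$measure)
  # binomial error at n = 2e5 is about 1e-3 on a proportion
  for (id in c("Se", "Sp", "ODA", "J", "CZ", "ED"))
    expect_equal(unname(v_emp[id]), unname(v_true[id]), tolerance = 0.02,
                 label = id)
  expect_equal(unname(v_emp["DOR"]), unname(v_true["DOR"]),
               tolerance = 0.1)
})

test_that("a measurement exactly at the threshold counts as test-negative", {
  raw <- list(diseased = c(1, 1.5), non_diseased = c(0.5, 1))
  ct <- tabulate_samples(raw, d = 1)
  expect_equal(ct$fn, 1)  # the diseased value at d is negative
  expect_equal(ct$tn, 2)  # the non-diseased value at d is negative
  expect_equal(ct$tp, 1)
  expect_equal(ct$fp, 0)
})
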