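test_that("input component uncertainties follow the closed forms", {
  nd <- population_sample(0, 1, 2488)
  mm <- measurement_model(0.046, 80)

  # frozen values computed by direct evaluation of the formulas
  expect_equal(sampling_u_mean(nd), 1 / sqrt(2488), tolerance = 1e-12)
  expect_equal(sampling_u_mean(nd), 0.020048, tolerance = 1e-4)
  expect_equal(sampling_u_sd(nd), 1 / sqrt(2 * 2487), tolerance = 1e-12)
  expect_equal(sampling_u_sd(nd), 0.014179, tolerance = 1e-4)
  expect_equal(combined_u_mean(nd, mm), sqrt(1 / 2488 + 0.046^2),
               tolerance = 1e-12)
  expect_equal(combined_u_mean(nd, mm), 0.050179, tolerance = 1e-4)
  expect_equal(combined_u_sd(nd, mm), 0.048137, tolerance = 1e-4)

  # identity denominator case for the SD uncertainty: 2/sqrt(2*2) = 1
  expect_equal(sampling_u_sd(population_sample(0, 2, 3)), 1)

  # zero measurement uncertainty collapses combined onto sampling
  mm0 <- measurement_model(0, 50)
  expect_equal(combined_u_mean(nd, mm0), sampling_u_mean(nd))
  expect_equal(combined_u_sd(nd, mm0), sampling_u_sd(nd))

  # huge samples leave only the measurement component
  big <- population_sample(0, 1, 1000000000L)
  expect_equal(combined_u_mean(big, mm), mm$u_m, tolerance = 1e-5)

  # quadrature monotonicity: combined >= each of its parts
  expect_gte(combined_u_mean(nd, mm), sampling_u_mean(nd))
  expect_gte(combined_u_mean(nd, mm), mm$u_m)
  expect_gte(combined_u_sd(nd, mm), sampling_u_sd(nd))
})

test_that("prevalence uncertainty is the adjusted-Wald standard error", {
  expect_equal(prevalence_u(2488, 179),
               sqrt((2 + 2488) * (2 + 179) / (4 + 2488 + 179)^3),
               tolerance = 1e-15)
  expect_equal(prevalence_u(2488, 179), 0.004863, tolerance = 1e-4)
  expect_equal(prevalence_u(2488, 179), prevalence_u(179, 2488))
  expect_error(prevalence_u(0, 0), "at least one")
})

test_that("analytic gradients separate and agree with finite differences", {
  g_se <- dam_gradient("Se", glucose)
  g_sp <- dam_gradient("Sp", glucose)
  expect_identical(unname(g_se["m_nd"]), 0)
  expect_identical(unname(g_se["s_nd"]), 0)
  expect_identical(unname(g_sp["m_d"]), 0)
  expect_identical(unname(g_sp["s_d"]), 0)

  # prevalence components: zero for invariant measures, Se - Sp for ODA
  m <- all_measures(glucose)
  v <- setNames(m$value, m$measure)
  expect_identical(unname(dam_gradient("J", glucose)["r"]), 0)
  expect_identical(unname(dam_gradient("DOR", glucose)["r"]), 0)
  expect_equal(unname(dam_gradient("ODA", glucose)["r"]),
               unname(v["Se"] - v["Sp"]), tolerance = 1e-12)

  # d(Se)/d(m_D) at the glucose settings equals phi(z)/sigma
  # (the threshold derivative is its negative: -0.3317)
  expect_equal(unname(g_se["m_d"]), dnorm(-0.97333333) / 0.75,
               tolerance = 1e-6)
  expect_equal(unname(g_se["m_d"]), 0.331229, tolerance = 1e-5)

  for (seed in 1:40) {
    s <- random_scenario(seed)
    for (id in dam_ids()) {
      a <- dam_gradient(id, s)
      n <- numeric_gradient(id, s)
      expect_true(all(abs(a - n) <= 1e-6 * pmax(abs(a), abs(n), 1)),
                  label = sprintf("%s seed %d", id, seed))
    }
  }
})

test_that("Welch-Satterthwaite dof behaves per the combining rule", {
  # symmetric pair doubles the df; a single component keeps its own
  expect_equal(effective_dof(c(0.2, 0.2), c(7, 7)), 14)
  expect_equal(effective_dof(0.5, 12), 12)
  # frozen value from direct arithmetic:
  # (0.09 + 0.16)^2 / (0.0081/10 + 0.0256/20)
  expect_equal(effective_dof(c(0.3, 0.4), c(10, 20)), 29.904306,
               tolerance = 1e-6)
  expect_error(effective_dof(c(0, 0), c(5, 5)), "zero")
  # bounds: min(v) <= v_eff <= sum(v) on random component sets
  set.seed(7)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    u <- runif(k, 0, 2); v <- sample(1:300, k, replace = TRUE)
    if (all(u == 0)) next
    ve <- effective_dof(u, v)
    expect_gte(ve, min(v) - 1e-9)
    expect_lte(ve, sum(v) + 1e-9)
  }
})

test_that("expanded uncertainty uses Student-t quantiles symmetrically", {
  expect_equal(expanded_uncertainty(0, 10, 0.95),
               c(lower = 0, upper = 0))
  e10 <- expanded_uncertainty(1, 10, 0.95)
  expect_equal(unname(e10["upper"]), 2.2281, tolerance = 1e-4)
  expect_equal(unname(e10["lower"]), -unname(e10["upper"]))
  # normal limit of the t quantile
  einf <- expanded_uncertainty(1, 1e9, 0.95)
  expect_equal(unname(einf["upper"]), 1.95996, tolerance = 1e-4)
  # non-integer df accepted
  expect_silent(expanded_uncertainty(1, 12.34, 0.9))
  expect_error(expanded_uncertainty(1, 10, 1.2), "0, 1")
})

test_that("confidence intervals contain the estimate and clip to range", {
  ci <- confidence_interval(0.5, 0, 10, 0.95, "Se")
  expect_equal(unname(ci$ci), c(0.5, 0.5))
  ci <- confidence_interval(0.999, 0.05, 30, 0.95, "Sp")
  expect_equal(unname(ci$ci["upper"]), 1)
  expect_true(ci$clipped["upper"])
  expect_false(ci$clipped["lower"])
  ci <- confidence_interval(0.1, 0.2, 30, 0.95, "DOR")
  expect_equal(unname(ci$ci["lower"]), 0)
  ci <- confidence_interval(-0.9, 0.2, 30, 0.95, "J")
  expect_equal(unname(ci$ci["lower"]), -1)
  # all glucose CIs contain their point estimate
  for (b in propagate_all(glucose)) {
    expect_lte(b$ci[["lower"]], b$value)
    expect_gte(b$ci[["upper"]], b$value)
  }
})

test_that("propagation splits into measurement and sampling budgets", {
  # no measurement uncertainty: the measurement share vanishes
  s0 <- with_um(glucose, 0)
  for (b in propagate_all(s0)) {
    expect_equal(b$u_meas, 0)
    expect_equal(b$u_c, b$u_samp, tolerance = 1e-12)
  }
  # enormous samples: only the measurement share is left
  sbig <- with_sizes(glucose, 50000000L, 50000000L)
  for (id in c("Se", "Sp", "J", "CZ", "ED")) {
    b <- propagate(id, sbig)
    expect_lt(b$u_samp / b$u_c, 0.01)
    expect_equal(b$u_c, b$u_meas, tolerance = 1e-3)
  }
  # quadrature identity, Welch-Satterthwaite bounds on random scenarios
  for (seed in 1:30) {
    s <- random_scenario(seed)
    for (b in propagate_all(s)) {
      expect_equal(b$u_c^2, b$u_meas^2 + b$u_samp^2,
                   tolerance = 1e-10)
      expect_gte(b$v_eff, min(b$components$df) - 1e-9)
      expect_lte(b$v_eff, sum(b$components$df) + 1e-9)
    }
  }
})

test_that("combined uncertainty is monotone in u_m and sample size", {
  ums <- c(0, 0.02, 0.046, 0.08, 0.15)
  for (id in c("Se", "Sp", "DOR", "PPV", "J")) {
    ucs <- vapply(ums, function(u) propagate(id, with_um(glucose, u))$u_c,
                  numeric(1))
    expect_true(all(diff(ucs) >= -1e-12), label = id)
  }
  sizes <- c(50, 200, 1000, 5000)
  for (id in c("Se", "Sp", "DOR", "NPV")) {
    us <- vapply(sizes, function(n) {
      n_d <- max(2L, as.integer(round(0.067 * n)))
      propagate(id, with_sizes(glucose, n - n_d, n_d))$u_samp
    }, numeric(1))
    expect_true(all(diff(us) <= 1e-12), label = id)
  }
})

test_that("degenerate measures yield flagged, rectangular breakdowns", {
  # threshold so far below the diseased mean that 1 - Se underflows to
  # zero: DOR is infinite and flagged unbounded
  s <- scenario(population_sample(0, 1, 100),
                population_sample(400, 1, 100),
                measurement_model(0.02, 50), threshold = 1)
  b <- propagate("DOR", s)
  expect_identical(b$flag, "unbounded")
  expect_true(is.na(b$u_c))
  expect_error(dam_gradient("DOR", s), "unbounded")
  # less extreme tail: DOR itself is still representable but its gradient
  # overflows; the breakdown is flagged rather than raising
  s2 <- scenario(population_sample(0, 1, 100),
                 population_sample(30, 1, 100),
                 measurement_model(0.02, 50), threshold = 1)
  b2 <- propagate("DOR", s2)
  expect_true(is.finite(b2$value))
  expect_identical(b2$flag, "undefined")
  expect_true(is.na(b2$u_c))
})

test_that("relative uncertainty divides by the value and guards zero", {
  b <- propagate("Se", glucose)
  rel <- relative_uncertainty(b)
  expect_equal(unname(rel["rel_c"]), b$u_c / b$value, tolerance = 1e-12)
  expect_equal(attr(rel, "flag"), "ok")
  # J = 0 at an uninformative test: relative uncertainty is undefined
  bj <- propagate("J", identical_populations())
  relj <- relative_uncertainty(bj)
  expect_true(all(is.na(relj)))
  expect_equal(attr(relj, "flag"), "undefined-relative")
})
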