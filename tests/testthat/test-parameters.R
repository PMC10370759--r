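test_that("packaged defaults are internally consistent", {
  p <- default_parameters()
  expect_s3_class(p, "parameter_set")
  expect_length(validate_parameters(p), 0)
  expect_equal(p$prevalence_aneurysm, 0.173)
  expect_equal(sum(p$outcome_rebleed), 1)
  expect_equal(sum(p$outcome_no_aneurysm), 1)
})

test_that("validate_parameters reports every violation, not just the first", {
  p <- default_parameters()
  p$outcome_rebleed <- c(favorable = 0.5, unfavorable = 0.5, dead = 0.5)
  p$cost_cta <- -1
  p$utility_favorable <- 1.3
  v <- validate_parameters(p)
  expect_length(v, 3)
  expect_true(any(grepl("outcome_rebleed.*sum", v)))
  expect_true(any(grepl("cost_cta", v)))
  expect_true(any(grepl("utility_favorable", v)))
})

test_that("config loading fills defaults, applies overrides, rejects junk", {
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", empty)
  p <- load_parameters(empty)
  expect_equal(p$prevalence_aneurysm, 0.173)

  over <- withr::local_tempfile(fileext = ".yaml")
  writeLines("start_age: 60", over)
  p2 <- load_parameters(over)
  expect_equal(p2$start_age, 60)
  p2$start_age <- 55
  expect_equal(p2[yaml_names <- setdiff(names(p2), "dist")],
               default_parameters()[yaml_names])

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("utility_favorable: 1.3", bad)
  expect_error(load_parameters(bad), "utility_favorable")

  unknown <- withr::local_tempfile(fileext = ".yaml")
  writeLines("utility_favourable: 0.9", unknown)
  expect_error(load_parameters(unknown), "unknown config keys")

  expect_error(load_parameters(tempfile()), "not found")
})

test_that("parameter sets round-trip through YAML", {
  p <- default_parameters()
  p$start_age <- 62
  p$cost_dsa <- 2000
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, f)
  p2 <- load_parameters(f)
  expect_equal(p2[setdiff(names(p2), "dist")], p[setdiff(names(p), "dist")])
  # cost distributions re-centre on the overridden means
  expect_equal(distribution_mean(p2$dist$cost_dsa), 2000)
})

test_that("derive_gamma_spec pins the coefficient of variation", {
  d <- derive_gamma_spec(331)
  expect_equal(d$params$shape, 144)
  expect_equal(d$params$rate, 144 / 331)
  expect_equal(derive_gamma_spec(1, sd_divisor = 1)$params,
               list(shape = 1, rate = 1))
  # mean recovery to 1e-9 relative across magnitudes
  for (m in c(0.5, 331, 1919, 2665.25, 84346.39)) {
    expect_equal(distribution_mean(derive_gamma_spec(m)), m,
                 tolerance = 1e-9)
  }
  expect_error(derive_gamma_spec(0), "positive")
  expect_error(derive_gamma_spec(-5), "positive")
})

test_that("distribution_mean covers every family", {
  expect_equal(distribution_mean(dist_spec("beta", alpha = 1, beta = 1)), 0.5)
  # the published CTA-sensitivity Beta recovers the 98% base value
  expect_equal(distribution_mean(dist_spec("beta", alpha = 737.51, beta = 15.05)),
               737.51 / (737.51 + 15.05))
  expect_equal(distribution_mean(dist_spec("beta", alpha = 737.51, beta = 15.05)),
               0.98, tolerance = 1e-4)
  expect_equal(distribution_mean(dist_spec("gamma", shape = 144, rate = 0.43)),
               144 / 0.43)
  conc <- c(0.51, 0.34, 0.15)
  expect_equal(distribution_mean(dist_spec("dirichlet", conc)), conc)
  expect_equal(distribution_mean(dist_spec("point", value = 7)), 7)
})

test_that("dist_spec rejects malformed specifications", {
  expect_error(dist_spec("beta", alpha = -1, beta = 2), "positive")
  expect_error(dist_spec("gamma", shape = 1), "rate")
  expect_error(dist_spec("dirichlet", 0.5), "length >= 2")
  expect_error(dist_spec("point", value = c(1, 2)), "exactly one")
})

test_that("the audit flags known base/distribution mismatches without failing", {
  a <- audit_parameter_distributions()
  expect_s3_class(a, "data.frame")
  flagged <- a$parameter[a$mismatch]
  expect_true("prevalence_aneurysm" %in% flagged)  # beta mean ~0.200 vs 0.173
  expect_true("utility_favorable" %in% flagged)    # beta mean ~0.775 vs 0.87
  # and the well-matched rows stay unflagged
  expect_false("cta_sensitivity" %in% flagged)
  expect_false("cost_cta" %in% flagged)
})
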