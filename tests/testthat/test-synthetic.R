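# Synthetic catalog generator: determinism, ground-truth algebra and
# parameter recovery at module-test scale (the acceptance suite re-runs
# the recovery checks at the stated full scale).

test_that("case frequency from odds ratio inverts correctly", {
  expect_equal(case_freq_from_or(0.2, 1), 0.2)
  expect_equal(case_freq_from_or(0.2, 2), 1 / 3)
  # composing psi then 1/psi returns p0
  set.seed(21)
  for (i in 1:20) {
    p0 <- runif(1, 0.05, 0.95)
    psi <- exp(runif(1, -2, 2))
    p1 <- case_freq_from_or(p0, psi)
    expect_equal(case_freq_from_or(p1, 1 / psi), p0, tolerance = 1e-12)
    # odds identity
    expect_equal((p1 / (1 - p1)) / (p0 / (1 - p0)), psi,
                 tolerance = 1e-12)
  }
  expect_error(case_freq_from_or(0, 2), "p0")
  expect_error(case_freq_from_or(0.2, -1), "psi")
})

test_that("generation is seed-deterministic and order-independent", {
  params <- list(a = truth_params(n_studies = 3, n_case = 200,
                                  n_control = 200),
                 b = truth_params(p0 = 0.1, psi = 2, n_studies = 3,
                                  n_case = 200, n_control = 200))
  g1 <- generate_catalog(params, seed = 17)
  g2 <- generate_catalog(params, seed = 17)
  expect_identical(g1$catalog$records, g2$catalog$records)
  f1 <- tempfile(); f2 <- tempfile()
  write_catalog(g1$catalog, f1); write_catalog(g2$catalog, f2)
  expect_identical(readLines(f1), readLines(f2))
  g3 <- generate_catalog(params, seed = 18)
  expect_false(identical(g1$catalog$records, g3$catalog$records))
  # substreams are indexed, so one study's draw ignores the others
  solo <- simulate_study(params$b, "b", 2, 2, 17)
  expect_identical(solo$case_b,
                   g1$catalog$records$case_b[g1$catalog$records$pub_id ==
                                               "b_s02"])
})

test_that("catalog layout matches variants x studies with truth table", {
  params <- replicate(10, truth_params(n_studies = 4, n_case = 50,
                                       n_control = 50),
                      simplify = FALSE)
  g <- generate_catalog(params, seed = 5)
  expect_equal(nrow(g$catalog$records), 40)
  expect_equal(nrow(g$truth), 10)
  expect_equal(g$truth$p1,
               case_freq_from_or(g$truth$p0, g$truth$psi))
})

test_that("withheld raw data makes every record ineligible", {
  g <- generate_catalog(list(truth_params(psi = 3, n_studies = 3,
                                          n_case = 400, n_control = 400,
                                          missing_raw_rate = 1)),
                        seed = 9)
  grp <- filter_replicated(group_records(g$catalog))
  expect_length(grp, 1)
  es <- eligible_strata(grp[[1]])
  expect_false(any(es$eligible))
  expect_true(all(is.na(g$catalog$records$case_a)))
})

test_that("null variants are significant at roughly the alpha rate", {
  # module-scale calibration; the acceptance suite runs 2000 studies
  g <- generate_catalog(list(truth_params(psi = 1, p0 = 0.3,
                                          n_case = 300, n_control = 300,
                                          n_studies = 400)), seed = 31)
  rate <- mean(g$catalog$records$p_value < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("self-computed odds ratios recover the true psi", {
  g <- generate_catalog(list(truth_params(psi = 1.5, p0 = 0.3,
                                          n_case = 2000,
                                          n_control = 2000,
                                          n_studies = 200)), seed = 23)
  r <- annotate_associations(g$catalog)
  # orient each drawn OR toward allele b before taking the median
  or_b <- ifelse(r$risk_allele == "B" | is.na(r$risk_allele),
                 r$assoc_or, 1 / r$assoc_or)
  expect_equal(unname(stats::median(or_b)), 1.5, tolerance = 0.05)
})

test_that("pooled metrics recover p1, 1-p0 and the implied PPV", {
  t <- truth_params(p0 = 0.30, psi = 1.5, n_case = 2000,
                    n_control = 2000, n_studies = 5)
  g <- generate_catalog(list(v = t), seed = 17)
  grp <- filter_replicated(group_records(g$catalog))
  pred <- predictability_table(grp)
  b <- pred[pred$risk_allele == "B", ]
  expect_equal(nrow(b), 1)
  n_al <- 2 * 2000 * 5
  se1 <- sqrt(t$p1 * (1 - t$p1) / n_al)
  se0 <- sqrt(t$p0 * (1 - t$p0) / n_al)
  expect_lt(abs(b$sensitivity - t$p1), 3 * se1)
  expect_lt(abs(b$specificity - (1 - t$p0)), 3 * se0)
  ppv_true <- t$p1 / (t$p1 + t$p0)  # equal arms
  expect_lt(abs(b$ppv - ppv_true), 0.02)
  expect_equal(b$sensitivity, t$p1, tolerance = 0.02)
})

test_that("reporting discordance flips consistency at the analytic rate", {
  d <- 0.3; k <- 3
  params <- replicate(300, truth_params(p0 = 0.3, psi = 3, n_case = 400,
                                        n_control = 400, n_studies = k,
                                        discordance_rate = d,
                                        missing_raw_rate = 1),
                      simplify = FALSE)
  g <- generate_catalog(params, seed = 29)
  grp <- filter_replicated(group_records(g$catalog))
  status <- vapply(grp, function(x) assess_consistency(x)$status,
                   character(1))
  frac_inc <- mean(status != "consistent")
  analytic <- 1 - ((1 - d)^k + d^k)  # not all flips equal
  se <- sqrt(analytic * (1 - analytic) / length(grp))
  expect_lt(abs(frac_inc - analytic), 4 * se)
  # with raw counts retained, harmonization ignores the flipped report
  params2 <- lapply(params[1:50], function(p) {
    p$missing_raw_rate <- 0; p
  })
  g2 <- generate_catalog(params2, seed = 29)
  grp2 <- filter_replicated(group_records(g2$catalog))
  status2 <- vapply(grp2, function(x) assess_consistency(x)$status,
                    character(1))
  expect_true(mean(status2 == "consistent") > 0.95)
})

test_that("an all-null catalog replicates at the binomial tail rate", {
  k <- 4; n_null <- 400
  params <- replicate(n_null, truth_params(psi = 1, p0 = 0.3,
                                           n_case = 400,
                                           n_control = 400,
                                           n_studies = k),
                      simplify = FALSE)
  g <- generate_catalog(params, seed = 37)
  n_rep <- length(filter_replicated(group_records(g$catalog)))
  p_tail <- 1 - (0.95^k + k * 0.05 * 0.95^(k - 1))  # P(>=2 of k sig)
  bounds <- stats::qbinom(c(0.0005, 0.9995), n_null, p_tail)
  expect_gte(n_rep, bounds[1])
  expect_lte(n_rep, bounds[2])
})

test_that("genotype mode draws HWE genotypes consistent with alleles", {
  g <- generate_catalog(list(truth_params(p0 = 0.4, psi = 1.5,
                                          n_case = 500, n_control = 500,
                                          n_studies = 4,
                                          genotypes = TRUE)), seed = 8)
  r <- g$catalog$records
  expect_true(all(r$case_AA + r$case_AB + r$case_BB == r$n_case))
  expect_true(all(2 * r$case_BB + r$case_AB == r$case_b))
  # carrier-unit path works on these records
  cc <- confusion_from_study(r[1, ], "B", unit = "carrier")
  expect_equal(cc$tp + cc$fn, 500)
})
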