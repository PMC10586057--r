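# Allelic odds ratio, Woolf interval, chi-square p and risk-allele
# harmonization, checked against independent brute-force oracles.

test_that("odds ratio and Woolf interval match direct arithmetic", {
  # symmetric table
  sym <- allelic_odds_ratio(allele_table(10, 10, 10, 10))
  expect_equal(sym$or, 1)
  expect_true(sym$ci_low < 1 && sym$ci_high > 1)

  # frozen oracle: or = 30*85/(70*15); se = sqrt(1/30+1/70+1/15+1/85)
  est <- allelic_odds_ratio(allele_table(30, 70, 15, 85))
  expect_equal(est$or, 2.428571, tolerance = 1e-6)
  expect_equal(est$ci_low, 1.210999, tolerance = 1e-6)
  expect_equal(est$ci_high, 4.870325, tolerance = 1e-6)

  # zero cell: Haldane-Anscombe +0.5 => 5.5*7.5/(0.5*3.5)
  h <- allelic_odds_ratio(allele_table(5, 0, 3, 7))
  expect_equal(h$or, 23.571429, tolerance = 1e-6)
  expect_error(allelic_odds_ratio(allele_table(5, 0, 3, 7),
                                  zero_cell = "error"), "zero cell")
  expect_error(allelic_odds_ratio(allele_table(0, 0, 3, 7)),
               "undefined")
})

test_that("chi-square p matches the closed-form statistic", {
  ind <- allelic_chi2_p(allele_table(10, 10, 10, 10))
  expect_equal(ind$statistic, 0)
  expect_equal(ind$p, 1)

  # frozen oracle: n(ad-bc)^2/(r1 r2 c1 c2) = 200*1500^2/(100*100*45*155)
  x <- allelic_chi2_p(allele_table(30, 70, 15, 85))
  expect_equal(x$statistic, 6.451613, tolerance = 1e-6)
  expect_equal(x$p, 0.01108517, tolerance = 1e-5)

  expect_error(allelic_chi2_p(allele_table(5, 0, 3, 0)), "zero margin")
})

test_that("chi-square agrees with exhaustive oracle over small tables", {
  # brute force over every 2x2 with all cells <= 6 and positive margins
  oracle <- function(a, b, c, d) {
    n <- a + b + c + d
    n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
  }
  for (a in 0:6) for (b in 0:6) for (c in 0:6) for (d in 0:6) {
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
      next
    t <- allele_table(a, b, c, d)
    got <- allelic_chi2_p(t)
    expect_equal(got$statistic, oracle(a, b, c, d), tolerance = 1e-9)
    expect_equal(got$p,
                 stats::pchisq(oracle(a, b, c, d), 1,
                               lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("odds-ratio algebraic invariants hold", {
  set.seed(41)
  for (i in 1:25) {
    x <- sample(1:50, 4, replace = TRUE)
    t <- allele_table(x[1], x[2], x[3], x[4])
    swapped <- allele_table(x[3], x[4], x[1], x[2])
    expect_equal(allelic_odds_ratio(swapped)$or,
                 1 / allelic_odds_ratio(t)$or, tolerance = 1e-12)
    # p is invariant under swapping the group labels
    expect_equal(allelic_chi2_p(swapped)$p, allelic_chi2_p(t)$p,
                 tolerance = 1e-12)
    # OR invariant under scaling one row by a positive integer
    k <- sample(2:5, 1)
    scaled <- allele_table(k * x[1], k * x[2], x[3], x[4])
    expect_equal(allelic_odds_ratio(scaled)$or,
                 allelic_odds_ratio(t)$or, tolerance = 1e-12)
  }
})

test_that("genotype counts collapse to allele counts", {
  ac <- alleles_from_genotypes(10, 0, 0, 5, 5, 5)
  expect_equal(ac$case_a, 20)
  expect_equal(ac$case_b, 0)
  ac2 <- alleles_from_genotypes(10, 20, 5, 10, 20, 5)
  expect_equal(ac2$case_a, 40)
  expect_equal(ac2$case_b, 30)
  expect_equal(ac2$case_a + ac2$case_b, 2 * 35)
  expect_error(alleles_from_genotypes(1, 1, 1, 0, 0, 0), "empty group")
})

test_that("risk-allele harmonization flips protective reports", {
  # reported allele with OR < 1 -> the other allele
  h <- harmonize_risk_allele(make_record(allele_a = "G", allele_b = "A",
                                         reported = "T"))
  expect_true(is.na(h$risk_allele))  # unmappable label
  h <- harmonize_risk_allele(make_record(allele_a = "G", allele_b = "A",
                                         reported = "A", or = 0.722))
  expect_equal(h$risk_allele, "G")
  expect_equal(h$basis, "reported_or_direction")
  # protective report on the alternate allele
  h <- harmonize_risk_allele(make_record(allele_a = "A", allele_b = "C",
                                         reported = "A", or = 0.79))
  expect_equal(h$risk_allele, "C")
  # genotype label: composing allele, flipped by OR direction
  h <- harmonize_risk_allele(make_record(allele_a = "C", allele_b = "G",
                                         reported = "GG", or = 0.45,
                                         model = "genotypic"))
  expect_equal(h$risk_allele, "C")
  expect_equal(h$basis, "reported_genotype")
  # raw counts dominate any report
  h <- harmonize_risk_allele(make_record(case_a = 40, case_b = 60,
                                         ctrl_a = 60, ctrl_b = 40,
                                         reported = "A", or = 2))
  expect_equal(h$risk_allele, "B")
  expect_equal(h$basis, "raw_counts")
  # exact frequency tie -> none
  h <- harmonize_risk_allele(make_record(case_a = 50, case_b = 50,
                                         ctrl_a = 50, ctrl_b = 50))
  expect_true(is.na(h$risk_allele))
})

test_that("raw-count harmonization agrees with the OR direction", {
  set.seed(7)
  for (i in 1:30) {
    x <- sample(1:80, 4, replace = TRUE)
    s <- make_record(case_a = x[1], case_b = x[2],
                     ctrl_a = x[3], ctrl_b = x[4])
    h <- harmonize_risk_allele(s)
    or_b <- allelic_odds_ratio(
      allele_table(x[2], x[1], x[4], x[3]))$or  # risk = allele b
    if (or_b > 1) expect_equal(h$risk_allele, "B")
    else if (or_b < 1) expect_equal(h$risk_allele, "A")
    else expect_true(is.na(h$risk_allele))
  }
})

test_that("selection prefers recomputed allelic stats over reports", {
  # genotype counts only: allelic p computed from the derived table
  s <- make_record(case_AA = 10, case_AB = 20, case_BB = 5,
                   ctrl_AA = 20, ctrl_AB = 10, ctrl_BB = 5,
                   reported = "B", model = "genotypic", p = 0.5)
  res <- select_reported_association(s)
  expect_equal(res$basis, "raw_counts")
  ac <- alleles_from_genotypes(10, 20, 5, 20, 10, 5)
  ref <- allelic_chi2_p(allele_table(ac$case_b, ac$case_a,
                                     ac$ctrl_b, ac$ctrl_a))
  expect_equal(res$p, ref$p)

  # reported-only records fall back to published statistics
  s2 <- make_record(reported = "B", or = 1.4, p = 0.20)
  res2 <- select_reported_association(s2)
  expect_equal(res2$basis, "reported")
  expect_false(res2$significant)

  # frequencies reconstruct counts as round(freq * 2n), half-up
  s3 <- make_record(n_case = 100, n_control = 100)
  s3$case_freq_b <- 0.30; s3$ctrl_freq_b <- 0.20
  res3 <- select_reported_association(s3)
  expect_equal(res3$basis, "reconstructed_freq")
  expect_equal(res3$or, (60 * 160) / (140 * 40), tolerance = 1e-12)

  # nothing usable: unassessable, not an error
  s4 <- make_record()
  expect_equal(select_reported_association(s4)$basis, "unassessable")
})
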