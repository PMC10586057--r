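# Confusion tables, pooling, metrics, eligibility and the shortlist.

test_that("confusion tables follow the TP/FN/TN/FP definitions", {
  s <- make_record(case_a = 40, case_b = 30, ctrl_a = 50, ctrl_b = 50)
  c1 <- confusion_from_study(s, "B")
  expect_equal(c1$tp, 30); expect_equal(c1$fn, 40)
  expect_equal(c1$fp, 50); expect_equal(c1$tn, 50)
  # the other allele swaps the roles
  c2 <- confusion_from_study(s, "A")
  expect_equal(c2$tp, 40); expect_equal(c2$fp, 50)
  # flagged unavailable raw data -> ineligibility signal, not an error
  s2 <- make_record(case_a = 40, case_b = 30, ctrl_a = 50, ctrl_b = 50,
                    raw = FALSE)
  expect_null(confusion_from_study(s2, "B"))
  # carrier unit needs genotype counts
  s3 <- make_record(case_AA = 10, case_AB = 20, case_BB = 5,
                    ctrl_AA = 15, ctrl_AB = 10, ctrl_BB = 5)
  cc <- confusion_from_study(s3, "B", unit = "carrier")
  expect_equal(cc$tp, 25); expect_equal(cc$fn, 10)
  expect_null(confusion_from_study(s, "B", unit = "carrier"))
})

test_that("pooling is element-wise, associative and unit-checked", {
  a <- confusion2x2(1, 2, 3, 4)
  b <- confusion2x2(10, 20, 30, 40)
  d <- confusion2x2(5, 5, 5, 5)
  expect_equal(pool_confusions(list(a))[c("tp", "fn", "tn", "fp")],
               a[c("tp", "fn", "tn", "fp")])
  ab <- pool_confusions(list(a, b))
  expect_equal(unlist(ab[c("tp", "fn", "tn", "fp")]),
               c(tp = 11, fn = 22, tn = 33, fp = 44))
  expect_equal(pool_confusions(list(pool_confusions(list(a, b)), d)),
               pool_confusions(list(a, pool_confusions(list(b, d)))))
  expect_equal(pool_confusions(list(a, b)), pool_confusions(list(b, a)))
  expect_error(pool_confusions(list()), "empty")
  expect_error(pool_confusions(list(a, confusion2x2(1, 1, 1, 1,
                                                    unit = "carrier"))),
               "mixed units")
})

test_that("metrics are definition-forced and identity-exact", {
  m <- confusion_metrics(confusion2x2(25, 25, 25, 25))
  expect_equal(unlist(m), c(sensitivity = 0.5, specificity = 0.5,
                            ppv = 0.5))
  m2 <- confusion_metrics(confusion2x2(30, 70, 85, 15))
  expect_equal(m2$sensitivity, 0.30)
  expect_equal(m2$specificity, 0.85)
  expect_equal(m2$ppv, 30 / 45)
  m3 <- confusion_metrics(confusion2x2(100, 0, 100, 0))
  expect_equal(unlist(m3), c(sensitivity = 1, specificity = 1, ppv = 1))
  # ppv * (tp + fp) == tp exactly, over random tables
  set.seed(5)
  for (i in 1:20) {
    x <- sample(0:200, 4, replace = TRUE) + 1
    cm <- confusion2x2(x[1], x[2], x[3], x[4])
    expect_equal(confusion_metrics(cm)$ppv * (x[1] + x[4]),
                 as.numeric(x[1]), tolerance = 1e-12)
  }
  # zero denominator -> NA metric, not an error
  expect_true(is.na(confusion_metrics(confusion2x2(0, 0, 5, 5))$sensitivity))
})

test_that("pooled sensitivity is a weighted mean of per-study values", {
  set.seed(9)
  for (rep in 1:10) {
    tabs <- lapply(1:4, function(i) {
      x <- sample(1:100, 4, replace = TRUE)
      confusion2x2(x[1], x[2], x[3], x[4])
    })
    sens <- vapply(tabs, function(t) confusion_metrics(t)$sensitivity,
                   numeric(1))
    pooled <- confusion_metrics(pool_confusions(tabs))$sensitivity
    expect_true(pooled >= min(sens) - 1e-12 &&
                  pooled <= max(sens) + 1e-12)
  }
})

test_that("allele-unit confusion totals equal 2*(cases+controls)", {
  set.seed(13)
  gen <- generate_catalog(list(truth_params(p0 = 0.25, psi = 1.8,
                                            n_case = 150,
                                            n_control = 200,
                                            n_studies = 3)), seed = 3)
  g <- group_records(gen$catalog)[[1]]
  confs <- lapply(seq_len(nrow(g$records)), function(i)
    confusion_from_study(g$records[i, ], "B"))
  pooled <- pool_confusions(confs)
  expect_equal(pooled$tp + pooled$fn + pooled$tn + pooled$fp,
               2 * (150 + 200) * 3)
})

test_that("eligibility follows the availability flags and strata", {
  mdd <- load_fixture("mdd_variants")
  g <- filter_maf(filter_replicated(group_records(mdd)))$kept
  keys <- vapply(g, `[[`, character(1), "key")
  e242939 <- eligible_strata(g[[match("rs242939", keys)]])
  expect_true(e242939$eligible[e242939$risk_allele == "G"])
  expect_equal(e242939$n_raw[e242939$risk_allele == "G"], 3)
  e2234693 <- eligible_strata(g[[match("rs2234693", keys)]])
  expect_false(e2234693$eligible[e2234693$risk_allele == "C"])
  expect_equal(e2234693$reason[e2234693$risk_allele == "C"],
               "singleton_stratum")
  # a two-study stratum with one raw-data study is not poolable
  two <- make_catalog(
    make_record(pub = "a", reported = "B", or = 2, p = 0.01),
    make_record(pub = "b", reported = "B", or = 2, p = 0.01,
                raw = FALSE))
  eg <- eligible_strata(group_records(two)[[1]])
  expect_false(eg$eligible)
  expect_equal(eg$reason, "no_raw_data")
})

test_that("predictability pools counts when they are in the catalog", {
  cat <- make_catalog(
    make_record(pub = "a", case_a = 40, case_b = 60, ctrl_a = 70,
                ctrl_b = 30),
    make_record(pub = "b", case_a = 35, case_b = 65, ctrl_a = 72,
                ctrl_b = 28))
  g <- filter_replicated(group_records(cat))
  pred <- predictability_table(g)
  expect_equal(nrow(pred), 1)
  expect_equal(pred$risk_allele, "B")
  expect_equal(pred$sensitivity, (60 + 65) / 200)
  expect_equal(pred$specificity, (70 + 72) / 200)
  expect_equal(pred$ppv, 125 / (125 + 58))
  expect_equal(nrow(predictability_table(list())), 0)
})

test_that("shortlist requires replication, consistency and a PPV", {
  mdd <- load_fixture("mdd_variants")
  g <- filter_maf(filter_replicated(group_records(mdd)))$kept
  pred <- predictability_table(g)
  sl <- shortlist_variants(g, pred)
  expect_true(all(c("rs242939", "rs1801133") %in% sl$key))
  # consistent but assessable nowhere -> excluded
  expect_false("rs2273289" %in% sl$key)
  # inconsistent -> excluded
  expect_false("5-HTTLPR" %in% sl$key)

  resp <- load_fixture("response_variants")
  rg <- filter_replicated(group_records(resp, domain = "response"))
  rpred <- predictability_table(rg)
  rsl <- shortlist_variants(rg, rpred)
  expect_setequal(rsl$key, c("STin2", "rs41423247"))
  expect_equal(rsl$stratum[rsl$key == "rs41423247"], "response/SSRI/C")
})
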